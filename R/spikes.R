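#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold` separated from the previous
#' accepted spike by at least `refractory` ms.  Crossing times are linearly
#' interpolated between samples.
#'
#' @param result A `simulation_result`, or a list with `time` and a numeric
#'   `V` vector.
#' @param threshold Detection threshold, mV (default -20 for neurons, 0 for
#'   pacemaker cycle detection).
#' @param refractory Minimum separation, ms.
#' @param compartment State column to use (default: somatic/only voltage).
#' @return Numeric vector of spike times (ms); empty if none.
#' @export
detect_spikes <- function(result, threshold = -20, refractory = 2,
                          compartment = NULL) {
  tv <- .voltage_trace(result, compartment)
  upward_crossings(tv$time, tv$V, threshold, refractory)
}

#' @rdname detect_spikes
#' @param time,v Raw time (ms) and voltage (mV) vectors.
#' @export
upward_crossings <- function(time, v, threshold, refractory = 0) {
  above <- v >= threshold
  idx <- which(!above[-length(above)] & above[-1])
  if (!length(idx)) return(numeric(0))
  frac <- (threshold - v[idx]) / (v[idx + 1] - v[idx])
  tcross <- time[idx] + frac * (time[idx + 1] - time[idx])
  if (refractory > 0 && length(tcross) > 1) {
    keep <- tcross[1]
    for (tc in tcross[-1]) if (tc - keep[length(keep)] >= refractory)
      keep <- c(keep, tc)
    tcross <- keep
  }
  tcross
}

.voltage_trace <- function(result, compartment = NULL) {
  if (inherits(result, "simulation_result")) {
    cols <- colnames(result$states)
    if (is.null(compartment))
      compartment <- if ("V" %in% cols) "V" else "Vs"
    list(time = result$time, V = result$states[, compartment])
  } else {
    list(time = result$time, V = result$V)
  }
}

#' Action-potential shape metrics
#'
#' Measures per-AP shape statistics over a time window: peak (mV), minimum
#' diastolic potential (mV), amplitude (peak minus MDP), width at half
#' amplitude (ms), APD50/APD90 (ms, from the upstroke half-amplitude
#' crossing to 50%/90% repolarisation), and mean cycle length (ms).  All
#' level crossings are linearly interpolated.
#'
#' @param result A `simulation_result` (or `time`/`V` list).
#' @param window Length-2 numeric window `[t0, t1]` in ms; default the full
#'   trace.
#' @param threshold Spike-detection threshold used to locate APs.
#' @param refractory Spike-detector refractory period, ms.
#' @param compartment Voltage column (see [detect_spikes()]).
#' @return A list of class `ap_metrics`; if the window holds no AP, the
#'   field `no_ap` is `TRUE` and the numeric fields are `NA`.
#' @export
ap_metrics <- function(result, window = NULL, threshold = -20,
                       refractory = 2, compartment = NULL) {
  tv <- .voltage_trace(result, compartment)
  if (is.null(window)) window <- range(tv$time)
  sel <- tv$time >= window[1] & tv$time <= window[2]
  tt <- tv$time[sel]; vv <- tv$V[sel]
  empty <- structure(list(no_ap = TRUE, n_ap = 0L, peak = NA_real_,
                          mdp = NA_real_, amplitude = NA_real_,
                          half_width = NA_real_, apd50 = NA_real_,
                          apd90 = NA_real_, cycle_length = NA_real_),
                     class = "ap_metrics")
  if (length(tt) < 3) return(empty)
  sp <- upward_crossings(tt, vv, threshold, refractory)
  if (!length(sp)) return(empty)

  peaks <- mdps <- hw <- a50 <- a90 <- numeric(0)
  peak_t <- numeric(0)
  for (i in seq_along(sp)) {
    # segment runs from the AP base (voltage minimum since the previous
    # upstroke) to the next upstroke, so the rising phase is included
    prev <- if (i > 1) sp[i - 1] else tt[1]
    pre <- tt >= prev & tt <= sp[i]
    lo <- if (any(pre)) tt[pre][which.min(vv[pre])] else sp[i]
    hi <- if (i < length(sp)) sp[i + 1] else tt[length(tt)]
    seg <- tt >= lo & tt <= hi
    if (sum(seg) < 3) next
    ts <- tt[seg]; vs <- vv[seg]
    ipk <- which.max(vs)
    pk <- vs[ipk]
    md <- min(vs[ipk:length(vs)])   # diastolic minimum after the peak
    peaks <- c(peaks, pk); mdps <- c(mdps, md); peak_t <- c(peak_t, ts[ipk])
    amp <- pk - md
    hw <- c(hw, .width_at_level(ts, vs, md + amp / 2))
    a50 <- c(a50, .apd(ts, vs, ipk, pk - 0.5 * amp))
    a90 <- c(a90, .apd(ts, vs, ipk, pk - 0.9 * amp))
  }
  if (!length(peaks)) return(empty)
  cl <- if (length(sp) > 1) mean(diff(sp)) else NA_real_
  structure(list(no_ap = FALSE, n_ap = length(peaks),
                 peak = mean(peaks), mdp = mean(mdps),
                 amplitude = mean(peaks - mdps),
                 half_width = mean(hw, na.rm = TRUE),
                 apd50 = mean(a50, na.rm = TRUE),
                 apd90 = mean(a90, na.rm = TRUE),
                 cycle_length = cl),
            class = "ap_metrics")
}

# total time spent above `level` within one AP segment (interpolated)
.width_at_level <- function(ts, vs, level) {
  above <- vs >= level
  if (!any(above)) return(NA_real_)
  w <- 0
  for (i in seq_len(length(ts) - 1)) {
    t0 <- ts[i]; t1 <- ts[i + 1]; v0 <- vs[i]; v1 <- vs[i + 1]
    if (above[i] && above[i + 1]) w <- w + (t1 - t0)
    else if (!above[i] && above[i + 1])
      w <- w + (t1 - t0) * (1 - (level - v0) / (v1 - v0))
    else if (above[i] && !above[i + 1])
      w <- w + (t1 - t0) * (level - v0) / (v1 - v0)
  }
  w
}

# duration from upstroke crossing of `level` to repolarisation below it
.apd <- function(ts, vs, ipk, level) {
  iup <- which(vs[1:max(ipk - 1, 1)] < level)
  t_up <- if (length(iup)) {
    i <- max(iup)
    ts[i] + (ts[i + 1] - ts[i]) * (level - vs[i]) / (vs[i + 1] - vs[i])
  } else ts[1]
  rest <- ipk:length(ts)
  idn <- which(vs[rest] < level)
  if (!length(idn)) return(NA_real_)
  j <- rest[min(idn)]
  t_dn <- ts[j - 1] + (ts[j] - ts[j - 1]) *
    (level - vs[j - 1]) / (vs[j] - vs[j - 1])
  t_dn - t_up
}

#' @export
print.ap_metrics <- function(x, ...) {
  if (x$no_ap) cat("<ap_metrics> no action potential in window\n")
  else cat(sprintf(
    "<ap_metrics> n=%d peak=%.1f mV MDP=%.1f mV amp=%.1f mV hw=%.2f ms CL=%.1f ms\n",
    x$n_ap, x$peak, x$mdp, x$amplitude, x$half_width, x$cycle_length))
  invisible(x)
}
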