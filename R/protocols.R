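#' f-I curve (firing frequency versus injected DC amplitude)
#'
#' Applies a somatic DC of each amplitude for `duration` ms and counts
#' spikes in the analysis window, which excludes the first
#' `settle` ms after stimulus onset so that steady firing is measured.
#'
#' @param model A neuron [cell_model()].
#' @param amplitudes Strictly increasing stimulus amplitudes, nA.
#' @param duration Stimulus duration, ms (default 1000).
#' @param settle Onset exclusion, ms (default 200).
#' @param threshold,refractory Spike-detection settings.
#' @return An object of class `fi_curve`: data frame with columns
#'   `amplitude` (nA), `frequency` (Hz), `failed` (logical), plus
#'   attributes `duration` and `settle`.
#' @export
fi_curve <- function(model, amplitudes = seq(0.25, 1.4, by = 0.05),
                     duration = 1000, settle = 200,
                     threshold = -20, refractory = 2) {
  stopifnot(inherits(model, "cell_model"))
  if (any(diff(amplitudes) <= 0))
    stop("amplitudes must be strictly increasing")
  onset <- 100
  freq <- numeric(length(amplitudes))
  failed <- logical(length(amplitudes))
  for (i in seq_along(amplitudes)) {
    res <- tryCatch(
      integrate_cell(model,
                     stimulus = data.frame(start = onset,
                                           end = onset + duration,
                                           amplitude = amplitudes[i]),
                     duration = onset + duration),
      error = function(e) e)
    if (inherits(res, "error")) {
      freq[i] <- NA_real_
      failed[i] <- TRUE
      next
    }
    sp <- detect_spikes(res, threshold = threshold, refractory = refractory)
    sp <- sp[sp >= onset + settle & sp <= onset + duration]
    freq[i] <- length(sp) / ((duration - settle) / 1000)
  }
  out <- data.frame(amplitude = amplitudes, frequency = freq, failed = failed)
  attr(out, "duration") <- duration
  attr(out, "settle") <- settle
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Threshold (rheobase) current by bisection
#'
#' Finds the minimal DC amplitude that elicits at least one spike from the
#' resting state, by bisection on a straddling bracket.
#'
#' @param model A neuron [cell_model()].
#' @param bracket Length-2 interval (nA) with no spike at the lower end and
#'   at least one at the upper end.
#' @param tol Bisection tolerance, nA (default 0.001 = 1 pA).
#' @param duration Stimulus duration, ms.
#' @param threshold Spike-detection threshold, mV.
#' @return Threshold current in nA (midpoint of the final bracket), with
#'   attribute `iterations`.
#' @export
threshold_current <- function(model, bracket = c(0.05, 1.0), tol = 0.001,
                              duration = 1000, threshold = -20) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], tol > 0)
  spikes_at <- function(amp) {
    res <- integrate_cell(model,
                          stimulus = data.frame(start = 100,
                                                end = 100 + duration,
                                                amplitude = amp),
                          duration = 100 + duration)
    length(detect_spikes(res, threshold = threshold))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (spikes_at(lo) > 0 || spikes_at(hi) == 0)
    stop("bracket does not straddle the spike threshold: ",
         "need 0 spikes at ", lo, " nA and >= 1 at ", hi, " nA")
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) > 0) hi <- mid else lo <- mid
    iter <- iter + 1L
  }
  structure((lo + hi) / 2, iterations = iter)
}

#' Pacemaking frequency of a spontaneously active cell
#'
#' Integrates the model with no stimulus and measures the cycle rate as
#' `(n - 1) / (t_last - t_first)` over upward 0 mV crossings after the
#' settling period.  A cell with fewer than 2 crossings is quiescent.
#'
#' @param model A SAN [cell_model()], or a precomputed `simulation_result`.
#' @param record Total recording, ms (default 20000).
#' @param settle Settling exclusion, ms (default 2000).
#' @param control_frequency Optional control rate (Hz) for the relative
#'   difference.
#' @return A list of class `pacemaking_summary`: `frequency` (Hz; 0 if
#'   quiescent), `quiescent`, `n_cycles`, and `relative_difference`
#'   (`(f - f_ctrl) / f_ctrl`, `NA` if no control given).
#' @export
pacemaking_frequency <- function(model, record = 20000, settle = 2000,
                                 control_frequency = NULL) {
  res <- if (inherits(model, "simulation_result") ||
             (is.list(model) && !inherits(model, "cell_model") &&
              all(c("time", "V") %in% names(model)))) model
         else integrate_cell(model, duration = record)
  tv <- .voltage_trace(res)
  sel <- tv$time >= settle
  cross <- upward_crossings(tv$time[sel], tv$V[sel], 0, 50)
  quiescent <- length(cross) < 2
  f <- if (quiescent) 0
       else (length(cross) - 1) / (cross[length(cross)] - cross[1]) * 1000
  rel <- if (is.null(control_frequency)) NA_real_
         else (f - control_frequency) / control_frequency
  structure(list(frequency = f, quiescent = quiescent,
                 n_cycles = length(cross), relative_difference = rel),
            class = "pacemaking_summary")
}

#' @export
print.pacemaking_summary <- function(x, ...) {
  if (x$quiescent) cat("<pacemaking_summary> quiescent\n")
  else cat(sprintf("<pacemaking_summary> %.3f Hz over %d cycles%s\n",
                   x$frequency, x$n_cycles,
                   if (is.na(x$relative_difference)) "" else
                     sprintf(" (%+.1f%% vs control)",
                             100 * x$relative_difference)))
  invisible(x)
}

#' Mean firing rate over an amplitude range
#'
#' Arithmetic mean of the f-I curve frequencies at amplitudes inside the
#' closed interval `range`.
#'
#' @param fi An [fi_curve()] result.
#' @param range Length-2 amplitude interval, nA.
#' @return Mean rate, Hz.
#' @export
mean_rate <- function(fi, range = c(0.35, 1.4)) {
  stopifnot(inherits(fi, "fi_curve") || is.data.frame(fi))
  sel <- fi$amplitude >= range[1] & fi$amplitude <= range[2] & !fi$failed
  if (!any(sel)) stop("no f-I amplitudes inside the requested range")
  mean(fi$frequency[sel])
}
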