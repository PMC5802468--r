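#' Behaviour-preservation condition sets
#'
#' Conditions under which a variant cell still counts as "the same kind of
#' cell" as its control.  For neurons: A1-A3 require identical spike
#' counts under three brief somatic probe stimuli (multiples of the
#' control rheobase, `probe_duration` ms long, spanning sub-threshold,
#' just-supra-threshold and strong drive); A4 bounds the relative change
#' in steady firing frequency under a sustained DC; A5 bounds the change
#' in AP peak (mV) and the relative change in spike half-width on the
#' same sustained trace.  The count conditions use *brief* probes rather
#' than second-long trains deliberately: over a long train the count is
#' just frequency x time, so count equality would duplicate A4 at
#' near-zero tolerance and no variant could retain a visible steady-state
#' effect.  For pacemaker cells: B1 bounds the relative change in
#' pacemaking frequency; B2 bounds the relative changes in AP amplitude
#' and APD50.
#'
#' All tolerances are configurable; calibrated thresholds are therefore
#' configuration-dependent quantities, not universal constants.
#'
#' @param family `"neuron"` or `"san"`.
#' @param probe_multiples Probe amplitudes as multiples of the control
#'   rheobase (A1-A3).  The defaults `c(0.5, 10, 2.5)` with durations
#'   `c(150, 5, 32)` ms give control responses of 0, 1 and 1 spikes with
#'   wide margins: a sub-threshold hold, a brief strong pulse that fires
#'   exactly one AP, and a short supra-threshold step whose count is
#'   guarded by the first-spike latency.  Counts of 0 or 1 make spike-count
#'   equality a robust qualitative condition rather than a disguised
#'   zero-tolerance frequency condition.
#' @param probe_duration Probe stimulus durations, ms (recycled to the
#'   length of `probe_multiples`).
#' @param sustain_multiple Sustained-DC amplitude as a multiple of the
#'   control rheobase (A4/A5; default 2.5, strong drive where the f-I
#'   curve is flat and the frequency condition measures gain rather than
#'   amplified threshold shifts).
#' @param stim_duration Sustained stimulus duration, ms (default 700).
#' @param freq_tol Relative frequency tolerance (A4/B1).
#' @param peak_tol_mV Max AP peak deviation, mV (A5).
#' @param width_tol Relative half-width (A5) / APD50 (B2) tolerance.
#' @param amp_tol Relative AP amplitude tolerance (B2).
#' @param record SAN recording length, ms.
#' @param settle SAN settling exclusion, ms.
#' @return An object of class `condition_set`.
#' @export
condition_set <- function(family = c("neuron", "san"),
                          probe_multiples = c(0.5, 10, 2.5),
                          probe_duration = c(150, 5, 32),
                          sustain_multiple = 2.5,
                          stim_duration = 700,
                          freq_tol = 0.25,
                          peak_tol_mV = 10,
                          width_tol = 0.25,
                          amp_tol = 0.20,
                          record = 8000, settle = 2000) {
  family <- match.arg(family)
  stopifnot(freq_tol > 0, peak_tol_mV > 0, width_tol > 0, amp_tol > 0,
            probe_duration > 0, stim_duration > 0)
  probe_duration <- rep_len(probe_duration, length(probe_multiples))
  structure(list(family = family,
                 probe_multiples = probe_multiples,
                 probe_duration = probe_duration,
                 sustain_multiple = sustain_multiple,
                 stim_duration = stim_duration,
                 freq_tol = freq_tol, peak_tol_mV = peak_tol_mV,
                 width_tol = width_tol, amp_tol = amp_tol,
                 record = record, settle = settle),
            class = "condition_set")
}

#' Reference measurements of a control model
#'
#' Computes (once) the control-side quantities that condition evaluation
#' compares against: rheobase and per-stimulus spike counts, frequency and
#' AP shape for neurons; pacemaking frequency and AP shape for SAN cells.
#'
#' @param control A [cell_model()].
#' @param conditions A [condition_set()] of the same family.
#' @return An opaque reference object, reusable across many candidates.
#' @export
condition_reference <- function(control, conditions) {
  stopifnot(inherits(control, "cell_model"),
            control$family == conditions$family)
  if (conditions$family == "neuron") {
    rheo <- threshold_current(control, tol = 0.005,
                              duration = conditions$stim_duration)
    probe_amps <- as.numeric(rheo) * conditions$probe_multiples
    probes <- Map(.neuron_probe_count, amp = probe_amps,
                  dur = conditions$probe_duration,
                  MoreArgs = list(model = control))
    sustain_amp <- as.numeric(rheo) * conditions$sustain_multiple
    sustained <- .neuron_sustained_measure(control, sustain_amp, conditions)
    list(family = "neuron", rheobase = as.numeric(rheo),
         probe_amps = probe_amps, probes = probes,
         sustain_amp = sustain_amp, sustained = sustained)
  } else {
    meas <- .san_measure(control, conditions)
    if (meas$quiescent)
      stop("control SAN model is quiescent; cannot calibrate against it")
    list(family = "san", measure = meas)
  }
}

# spike count under a brief probe stimulus (A1-A3)
.neuron_probe_count <- function(model, amp, dur) {
  res <- tryCatch(
    integrate_cell(model,
                   stimulus = data.frame(start = 100, end = 100 + dur,
                                         amplitude = amp),
                   duration = 120 + dur),
    error = function(e) NULL)
  if (is.null(res)) return(list(failed = TRUE))
  list(failed = FALSE, n_spikes = length(detect_spikes(res)))
}

# steady frequency and AP shape under a sustained DC (A4/A5)
.neuron_sustained_measure <- function(model, amp, conditions) {
  res <- tryCatch(
    integrate_cell(model,
                   stimulus = data.frame(
                     start = 100, end = 100 + conditions$stim_duration,
                     amplitude = amp),
                   duration = 100 + conditions$stim_duration),
    error = function(e) NULL)
  if (is.null(res)) return(list(failed = TRUE))
  window <- c(300, 100 + conditions$stim_duration)
  sp <- detect_spikes(res)
  nsp <- sum(sp >= window[1] & sp <= window[2])
  list(failed = FALSE, n_spikes = length(sp),
       frequency = nsp / diff(window) * 1000,
       metrics = ap_metrics(res, window = window))
}

.san_measure <- function(model, conditions) {
  res <- tryCatch(integrate_cell(model, duration = conditions$record),
                  error = function(e) NULL)
  if (is.null(res)) return(list(failed = TRUE, quiescent = TRUE))
  pf <- pacemaking_frequency(res, record = conditions$record,
                             settle = conditions$settle)
  met <- ap_metrics(res, window = c(conditions$settle, conditions$record),
                    threshold = -20)
  list(failed = FALSE, quiescent = pf$quiescent, frequency = pf$frequency,
       metrics = met)
}

#' Evaluate behaviour-preservation conditions
#'
#' Compares a candidate model against control reference measurements and
#' reports, per condition, the measured quantity, its bound, and pass/fail.
#' A candidate that loses the reference behaviour class altogether (no
#' spikes where the control spikes; quiescence where the control paces;
#' integration failure) fails all conditions and is flagged
#' `qualitative_loss`.
#'
#' @param control A [cell_model()] (control).
#' @param candidate A [cell_model()] of the same family.
#' @param conditions A [condition_set()].
#' @param reference Optional precomputed [condition_reference()] for
#'   `control` (computed on the fly if omitted).
#' @return A data frame of class `condition_report` with columns
#'   `condition`, `measured`, `bound`, `pass`, and attribute
#'   `qualitative_loss`.
#' @export
evaluate_conditions <- function(control, candidate, conditions,
                                reference = NULL) {
  stopifnot(inherits(candidate, "cell_model"),
            candidate$family == conditions$family)
  if (is.null(reference)) reference <- condition_reference(control, conditions)
  if (conditions$family == "neuron")
    .evaluate_neuron(reference, candidate, conditions)
  else
    .evaluate_san(reference, candidate, conditions)
}

.report <- function(condition, measured, bound, pass) {
  data.frame(condition = condition, measured = measured, bound = bound,
             pass = pass, stringsAsFactors = FALSE)
}

.all_fail <- function(conds) {
  rep <- do.call(rbind, lapply(conds, .report, measured = NA_real_,
                               bound = NA_real_, pass = FALSE))
  attr(rep, "qualitative_loss") <- TRUE
  class(rep) <- c("condition_report", "data.frame")
  rep
}

.evaluate_neuron <- function(reference, candidate, cs) {
  cond_names <- c("A1", "A2", "A3", "A4", "A5.peak", "A5.width")
  probes <- Map(.neuron_probe_count, amp = reference$probe_amps,
                dur = cs$probe_duration, MoreArgs = list(model = candidate))
  sustained <- .neuron_sustained_measure(candidate, reference$sustain_amp,
                                         cs)
  if (any(vapply(probes, `[[`, logical(1), "failed")) || sustained$failed)
    return(.all_fail(cond_names))
  # qualitative loss: no spikes anywhere although the control spikes
  ctrl_spk <- vapply(reference$probes, `[[`, numeric(1), "n_spikes")
  cand_spk <- vapply(probes, `[[`, numeric(1), "n_spikes")
  if (all(cand_spk == 0) && sustained$n_spikes == 0 &&
      (any(ctrl_spk > 0) || reference$sustained$n_spikes > 0))
    return(.all_fail(cond_names))

  rows <- list()
  for (i in seq_along(reference$probe_amps))
    rows[[i]] <- .report(paste0("A", i), cand_spk[i] - ctrl_spk[i], 0,
                         cand_spk[i] == ctrl_spk[i])
  f0 <- reference$sustained$frequency
  f1 <- sustained$frequency
  df <- if (f0 > 0) abs(f1 - f0) / f0 else abs(f1 - f0)
  rows[[length(rows) + 1L]] <- .report("A4", df, cs$freq_tol, df <= cs$freq_tol)
  m0 <- reference$sustained$metrics
  m1 <- sustained$metrics
  if (m1$no_ap || m0$no_ap) {
    rows[[length(rows) + 1L]] <- .report("A5.peak", NA_real_, cs$peak_tol_mV, FALSE)
    rows[[length(rows) + 1L]] <- .report("A5.width", NA_real_, cs$width_tol, FALSE)
  } else {
    dpk <- abs(m1$peak - m0$peak)
    dw <- abs(m1$half_width - m0$half_width) / m0$half_width
    rows[[length(rows) + 1L]] <- .report("A5.peak", dpk, cs$peak_tol_mV,
                                         dpk <= cs$peak_tol_mV)
    rows[[length(rows) + 1L]] <- .report("A5.width", dw, cs$width_tol,
                                         dw <= cs$width_tol)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "qualitative_loss") <- FALSE
  class(rep) <- c("condition_report", "data.frame")
  rep
}

.evaluate_san <- function(reference, candidate, cs) {
  cond_names <- c("B1", "B2.amp", "B2.apd50")
  m1 <- .san_measure(candidate, cs)
  if (m1$failed || m1$quiescent) return(.all_fail(cond_names))
  m0 <- reference$measure
  df <- abs(m1$frequency - m0$frequency) / m0$frequency
  rows <- list(.report("B1", df, cs$freq_tol, df <= cs$freq_tol))
  if (m1$metrics$no_ap || m0$metrics$no_ap) {
    rows[[2]] <- .report("B2.amp", NA_real_, cs$amp_tol, FALSE)
    rows[[3]] <- .report("B2.apd50", NA_real_, cs$width_tol, FALSE)
  } else {
    da <- abs(m1$metrics$amplitude - m0$metrics$amplitude) /
      m0$metrics$amplitude
    dapd <- abs(m1$metrics$apd50 - m0$metrics$apd50) / m0$metrics$apd50
    rows[[2]] <- .report("B2.amp", da, cs$amp_tol, da <= cs$amp_tol)
    rows[[3]] <- .report("B2.apd50", dapd, cs$width_tol, dapd <= cs$width_tol)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "qualitative_loss") <- FALSE
  class(rep) <- c("condition_report", "data.frame")
  rep
}

#' Generic threshold-scale search
#'
#' Finds the largest scale `c` in `[0, 1]` such that `pass_fn(s)` is `TRUE`
#' at every probed scale `s <= c`: ascending coarse scan followed by
#' bisection of the first failing interval.  If no probed scale fails,
#' returns 1.  Non-monotone pass patterns are resolved by honouring the
#' FIRST violation from below.
#'
#' @param pass_fn Function of one scale argument returning `TRUE`/`FALSE`.
#' @param step Coarse scan step (default 0.1).
#' @param tol Bisection tolerance on `c` (default 1e-3).
#' @return List with `c`, `n_evals`, and `first_violation` (scale of the
#'   bisected upper bound, or `NA` if conditions pass everywhere).
#' @export
find_threshold_scale <- function(pass_fn, step = 0.1, tol = 1e-3) {
  n <- 0L
  passes <- function(s) { n <<- n + 1L; isTRUE(pass_fn(s)) }
  grid <- seq(step, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  lo <- 0; hi <- NA_real_
  for (s in grid) {
    if (passes(s)) lo <- s else { hi <- s; break }
  }
  if (is.na(hi)) return(list(c = 1, n_evals = n, first_violation = NA_real_))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (passes(mid)) lo <- mid else hi <- mid
  }
  list(c = lo, n_evals = n, first_violation = hi)
}

#' Calibrate the downscaling threshold c for a variant
#'
#' Scales a variant's parameter effects by `c` (offsets linearly, factors
#' on the log scale) and finds the largest `c` in `[0, 1]` at which the
#' variant model still satisfies every behaviour-preservation condition at
#' all probed scales below.  `c = 0` reproduces the control exactly and
#' always passes; an effect violating conditions at every probed scale gets
#' `c = 0`.
#'
#' @param control Control [cell_model()].
#' @param effect A [variant_effect()].
#' @param conditions A [condition_set()] matching the control's family.
#' @param reference Optional precomputed [condition_reference()].
#' @param step Coarse scan step (default 0.1).
#' @param tol Bisection tolerance (default 1e-3).
#' @return A list of class `calibration_result`: `c`, `report` (condition
#'   report at the calibrated `c`), `first_violation`, `n_evaluations`.
#' @export
find_threshold_c <- function(control, effect, conditions, reference = NULL,
                             step = 0.1, tol = 1e-3) {
  if (is.null(reference)) reference <- condition_reference(control, conditions)
  if (!variant_applicable(control, effect))
    stop("variant ", effect$id, " is not applicable to model ", control$name)
  pass_fn <- function(s) {
    cand <- apply_variant(control, effect, epsilon = 1, c_scale = s)
    rep <- evaluate_conditions(control, cand, conditions, reference)
    all(rep$pass)
  }
  res <- find_threshold_scale(pass_fn, step = step, tol = tol)
  final <- evaluate_conditions(
    control, apply_variant(control, effect, epsilon = 1, c_scale = res$c),
    conditions, reference)
  structure(list(c = res$c, report = final,
                 first_violation = res$first_violation,
                 n_evaluations = res$n_evals),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> c = %.4f (%d condition evaluations)\n",
              x$c, x$n_evaluations))
  print(as.data.frame(x$report))
  invisible(x)
}

#' Serialise a calibration result as JSON
#'
#' @param x A `calibration_result`.
#' @param variant_id,model_id Identifiers recorded in the report.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calibration_json <- function(x, variant_id, model_id, path) {
  obj <- list(variant_id = variant_id, model_id = model_id, c = x$c,
              first_violation = x$first_violation,
              n_evaluations = x$n_evaluations,
              conditions = as.data.frame(x$report))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
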