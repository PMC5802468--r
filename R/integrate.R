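#' Integrate a cell model
#'
#' Runs the model's ODE system with a variable-step stiff solver
#' ([deSolve::lsoda]) under a piecewise-constant current stimulus.  The
#' integration is deterministic: identical inputs and tolerances give
#' bit-identical trajectories.
#'
#' @param model A [cell_model()].
#' @param stimulus `NULL` for no stimulus, or a data frame with columns
#'   `start`, `end` (ms) and `amplitude` (nA), optionally `compartment`
#'   (`"soma"`/`"dend"`, neuron only; default soma).  Segments must not
#'   overlap.
#' @param duration Total simulated time, ms.
#' @param state0 Optional initial state (defaults to the model's `state0`).
#' @param rtol,atol Solver tolerances (defaults `1e-8`).
#' @param dt_record Output grid spacing, ms (default 0.25 for pacemaker
#'   cells, 0.05 for neurons).
#' @return A `simulation_result`: list with `time` (ms), `states` (matrix,
#'   one named column per state variable), `model`, and solver diagnostics.
#' @export
integrate_cell <- function(model, stimulus = NULL, duration,
                           state0 = NULL, rtol = 1e-8, atol = 1e-8,
                           dt_record = NULL) {
  stopifnot(inherits(model, "cell_model"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (is.null(dt_record))
    dt_record <- if (model$family == "san") 0.25 else 0.05
  y0 <- if (is.null(state0)) model$state0 else {
    if (!identical(names(state0), names(model$state0)))
      stop("state0 does not match the model's state layout")
    state0
  }
  fam <- .family_code(model$family)
  nstim <- if (model$family == "neuron") 2L else 1L

  segs <- .stimulus_segments(stimulus, duration, model$family)
  rhs <- function(t, y, parms, stim) {
    list(cell_rhs_cpp(fam, t, y, parms, stim))
  }

  rows <- vector("list", nrow(segs))
  t0 <- 0
  y <- y0
  nfun <- 0L
  for (i in seq_len(nrow(segs))) {
    t1 <- segs$end[i]
    stim <- numeric(nstim)
    stim[1] <- segs$amp_soma[i]
    if (nstim == 2L) stim[2] <- segs$amp_dend[i]
    times <- unique(c(seq(t0, t1, by = dt_record), t1))
    out <- deSolve::lsoda(y = y, times = times, func = rhs, parms = model$params,
                          stim = stim, rtol = rtol, atol = atol,
                          maxsteps = 500000)
    di <- attributes(out)$istate
    if (!is.null(di) && di[1] < 0)
      stop("integration error: solver failed in segment ", i,
           " (istate ", di[1], ")")
    nfun <- nfun + if (!is.null(di)) di[3] else 0L
    m <- unclass(out)
    rows[[i]] <- if (i == 1) m else m[-1, , drop = FALSE]
    y <- m[nrow(m), -1]
    names(y) <- names(y0)
    t0 <- t1
  }
  m <- do.call(rbind, rows)
  time <- m[, 1]
  states <- m[, -1, drop = FALSE]
  colnames(states) <- names(y0)
  .check_trajectory(states, model)
  structure(list(time = time, states = states, model = model,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    n_rhs_evals = nfun)),
            class = "simulation_result")
}

.stimulus_segments <- function(stimulus, duration, family) {
  if (is.null(stimulus) || nrow(as.data.frame(stimulus)) == 0)
    return(data.frame(start = 0, end = duration, amp_soma = 0, amp_dend = 0))
  stimulus <- as.data.frame(stimulus)
  if (!all(c("start", "end", "amplitude") %in% names(stimulus)))
    stop("stimulus needs columns start, end, amplitude")
  if (is.null(stimulus$compartment)) stimulus$compartment <- "soma"
  stimulus <- stimulus[order(stimulus$start), , drop = FALSE]
  if (any(stimulus$end <= stimulus$start))
    stop("stimulus segments must have end > start")
  brk <- sort(unique(c(0, duration,
                       pmin(stimulus$start, duration),
                       pmin(stimulus$end, duration))))
  segs <- data.frame(start = brk[-length(brk)], end = brk[-1])
  segs$amp_soma <- 0
  segs$amp_dend <- 0
  for (i in seq_len(nrow(stimulus))) {
    hit <- segs$start >= stimulus$start[i] & segs$end <= stimulus$end[i]
    col <- if (identical(stimulus$compartment[i], "dend")) "amp_dend" else "amp_soma"
    segs[[col]][hit] <- segs[[col]][hit] + stimulus$amplitude[i]
  }
  segs[segs$end > segs$start, , drop = FALSE]
}

# post-hoc sanity: gates in [0,1], concentrations positive, V bounded
.check_trajectory <- function(states, model) {
  vcols <- intersect(colnames(states), c("V", "Vs", "Vd"))
  for (v in vcols) {
    if (any(!is.finite(states[, v])) || any(abs(states[, v]) > 200))
      stop("integration error: state blow-up in variable '", v, "'")
  }
  ccols <- intersect(colnames(states), c("Cai", "CaSR"))
  for (cc in ccols) {
    if (any(states[, cc] <= 0))
      stop("integration error: non-positive concentration in '", cc, "'")
  }
  gcols <- setdiff(colnames(states), c(vcols, ccols))
  g <- states[, gcols, drop = FALSE]
  if (any(g < -1e-6) || any(g > 1 + 1e-6))
    stop("integration error: gate out of [0,1] in '",
         gcols[which(apply(g < -1e-6 | g > 1 + 1e-6, 2, any))[1]], "'")
  invisible(TRUE)
}

#' Membrane currents along a simulated trajectory
#'
#' Re-evaluates the model's ionic currents at every stored time point,
#' optionally restricted to a time window.
#'
#' @param result A `simulation_result`.
#' @param window Optional length-2 time window `[t0, t1]`, ms.
#' @return Matrix with one named column per current (nA).
#' @export
cell_currents <- function(result, window = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  states <- result$states
  if (!is.null(window)) {
    sel <- result$time >= window[1] & result$time <= window[2]
    states <- states[sel, , drop = FALSE]
  }
  cell_currents_cpp(.family_code(result$model$family), states,
                    result$model$params)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$model$name, ":",
      length(x$time), "samples over", max(x$time), "ms\n")
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}

#' Write a simulation result as tidy CSV
#'
#' One row per time point, `time` plus one column per state variable; a
#' comment header declares the units.
#'
#' @param result A `simulation_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_simulation_csv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: time ms; V* mV; gates dimensionless; Ca* mM"), con)
  write.table(as.data.frame(result), con, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
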