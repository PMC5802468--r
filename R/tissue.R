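#' One-dimensional chain of coupled pacemaker cells
#'
#' `cable_config()` describes a chain of identical SAN cells coupled by a
#' diffusion constant `D` (um^2/ms), with a two-stage voltage-clamp
#' protocol: all cells are first clamped to a hyperpolarised potential,
#' then a fraction of them is clamped to a depolarised potential, and the
#' resulting pulse of activation propagates along the free cells.
#'
#' @param n_cells Number of cells (>= 10).
#' @param D Inter-cell diffusion constant, um^2/ms (default 6e4).
#' @param cell_length Cell length, um, used to convert the per-cell
#'   velocity to um/ms (default 70; a declared convention).
#' @param pre_mV,pulse_mV Clamp potentials, mV (defaults -80 and +23; the
#'   holding potential sits just below the models' diastolic range, the
#'   role a -64 mV hold plays for nodal cells with a -60 mV MDP).
#' @param clamp_fraction Fraction of cells clamped to `pulse_mV`.
#' @param t_pre Duration of the hyperpolarising clamp, ms.
#' @param t_pulse Duration of the depolarising pulse, ms.
#' @param dt Time step, ms (default 0.01).
#' @return An object of class `cable_config`.
#' @export
cable_config <- function(n_cells = 50, D = 6e4, cell_length = 70,
                         pre_mV = -80, pulse_mV = 23, clamp_fraction = 0.2,
                         t_pre = 300, t_pulse = 15, dt = 0.01) {
  stopifnot(n_cells >= 10, D >= 0, cell_length > 0,
            clamp_fraction > 0, clamp_fraction < 1, dt > 0)
  structure(list(n_cells = as.integer(n_cells), D = D,
                 cell_length = cell_length, pre_mV = pre_mV,
                 pulse_mV = pulse_mV, clamp_fraction = clamp_fraction,
                 t_pre = t_pre, t_pulse = t_pulse, dt = dt),
            class = "cable_config")
}

#' Simulate the 1D cable
#'
#' Finite-difference diffusion coupling with the clamp protocol of
#' [cable_config()].  Gates follow a Rush-Larsen update; membrane potential
#' and Ca pools a forward-Euler step.
#'
#' @param model A SAN [cell_model()] (control or variant).
#' @param config A [cable_config()].
#' @param post_release Free-running time after the pulse, ms (default 80).
#' @param record_dt Output sampling, ms.
#' @return List of class `propagation_result_1d`: `time`, `V` (matrix,
#'   cells in columns), `activation` (ms, `NA` for clamped cells or cells
#'   never activated), `config`.
#' @export
simulate_cable <- function(model, config, post_release = 80,
                           record_dt = 0.5) {
  stopifnot(inherits(model, "cell_model"), model$family == "san",
            inherits(config, "cable_config"))
  coupling <- config$D / config$cell_length^2   # 1/ms
  duration <- config$t_pre + config$t_pulse + post_release
  out <- cable_sim_cpp(model$params, model$state0, config$n_cells,
                       coupling, config$dt, duration,
                       config$pre_mV, config$t_pre, config$pulse_mV,
                       config$t_pre + config$t_pulse,
                       config$clamp_fraction, record_dt, vthresh = -20)
  structure(list(time = out$time, V = out$V, activation = out$activation,
                 n_clamped = out$n_clamped, config = config),
            class = "propagation_result_1d")
}

#' Conduction velocity from activation times
#'
#' Least-squares slope of cell position against activation time over the
#' interior of the chain (clamped cells and boundary zones excluded).
#'
#' @param result A `propagation_result_1d`, or a list with `activation`
#'   (ms) and a `cable_config` in `config`.
#' @param fit_cells Optional integer vector of cell indices to fit;
#'   default: all activated free cells excluding `boundary` cells at each
#'   end of the fitted region.
#' @param boundary Number of cells trimmed at each end (default 3).
#' @return Velocity in um/ms, with attributes `cells_per_ms` and
#'   `r_squared`.  Negative for a wave travelling toward lower indices.
#' @export
conduction_velocity <- function(result, fit_cells = NULL, boundary = 3) {
  act <- result$activation
  cfg <- result$config
  if (is.null(fit_cells)) {
    ok <- which(!is.na(act))
    if (length(ok) > 2 * boundary + 5)
      ok <- ok[(boundary + 1):(length(ok) - boundary)]
    fit_cells <- ok
  }
  if (length(fit_cells) < 5)
    stop("need at least 5 activation times to fit a velocity")
  t <- act[fit_cells]
  if (any(is.na(t))) stop("activation times missing inside the fit window")
  ord <- order(fit_cells)
  dt <- diff(t[ord])
  if (any(dt > 0) && any(dt < 0))
    stop("mixed propagation directions in fit window; ",
         "cannot assign a single velocity")
  fit <- lm(pos ~ t, data = data.frame(pos = fit_cells, t = t))
  cells_per_ms <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(cells_per_ms * cfg$cell_length,
            cells_per_ms = cells_per_ms,
            r_squared = r2)
}

# ---------------------------------------------------------------------------
# 2D monodomain SAN-in-atrium
# ---------------------------------------------------------------------------

#' Two-dimensional monodomain tissue configuration
#'
#' A square domain of atrial tissue with a central sinoatrial-node disc.
#' Anisotropic diffusion (fiber along x).  The desk-scale default grid is
#' 76 x 76 nodes (0.04 cm spacing) on a 3 x 3 cm domain; `preset = "full"`
#' selects the fine 151 x 151 / 0.02 cm grid.
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @param domain_cm Domain side length, cm.
#' @param nodes Grid nodes per side (overrides preset).
#' @param Dx_cm2_s,Dy_cm2_s Diffusion along/across the fiber, cm^2/s
#'   (defaults 1.2 and 0.25).
#' @param san_radius_cm SAN disc radius, cm (0.27 / 0.34 / 0.40 are the
#'   radii studied).
#' @param transition_cm Width of the transitional zone inside the disc
#'   over which pacemaker drive conductances ramp down toward the atrial
#'   edge (default: the full disc radius, i.e. a centre-to-periphery
#'   gradient), emulating the gradual change of cell properties between
#'   node centre and atrium.
#' @param edge_drive Drive-conductance fraction at the outermost SAN ring
#'   (default 0.25).
#' @param dt Diffusion time step, ms (default 0.125).
#' @param n_sub Reaction substeps per diffusion step (default 2).
#' @return An object of class `tissue_config`.
#' @export
tissue_config <- function(preset = c("desk", "full"), domain_cm = 3,
                          nodes = NULL, Dx_cm2_s = 1.2, Dy_cm2_s = 0.25,
                          san_radius_cm = 0.34, transition_cm = NULL,
                          edge_drive = 0.25, dt = 0.125, n_sub = 2) {
  preset <- match.arg(preset)
  if (is.null(nodes)) nodes <- if (preset == "full") 151L else 76L
  if (is.null(transition_cm)) transition_cm <- san_radius_cm
  dx <- domain_cm / (nodes - 1)
  stopifnot(san_radius_cm < domain_cm / 2, dt > 0, n_sub >= 1,
            transition_cm >= 0, edge_drive > 0, edge_drive <= 1)
  structure(list(preset = preset, domain_cm = domain_cm,
                 nodes = as.integer(nodes), dx = dx,
                 Dx = Dx_cm2_s / 1000, Dy = Dy_cm2_s / 1000,  # cm^2/ms
                 san_radius_cm = san_radius_cm,
                 transition_cm = transition_cm, edge_drive = edge_drive,
                 dt = dt, n_sub = as.integer(n_sub)),
            class = "tissue_config")
}

#' Default atrial membrane parameters
#'
#' Parameters of the three-variable phenomenological atrial AP model used
#' for the tissue surrounding the SAN disc, on the physical mV scale
#' (resting potential `V0`, AP amplitude `Vamp`).  The resting potential
#' and the fast-inward time constant `taud` place the SAN-atrium
#' source-sink balance at the operating point of the study design: control
#' tissue conducts 1:1 at every disc radius studied, while the
#' silencing and exit-block margins lie within reach of calibrated
#' variant effects.
#'
#' @return Named numeric vector in the atrial parameter layout.
#' @export
atrial_params <- function() {
  p <- c(V0 = -86, Vamp = 100, uc = 0.13, uv = 0.04, taud = 0.297,
         tauv1m = 19.6, tauv2m = 1250, tauvp = 3.33,
         tauwm = 41, tauwp = 870, tau0 = 12.5, taur = 33,
         tausi = 29, kk = 10, ucsi = 0.85)
  p[as.character(atrial_param_names_cpp())]
}

#' Simulate the 2D monodomain SAN-in-atrium tissue
#'
#' Operator-split monodomain: per-node reaction (full pacemaker model
#' inside the SAN disc, three-variable atrial model outside) followed by an
#' anisotropic finite-difference diffusion step with no-flux boundaries.
#' Membrane potential is recorded at six probe sites along the fiber
#' direction from the disc centre to the domain border.
#'
#' @param san_model A SAN [cell_model()] (control or variant).
#' @param config A [tissue_config()].
#' @param duration Simulated time, ms.
#' @param atrial Atrial parameter vector (default [atrial_params()]).
#' @param record_dt Probe sampling interval, ms (default 1).
#' @return List of class `propagation_result_2d`: `time`, `probes` (matrix,
#'   one column per probe; column 1 at the disc centre, last at the domain
#'   border), `probe_xy` (node coordinates), `n_san`, `config`.
#' @export
simulate_tissue_2d <- function(san_model, config, duration,
                               atrial = atrial_params(), record_dt = 1) {
  stopifnot(inherits(san_model, "cell_model"), san_model$family == "san",
            inherits(config, "tissue_config"))
  n <- config$nodes
  centre <- (n + 1) / 2
  xy <- (seq_len(n) - centre) * config$dx
  dist <- outer(xy, xy, function(x, y) sqrt(x^2 + y^2))
  depth <- config$san_radius_cm - dist          # cm inside the disc edge
  weight <- matrix(0, n, n)
  inside <- depth >= 0
  if (config$transition_cm > 0) {
    weight[inside] <- config$edge_drive + (1 - config$edge_drive) *
      pmin(1, depth[inside] / config$transition_cm)
  } else {
    weight[inside] <- 1
  }
  ctr <- as.integer(round(centre))
  probe_i <- unique(as.integer(round(seq(ctr, n - 1, length.out = 6))))
  probes <- cbind(probe_i, rep(ctr, length(probe_i)))
  out <- tissue2d_sim_cpp(san_model$params, san_model$state0, atrial,
                          weight, config$dx, config$Dx, config$Dy,
                          config$dt, config$n_sub, duration,
                          probes, record_dt, diffusion_only = FALSE)
  colnames(out$probes) <- sprintf("probe%d", seq_len(ncol(out$probes)))
  structure(list(time = out$time, probes = out$probes, probe_xy = probes,
                 n_san = out$n_san, config = config),
            class = "propagation_result_2d")
}

#' Detect sinoatrial exit block and beat-to-beat intervals
#'
#' An exit-block event is a SAN cycle with no atrial activation within the
#' causality window.  SAN cycles are upward -20 mV crossings at the disc
#' centre probe (electrotonic load flattens the nodal AP, so the cycle
#' threshold sits below the single-cell one); atrial activations are
#' upward -40 mV crossings at the distal probe.  Beat-to-beat intervals
#' are measured at the distal (atrial) probe.
#'
#' @param result A `propagation_result_2d`, or `NULL` when `san_times` and
#'   `atrial_times` are given directly.
#' @param window Causality window, ms (default 150).
#' @param settle Initial transient excluded, ms (default 500).
#' @param san_times,atrial_times Optional precomputed event series (ms);
#'   bypasses trace analysis.
#' @return List of class `exit_block_report`: `san_cycles`, `atrial_beats`,
#'   `events` (times of blocked SAN cycles), `n_blocked`, `intervals`
#'   (beat-to-beat, ms), `terminal_pause` (time from the last atrial beat
#'   to the end of the recording, ms; `NA` without a trace), and
#'   `silenced` (no SAN cycles after settling).
#' @export
detect_exit_block <- function(result = NULL, window = 150, settle = 500,
                              san_times = NULL, atrial_times = NULL) {
  if (is.null(san_times)) {
    stopifnot(inherits(result, "propagation_result_2d"))
    tt <- result$time
    sel <- tt >= settle
    san_times <- upward_crossings(tt[sel], result$probes[sel, 1], -20, 50)
    np <- ncol(result$probes)
    atrial_times <- upward_crossings(tt[sel], result$probes[sel, np], -40, 50)
  }
  silenced <- length(san_times) == 0
  # a SAN cycle too close to the end of the recording cannot be judged
  if (!is.null(result))
    san_times <- san_times[san_times <= max(result$time) - window]
  events <- numeric(0)
  for (ts in san_times) {
    hit <- any(atrial_times >= ts & atrial_times <= ts + window)
    if (!hit) events <- c(events, ts)
  }
  pause <- if (!is.null(result) && length(atrial_times))
    max(result$time) - max(atrial_times) else NA_real_
  structure(list(san_cycles = san_times, atrial_beats = atrial_times,
                 events = events, n_blocked = length(events),
                 intervals = diff(atrial_times), terminal_pause = pause,
                 silenced = silenced),
            class = "exit_block_report")
}

#' @export
print.exit_block_report <- function(x, ...) {
  cat(sprintf(
    "<exit_block_report> %d SAN cycles, %d atrial beats, %d blocked%s\n",
    length(x$san_cycles), length(x$atrial_beats), x$n_blocked,
    if (x$silenced) " [SILENCED]" else ""))
  invisible(x)
}
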