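#' Run configuration
#'
#' Bundles every setting of an end-to-end analysis: which models to run,
#' where the variant table comes from (a file or the seeded generator),
#' which epsilon scalings to evaluate, condition tolerances, protocol
#' ranges, calibration resolution, and the output directory.  The resolved
#' configuration is written into every run directory.
#'
#' @param neuron_model,san_model Model ids (see [model_registry()]).
#' @param variant_table Path to a variant TSV/JSON, or `NULL` to use the
#'   generator.
#' @param n_variants,seed Generator settings (used when `variant_table` is
#'   `NULL`).
#' @param epsilon Epsilon scalings to evaluate (default `c(-1/2, -1/4, 1/4,
#'   1/2)`).
#' @param freq_tol,peak_tol_mV,width_tol,amp_tol Condition tolerances (see
#'   [condition_set()]).
#' @param fi_amplitudes Neuron f-I amplitudes, nA.
#' @param fi_duration Neuron stimulus duration for f-I and calibration, ms.
#' @param mean_rate_range Amplitude range for the mean-rate summary, nA.
#' @param san_record,san_settle SAN recording/settling, ms.
#' @param calib_step,calib_tol Calibration scan step and bisection
#'   tolerance.
#' @param outdir Output directory (`NULL`: no files written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(neuron_model = "neuron-reduced",
                       san_model = "san-mouse",
                       variant_table = NULL,
                       n_variants = 30, seed = 1,
                       epsilon = c(-1/2, -1/4, 1/4, 1/2),
                       freq_tol = 0.25, peak_tol_mV = 10,
                       width_tol = 0.25, amp_tol = 0.20,
                       fi_amplitudes = seq(0.35, 1.4, by = 0.15),
                       fi_duration = 700,
                       mean_rate_range = c(0.35, 1.4),
                       san_record = 5000, san_settle = 1500,
                       calib_step = 0.2, calib_tol = 0.02,
                       outdir = NULL) {
  structure(list(neuron_model = neuron_model, san_model = san_model,
                 variant_table = variant_table,
                 n_variants = as.integer(n_variants), seed = as.integer(seed),
                 epsilon = epsilon, freq_tol = freq_tol,
                 peak_tol_mV = peak_tol_mV, width_tol = width_tol,
                 amp_tol = amp_tol, fi_amplitudes = fi_amplitudes,
                 fi_duration = fi_duration,
                 mean_rate_range = mean_rate_range,
                 san_record = san_record, san_settle = san_settle,
                 calib_step = calib_step, calib_tol = calib_tol,
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are errors, guarding against silent typos in tolerance
#' names.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Per-variant outcomes across cell types
#'
#' For every variant: calibrates the downscaling threshold `c` separately
#' for the neuron and the SAN model, applies the variant at each epsilon,
#' and measures the neuron mean firing rate (over the configured amplitude
#' range) and the SAN pacemaking rate.  Variants not applicable to a model
#' get `NA` there.
#'
#' @param effects Named list of [variant_effect()]s.
#' @param config A [run_config()].
#' @param progress Print one line per variant (default `TRUE`).
#' @return Data frame (one row per variant x epsilon) with columns
#'   `variant`, `gene`, `class`, `epsilon`, `c_neuron`, `c_san`,
#'   `neuron_rate`, `san_rate`, `neuron_change`, `san_change`.
#' @export
variant_outcomes <- function(effects, config = run_config(),
                             progress = TRUE) {
  neuron <- build_model(config$neuron_model)
  san <- build_model(config$san_model)
  cs_n <- condition_set("neuron", freq_tol = config$freq_tol,
                        peak_tol_mV = config$peak_tol_mV,
                        width_tol = config$width_tol,
                        amp_tol = config$amp_tol,
                        stim_duration = config$fi_duration)
  cs_s <- condition_set("san", freq_tol = config$freq_tol,
                        width_tol = config$width_tol,
                        amp_tol = config$amp_tol,
                        record = config$san_record,
                        settle = config$san_settle)
  ref_n <- condition_reference(neuron, cs_n)
  ref_s <- condition_reference(san, cs_s)

  fi0 <- fi_curve(neuron, config$fi_amplitudes,
                  duration = config$fi_duration)
  rate0_n <- mean_rate(fi0, config$mean_rate_range)
  rate0_s <- ref_s$measure$frequency

  rows <- list()
  for (eff in effects) {
    cal_n <- tryCatch(
      find_threshold_c(neuron, eff, cs_n, reference = ref_n,
                       step = config$calib_step, tol = config$calib_tol),
      error = function(e) NULL)
    cal_s <- tryCatch(
      find_threshold_c(san, eff, cs_s, reference = ref_s,
                       step = config$calib_step, tol = config$calib_tol),
      error = function(e) NULL)
    for (eps in config$epsilon) {
      nr <- sr <- NA_real_
      if (!is.null(cal_n)) {
        if (cal_n$c == 0) {
          nr <- rate0_n   # epsilon * 0 is exactly the control model
        } else {
          vn <- apply_variant(neuron, eff, epsilon = eps, c_scale = cal_n$c)
          fi <- tryCatch(fi_curve(vn, config$fi_amplitudes,
                                  duration = config$fi_duration),
                         error = function(e) NULL)
          if (!is.null(fi)) nr <- mean_rate(fi, config$mean_rate_range)
        }
      }
      if (!is.null(cal_s)) {
        if (cal_s$c == 0) {
          sr <- rate0_s
        } else {
          vs <- apply_variant(san, eff, epsilon = eps, c_scale = cal_s$c)
          pf <- tryCatch(
            pacemaking_frequency(vs, record = config$san_record,
                                 settle = config$san_settle),
            error = function(e) NULL)
          if (!is.null(pf)) sr <- pf$frequency
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant = eff$id, gene = eff$gene, class = gene_class(eff$gene),
        epsilon = eps,
        c_neuron = if (is.null(cal_n)) NA_real_ else cal_n$c,
        c_san = if (is.null(cal_s)) NA_real_ else cal_s$c,
        neuron_rate = nr, san_rate = sr,
        neuron_change = (nr - rate0_n) / rate0_n,
        san_change = (sr - rate0_s) / rate0_s,
        stringsAsFactors = FALSE)
    }
    if (progress)
      message(sprintf("variant %s (%s): c_neuron=%.3f c_san=%.3f",
                      eff$id, eff$gene,
                      if (is.null(cal_n)) NA else cal_n$c,
                      if (is.null(cal_s)) NA else cal_s$c))
  }
  out <- do.call(rbind, rows)
  attr(out, "control_rates") <- c(neuron = rate0_n, san = rate0_s)
  out
}

#' Cross-model correlation and classification analysis
#'
#' The aggregation stage: per gene class, the Pearson correlation between
#' neuron mean rate and SAN pacemaking rate across variants at one
#' epsilon, plus the analogous / non-analogous / neutral classification.
#'
#' @param outcomes Output of [variant_outcomes()].
#' @param epsilon Which epsilon slice to analyse (default -1/4).
#' @param dead_band Classification dead-band (see [classify_pleiotropy()]).
#' @return List with `correlations` (named vector per gene class),
#'   `classification` (per-variant), `summary` (contingency table), and
#'   the `epsilon` analysed.
#' @export
analyze_outcomes <- function(outcomes, epsilon = -1/4, dead_band = 0.01) {
  sl <- outcomes[abs(outcomes$epsilon - epsilon) < 1e-9, , drop = FALSE]
  if (!nrow(sl)) stop("no rows at epsilon = ", epsilon)
  cors <- sapply(c("Na/HCN", "Ca/transporter"), function(cl) {
    cm <- tryCatch(
      correlation_matrix(sl, subset = cl,
                         model_cols = c("neuron_rate", "san_rate")),
      error = function(e) matrix(NA_real_, 2, 2))
    cm[1, 2]
  })
  cls <- classify_pleiotropy(sl$neuron_change, sl$san_change, dead_band)
  list(correlations = cors,
       classification = data.frame(variant = sl$variant, gene = sl$gene,
                                   class = sl$class, pleiotropy = cls,
                                   stringsAsFactors = FALSE),
       summary = pleiotropy_summary(sl, cls),
       epsilon = epsilon)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the variant table, calibrates every variant
#' against both cell models, measures outcomes at every epsilon, runs the
#' correlation/classification analysis, and (if `config$outdir` is set)
#' writes all artifacts with a manifest.
#'
#' @param config A [run_config()].
#' @param progress Verbose per-variant progress.
#' @return List with `effects`, `outcomes`, `analysis`, `config`, and
#'   `files` (written artifact paths, if any).
#' @export
run_pipeline <- function(config = run_config(), progress = TRUE) {
  effects <- if (is.null(config$variant_table)) {
    gen <- variant_generator_config(n = config$n_variants, seed = config$seed)
    generate_variant_table(gen)
  } else {
    read_variant_table(config$variant_table)
  }
  outcomes <- variant_outcomes(effects, config, progress = progress)
  analysis <- analyze_outcomes(outcomes,
                               epsilon = if (-0.25 %in% config$epsilon)
                                 -0.25 else config$epsilon[1])
  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    files <- .write_run_artifacts(config, effects, outcomes, analysis)
  }
  list(effects = effects, outcomes = outcomes, analysis = analysis,
       config = config, files = files)
}

.write_run_artifacts <- function(config, effects, outcomes, analysis) {
  od <- config$outdir
  paths <- c(
    config = file.path(od, "config.json"),
    variants = file.path(od, "variants.tsv"),
    outcomes = file.path(od, "outcomes.csv"),
    correlations = file.path(od, "correlations.csv"),
    classification = file.path(od, "classification.json"))
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  write_variant_table(effects, paths["variants"],
                      header = sprintf("pipeline run, seed %d", config$seed))
  con <- file(paths["outcomes"], "w")
  writeLines("# units: rates Hz; changes relative to control; epsilon, c dimensionless", con)
  write.table(outcomes, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  cors <- data.frame(class = names(analysis$correlations),
                     pearson_r = as.numeric(analysis$correlations))
  con <- file(paths["correlations"], "w")
  writeLines(sprintf("# Pearson r between neuron mean rate and SAN rate at epsilon=%g",
                     analysis$epsilon), con)
  write.table(cors, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(epsilon = analysis$epsilon,
         counts = as.data.frame(analysis$summary),
         classification = analysis$classification),
    paths["classification"], dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  manifest <- data.frame(artifact = names(paths),
                         file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  mpath <- file.path(od, "manifest.json")
  jsonlite::write_json(manifest, mpath, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  c(paths, manifest = mpath)
}
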