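#' Synthetic variant-table generator configuration
#'
#' The generator emulates the *structure* of a curated functional-genomics
#' variant table: each variant belongs to one of seven genes, maps to the
#' channel parameters that gene encodes, and carries one to four parameter
#' modifications with mixed signs and magnitudes.  The default mixture
#' reproduces the published class proportions (80 Ca/transporter : 14
#' Na/HCN among 94 variants); within each class, genes are drawn with
#' weights reflecting the relative prevalence of functional studies per
#' gene.  Effect sizes are declared emulation parameters: voltage offsets
#' uniform on ±10 mV, multiplicative factors log-uniform on [1/3, 3].
#'
#' @param n Number of variants.
#' @param seed Integer seed; fully determines the output.
#' @param ca_fraction Fraction of variants in the Ca/transporter class
#'   (default 80/94; class counts are assigned deterministically by
#'   rounding).
#' @param delta_range Additive offset range, mV.
#' @param log_gamma_range Range of `log(gamma)` (default `log(1/3)` to
#'   `log(3)`).
#' @param max_mods Maximum modifications per variant (uniform on
#'   1..`max_mods`; genes with a single target always get 1).
#' @return An object of class `variant_generator_config`.
#' @export
variant_generator_config <- function(n = 94, seed = 1,
                                     ca_fraction = 80 / 94,
                                     delta_range = c(-10, 10),
                                     log_gamma_range = log(c(1 / 3, 3)),
                                     max_mods = 4) {
  stopifnot(n >= 1, is.finite(seed), ca_fraction >= 0, ca_fraction <= 1,
            all(is.finite(delta_range)), all(is.finite(log_gamma_range)),
            max_mods >= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 ca_fraction = ca_fraction, delta_range = delta_range,
                 log_gamma_range = log_gamma_range,
                 max_mods = as.integer(max_mods)),
            class = "variant_generator_config")
}

# gene -> parameter targets (canonical paths + modification mode).
# `density` targets model the current-density change that essentially every
# curated variant carries (truncations, knockouts, splice variants,
# trafficking mutants); `kinetic` targets are optional additional gating
# alterations.  CACNB2 encodes a beta-subunit that partners both L-type
# alpha-subunits, so its density effect touches Cav1.2 and Cav1.3 alike.
.gene_targets <- function() {
  list(
    SCN1A = list(
      density = list(c("Na.gbar", "mult")),
      kinetic = list(c("Na.act.vhalf", "add"), c("Na.inact.vhalf", "add"),
                     c("Na.act.slope", "mult"), c("Na.inact.tau", "mult"))),
    HCN1 = list(
      density = list(c("HCN.gbar", "mult")),
      kinetic = list(c("HCN.act.vhalf", "add"), c("HCN.act.slope", "mult"),
                     c("HCN.act.tau", "mult"))),
    CACNA1C = list(
      density = list(c("CaL12.gbar", "mult")),
      kinetic = list(c("CaL12.act.vhalf", "add"),
                     c("CaL12.inact.vhalf", "add"),
                     c("CaL12.act.slope", "mult"),
                     c("CaL12.inact.tau", "mult"))),
    CACNA1D = list(
      density = list(c("CaL13.gbar", "mult")),
      kinetic = list(c("CaL13.act.vhalf", "add"),
                     c("CaL13.inact.vhalf", "add"),
                     c("CaL13.act.slope", "mult"),
                     c("CaL13.inact.tau", "mult"))),
    CACNB2 = list(
      density = list(c("CaL12.gbar", "mult"), c("CaL13.gbar", "mult")),
      kinetic = list(c("CaL12.inact.tau", "mult"),
                     c("CaL12.act.vhalf", "add"))),
    CACNA1I = list(
      density = list(c("CaT.gbar", "mult")),
      kinetic = list(c("CaT.act.vhalf", "add"), c("CaT.inact.vhalf", "add"),
                     c("CaT.act.slope", "mult"), c("CaT.inact.tau", "mult"))),
    ATP2A2 = list(
      density = list(c("SERCA.P_up", "mult")),
      kinetic = list()))
}

# within-class gene weights (relative prevalence of functional studies)
.gene_weights <- function() {
  list("Ca/transporter" = c(CACNA1C = 6, CACNA1D = 6, CACNB2 = 4,
                            CACNA1I = 2, ATP2A2 = 4),
       "Na/HCN" = c(SCN1A = 6, HCN1 = 3))
}

#' Generate a synthetic variant-effect table
#'
#' Draws `config$n` variants: class counts are fixed by `ca_fraction`
#' (rounded), genes drawn within class by study-prevalence weights, and
#' each variant receives 1..`max_mods` distinct parameter modifications
#' with uniform offsets / log-uniform factors.  The same seed always
#' produces the identical table.
#'
#' @param config A [variant_generator_config()].
#' @return Named list of [variant_effect()] objects.
#' @examples
#' effs <- generate_variant_table(variant_generator_config(n = 5, seed = 42))
#' names(effs)
#' @export
generate_variant_table <- function(config = variant_generator_config()) {
  stopifnot(inherits(config, "variant_generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  n_ca <- round(config$n * config$ca_fraction)
  classes <- c(rep("Ca/transporter", n_ca), rep("Na/HCN", config$n - n_ca))
  weights <- .gene_weights()
  targets <- .gene_targets()

  draw_mod <- function(tg, value = NULL) {
    if (tg[2] == "add") {
      parameter_modification(tg[1], "add",
                             stats::runif(1, config$delta_range[1],
                                          config$delta_range[2]))
    } else {
      if (is.null(value))
        value <- exp(stats::runif(1, config$log_gamma_range[1],
                                  config$log_gamma_range[2]))
      parameter_modification(tg[1], "mult", value)
    }
  }

  out <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    w <- weights[[classes[i]]]
    gene <- sample(names(w), 1, prob = w)
    tg <- targets[[gene]]
    # every variant carries its density effect (one shared factor across
    # the gene's subunit targets), plus 0..(max_mods-1) kinetic changes
    dens_val <- exp(stats::runif(1, config$log_gamma_range[1],
                                 config$log_gamma_range[2]))
    mods <- lapply(tg$density, draw_mod, value = dens_val)
    n_kin <- min(sample.int(config$max_mods, 1) - 1L, length(tg$kinetic))
    if (n_kin > 0) {
      picks <- sample.int(length(tg$kinetic), n_kin)
      mods <- c(mods, lapply(tg$kinetic[picks], draw_mod))
    }
    id <- sprintf("SV%03d", i)
    out[[i]] <- variant_effect(id, gene, mods,
                               source_note = "synthetic (seeded generator)")
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write a generated table with provenance header
#'
#' Writes the TSV format of [write_variant_table()] with the generator
#' configuration and seed embedded as comment lines.
#'
#' @param effects Output of [generate_variant_table()].
#' @param config The [variant_generator_config()] used.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_generated_table <- function(effects, config, path) {
  header <- c("synthetic variant-effect table",
              sprintf("generator: n=%d seed=%d ca_fraction=%.4f", config$n,
                      config$seed, config$ca_fraction),
              sprintf("delta ~ U(%g, %g) mV; log(gamma) ~ U(%g, %g)",
                      config$delta_range[1], config$delta_range[2],
                      config$log_gamma_range[1], config$log_gamma_range[2]))
  write_variant_table(effects, path, header = header)
}
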