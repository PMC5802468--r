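#' Cell model container
#'
#' A `cell_model` bundles a model family (its ODE right-hand side), a named
#' parameter vector in the family's canonical layout, an initial state, and
#' a provenance note.  Models are immutable values: variant application and
#' parameter edits always return a new model and never touch the control.
#'
#' @param name Human-readable model id (e.g. `"san-mouse"`).
#' @param family `"san"` (single-compartment pacemaker) or `"neuron"`
#'   (two-compartment pyramidal cell).
#' @param params Named numeric vector matching [model_parameter_layout()].
#' @param state0 Named numeric initial state matching [model_state_layout()].
#' @param provenance Character note on where the formulation comes from.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(name, family = c("san", "neuron"), params, state0,
                       provenance = "") {
  family <- match.arg(family)
  layout <- model_parameter_layout(family)
  slayout <- model_state_layout(family)
  if (!identical(names(params), layout))
    stop("parameter vector does not match the '", family, "' layout")
  if (!identical(names(state0), slayout))
    stop("state vector does not match the '", family, "' layout")
  if (any(!is.finite(params))) stop("non-finite model parameter")
  structure(list(name = name, family = family,
                 params = params, state0 = state0,
                 provenance = provenance),
            class = "cell_model")
}

#' Canonical parameter and state layouts
#'
#' The flat parameter vector consumed by the compiled right-hand sides.
#' Order is fixed per family; builders and serialisation rely on it.
#'
#' @param family `"san"` or `"neuron"`.
#' @return Character vector of names.
#' @export
model_parameter_layout <- function(family = c("san", "neuron")) {
  family <- match.arg(family)
  if (family == "san") san_param_names_cpp() else neuron_param_names_cpp()
}

#' @rdname model_parameter_layout
#' @export
model_state_layout <- function(family = c("san", "neuron")) {
  family <- match.arg(family)
  if (family == "san") san_state_names_cpp() else neuron_state_names_cpp()
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", x$name, "(family:", x$family, ")\n")
  cat("  parameters:", length(x$params), " states:", length(x$state0), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Canonical channel-level parameter paths ("<current>.<part>") mapped to flat
# parameter names, shared across families so that one variant table applies
# to both cell types.  NA marks a path with no counterpart in that family.
.path_table <- function(family) {
  if (family == "san") {
    c("Na.gbar" = "gNa", "Na.act.vhalf" = "vm", "Na.act.slope" = "km",
      "Na.act.tau" = "taum", "Na.inact.vhalf" = "vh",
      "Na.inact.slope" = "kh", "Na.inact.tau" = "tauh",
      "HCN.gbar" = "gf", "HCN.act.vhalf" = "vy", "HCN.act.slope" = "ky",
      "HCN.act.tau" = "tauy", "HCN.Erev" = "Ef",
      "CaL12.gbar" = "gCaL12", "CaL12.act.vhalf" = "vd12",
      "CaL12.act.slope" = "kd12", "CaL12.act.tau" = "taud12",
      "CaL12.inact.vhalf" = "vf12", "CaL12.inact.slope" = "kf12",
      "CaL12.inact.tau" = "tauf12",
      "CaL13.gbar" = "gCaL13", "CaL13.act.vhalf" = "vd13",
      "CaL13.act.slope" = "kd13", "CaL13.act.tau" = "taud13",
      "CaL13.inact.vhalf" = "vf13", "CaL13.inact.slope" = "kf13",
      "CaL13.inact.tau" = "tauf13",
      "CaT.gbar" = "gCaT", "CaT.act.vhalf" = "vdT",
      "CaT.act.slope" = "kdT", "CaT.act.tau" = "taudT",
      "CaT.inact.vhalf" = "vfT", "CaT.inact.slope" = "kfT",
      "CaT.inact.tau" = "taufT",
      "Kr.gbar" = "gKr", "Kr.act.vhalf" = "vpa", "Kr.act.slope" = "kpa",
      "Kr.act.tau" = "taupa",
      "SERCA.P_up" = "Pup")
  } else {
    c("Na.gbar" = "gNaT", "Na.act.vhalf" = "vm", "Na.act.slope" = "km",
      "Na.act.tau" = "taum", "Na.inact.vhalf" = "vh",
      "Na.inact.slope" = "kh", "Na.inact.tau" = "tauh",
      # HCN conductance is split across the compartments; a density change
      # scales both (handled as a multi-key path)
      "HCN.gbar" = "gH+gHd", "HCN.act.vhalf" = "vq", "HCN.act.slope" = "kq",
      "HCN.act.tau" = "tauq", "HCN.Erev" = "Eh",
      # the neuron's high-voltage-activated Ca current stands for the merged
      # L-type (Cav1.2 + Cav1.3) population
      "CaL12.gbar" = "gCaHVA", "CaL12.act.vhalf" = "vc",
      "CaL12.act.slope" = "kc", "CaL12.act.tau" = "tauc",
      "CaL12.inact.vhalf" = "vhc", "CaL12.inact.slope" = "khc",
      "CaL12.inact.tau" = "tauhc",
      "CaL13.gbar" = "gCaHVA", "CaL13.act.vhalf" = "vc",
      "CaL13.act.slope" = "kc", "CaL13.act.tau" = "tauc",
      "CaL13.inact.vhalf" = "vhc", "CaL13.inact.slope" = "khc",
      "CaL13.inact.tau" = "tauhc",
      "CaT.gbar" = "gCaLVA", "CaT.act.vhalf" = "vs",
      "CaT.act.slope" = "ks", "CaT.act.tau" = "taus",
      "CaT.inact.vhalf" = "vhs", "CaT.inact.slope" = "khs",
      "CaT.inact.tau" = "tauhs",
      "Kr.gbar" = NA, "Kr.act.vhalf" = NA, "Kr.act.slope" = NA,
      "Kr.act.tau" = NA,
      "SERCA.P_up" = "Pup")
  }
}

#' Resolve a channel-level parameter path
#'
#' Maps a canonical path such as `"CaL13.act.vhalf"` or `"SERCA.P_up"` to
#' the flat parameter name(s) of a given model, or to the flat name itself
#' if it is already one.  A path may resolve to several flat parameters
#' (e.g. a conductance split across compartments).  Paths with no
#' counterpart in the model's family return `NA`.
#'
#' @param model A [cell_model()].
#' @param path Character path.
#' @return Character vector of flat parameter names, or `NA_character_`
#'   if inapplicable.
#' @export
resolve_parameter_path <- function(model, path) {
  stopifnot(inherits(model, "cell_model"))
  if (path %in% names(model$params)) return(path)
  tab <- .path_table(model$family)
  if (path %in% names(tab)) {
    key <- unname(tab[[path]])
    if (is.na(key)) return(NA_character_)
    return(strsplit(key, "+", fixed = TRUE)[[1]])
  }
  NA_character_
}

#' Read or set one model parameter
#'
#' `model_parameter()` returns the value at a canonical path or flat name;
#' `set_model_parameter()` returns a **new** model with the value replaced.
#'
#' @param model A [cell_model()].
#' @param path Canonical path or flat parameter name.
#' @param value Replacement value.
#' @return The value, or a new `cell_model`.
#' @export
model_parameter <- function(model, path) {
  key <- resolve_parameter_path(model, path)
  if (anyNA(key)) stop("parameter path not applicable to this model: ", path)
  unname(model$params[[key[1]]])
}

#' @rdname model_parameter
#' @export
set_model_parameter <- function(model, path, value) {
  key <- resolve_parameter_path(model, path)
  if (anyNA(key)) stop("parameter path not applicable to this model: ", path)
  for (k in key) model$params[[k]] <- value
  model
}

#' Serialise model parameters to a flat text file
#'
#' Writes `name = value` lines (one parameter per line) so that control and
#' variant models can be diffed with standard text tools.
#'
#' @param model A [cell_model()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_parameters <- function(model, path) {
  lines <- c(sprintf("# model: %s (family: %s)", model$name, model$family),
             sprintf("# units: mV, ms, nA, uS, nF, mM"),
             sprintf("%s = %.12g", names(model$params), model$params))
  writeLines(lines, path)
  invisible(path)
}
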