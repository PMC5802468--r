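#' Parameter modifications and variant effects
#'
#' A `parameter_modification` is one additive or multiplicative change to
#' one model parameter, addressed by a canonical channel-level path (see
#' [resolve_parameter_path()]).  Additive offsets (`delta`, mV) are allowed
#' only for half-(in)activation voltages and reversal potentials;
#' multiplicative factors (`gamma`, dimensionless, > 0) only for slope
#' factors, time constants, conductances and pump rates.
#'
#' @param path Canonical parameter path, e.g. `"CaL13.act.vhalf"`.
#' @param mode `"add"` or `"mult"`.
#' @param value Offset in mV (`add`) or positive factor (`mult`).
#' @return An object of class `parameter_modification`.
#' @export
parameter_modification <- function(path, mode = c("add", "mult"), value) {
  mode <- match.arg(mode)
  if (!is.finite(value)) stop("modification value must be finite")
  additive_ok <- grepl("\\.(vhalf|Erev)$", path)
  if (mode == "add" && !additive_ok)
    stop("additive modifications are only valid for vhalf/Erev parameters: ",
         path)
  if (mode == "mult") {
    if (additive_ok)
      stop("multiplicative modifications are not valid for vhalf/Erev: ", path)
    if (value <= 0) stop("multiplicative factor must be > 0")
  }
  structure(list(path = path, mode = mode, value = value),
            class = "parameter_modification")
}

#' @rdname parameter_modification
#' @param id Variant identifier.
#' @param gene Gene symbol (e.g. `"CACNA1C"`).
#' @param modifications List of [parameter_modification()] objects.
#' @param source_note Free-text provenance.
#' @export
variant_effect <- function(id, gene, modifications, source_note = "") {
  stopifnot(is.list(modifications))
  for (m in modifications)
    if (!inherits(m, "parameter_modification"))
      stop("modifications must be parameter_modification objects")
  structure(list(id = id, gene = gene, modifications = modifications,
                 source_note = source_note),
            class = "variant_effect")
}

#' @export
print.variant_effect <- function(x, ...) {
  cat("<variant_effect>", x$id, "(", x$gene, "),",
      length(x$modifications), "modification(s)\n")
  for (m in x$modifications)
    cat(sprintf("  %-20s %s %+g\n", m$path,
                if (m$mode == "add") "delta" else "gamma x", m$value))
  invisible(x)
}

#' Scale one modification by a dimensionless factor
#'
#' Additive offsets scale linearly (`delta -> s * delta`); multiplicative
#' factors scale on the log scale (`gamma -> gamma^s`).  Negative `s`
#' reverses the direction of the change; `s = 0` gives the neutral element
#' (offset 0 / factor 1), and scaling by `a` then `b` equals scaling once
#' by `a + b`.
#'
#' @param mod A [parameter_modification()].
#' @param s Dimensionless scale (finite; may be negative).
#' @return A new `parameter_modification`.
#' @export
scale_modification <- function(mod, s) {
  stopifnot(inherits(mod, "parameter_modification"), is.finite(s))
  if (mod$mode == "add") {
    mod$value <- s * mod$value
  } else {
    if (mod$value <= 0) stop("invalid modification: gamma must be > 0")
    mod$value <- mod$value^s
  }
  mod
}

#' Apply a variant to a model
#'
#' Applies `effect`'s modifications, scaled by `s = epsilon * c`, to a copy
#' of `model`.  The control model is never modified.  A modification whose
#' path has no counterpart in the model's family makes the variant
#' inapplicable: an error by default, or (with `partial = TRUE`) the
#' modification is skipped with a warning.
#'
#' @param model A [cell_model()].
#' @param effect A [variant_effect()].
#' @param epsilon User-chosen scale (typically ±1/4 or ±1/2).
#' @param c_scale Calibrated downscaling threshold in `[0, 1]`.
#' @param partial Allow partial application (default `FALSE`).
#' @return A new `cell_model` with `(epsilon * c_scale)`-scaled effects.
#' @examples
#' ctrl <- build_san("mouse")
#' eff <- variant_effect("v1", "CACNA1D",
#'   list(parameter_modification("CaL13.gbar", "mult", 2)))
#' vm <- apply_variant(ctrl, eff, epsilon = 0.5, c_scale = 1)
#' model_parameter(vm, "CaL13.gbar") / model_parameter(ctrl, "CaL13.gbar")
#' @export
apply_variant <- function(model, effect, epsilon = 1, c_scale = 1,
                          partial = FALSE) {
  stopifnot(inherits(model, "cell_model"), inherits(effect, "variant_effect"))
  s <- epsilon * c_scale
  out <- model
  for (mod in effect$modifications) {
    key <- resolve_parameter_path(model, mod$path)
    if (anyNA(key)) {
      if (partial) {
        warning("skipping inapplicable modification ", mod$path,
                " for model ", model$name)
        next
      }
      stop("variant ", effect$id, " not applicable to model ", model$name,
           ": unresolvable path ", mod$path)
    }
    sm <- scale_modification(mod, s)
    for (k in key) {
      if (sm$mode == "add") {
        out$params[[k]] <- out$params[[k]] + sm$value
      } else {
        out$params[[k]] <- out$params[[k]] * sm$value
      }
    }
  }
  out$name <- paste0(model$name, "+", effect$id, "@", format(s, digits = 4))
  out
}

#' Is a variant applicable to a model?
#'
#' @inheritParams apply_variant
#' @return `TRUE` if every modification path resolves in the model family.
#' @export
variant_applicable <- function(model, effect) {
  all(vapply(effect$modifications,
             function(m) !anyNA(resolve_parameter_path(model, m$path)),
             logical(1)))
}

# ---------------------------------------------------------------------------
# Variant table I/O (TSV, one modification per line, and a JSON mirror)
# ---------------------------------------------------------------------------

#' Read and write variant-effect tables
#'
#' The TSV format has one modification per line with columns `variant_id`,
#' `gene`, `model_scope` (`neuron`/`san`/`both`), `target_path`, `mode`
#' (`add`/`mult`), `value`, `units`, `source`.  Lines starting with `#` are
#' comments.  A JSON mirror with identical field names is also supported.
#'
#' @param effects List of [variant_effect()] objects.
#' @param path File path (`.tsv`/`.txt` or `.json`).
#' @param scope Model scope written for all rows (default `"both"`).
#' @param header Optional comment lines (provenance) for the TSV.
#' @return `write_variant_table()`: the path, invisibly.
#'   `read_variant_table()`: a named list of `variant_effect`s.
#' @export
write_variant_table <- function(effects, path, scope = "both",
                                header = character()) {
  df <- .effects_to_df(effects, scope)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (h in header) writeLines(paste0("# ", h), con)
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  need <- c("variant_id", "gene", "target_path", "mode", "value")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$variant_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$variant_id == id, , drop = FALSE]
    mods <- lapply(seq_len(nrow(rows)), function(i)
      parameter_modification(rows$target_path[i], rows$mode[i],
                             as.numeric(rows$value[i])))
    variant_effect(id, rows$gene[1], mods,
                   source_note = if ("source" %in% names(rows))
                     rows$source[1] else "")
  })
  names(out) <- ids
  out
}

.effects_to_df <- function(effects, scope = "both") {
  rows <- lapply(effects, function(e) {
    data.frame(
      variant_id = e$id, gene = e$gene, model_scope = scope,
      target_path = vapply(e$modifications, `[[`, character(1), "path"),
      mode = vapply(e$modifications, `[[`, character(1), "mode"),
      value = vapply(e$modifications, `[[`, numeric(1), "value"),
      units = vapply(e$modifications, function(m)
        if (m$mode == "add") "mV" else "dimensionless", character(1)),
      source = e$source_note,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
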