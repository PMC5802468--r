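#' Gene class of a variant
#'
#' Maps gene symbols to the two analysis classes: Na/HCN (voltage-gated Na
#' channels and HCN channels) versus Ca/transporter (voltage-gated Ca
#' channel subunits and Ca-ATPases).
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector, `"Na/HCN"` or `"Ca/transporter"`.
#' @export
gene_class <- function(gene) {
  na_hcn <- c("SCN1A", "HCN1")
  ca <- c("CACNA1C", "CACNA1D", "CACNB2", "CACNA1I", "ATP2A2")
  out <- ifelse(gene %in% na_hcn, "Na/HCN",
                ifelse(gene %in% ca, "Ca/transporter", NA_character_))
  if (any(is.na(out)))
    stop("unknown gene symbol(s): ",
         paste(unique(gene[is.na(out)]), collapse = ", "))
  out
}

#' Cross-model correlation matrix of variant outcomes
#'
#' Pearson correlations between per-variant summary rates predicted by
#' different models, optionally restricted to one gene class.  Rows with a
#' missing value in any model column are dropped (inapplicable variants are
#' omitted, not partially used).
#'
#' @param table Data frame with columns `variant`, `gene`, `class`, and one
#'   numeric column per model.
#' @param subset Optional gene class (`"Na/HCN"` or `"Ca/transporter"`).
#' @param model_cols Model columns; default: all numeric columns except
#'   bookkeeping ones.
#' @return Symmetric correlation matrix with unit diagonal; entries for
#'   zero-variance columns are `NA` (flagged with a warning).
#' @export
correlation_matrix <- function(table, subset = NULL, model_cols = NULL) {
  if (!is.null(subset)) table <- table[table$class == subset, , drop = FALSE]
  if (is.null(model_cols))
    model_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("epsilon", "c"))
  m <- as.matrix(table[, model_cols, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    stop("need at least 3 complete variant rows after filtering, got ",
         nrow(m))
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning("zero variance in column(s): ",
            paste(model_cols[sds == 0], collapse = ", "),
            "; correlation undefined there")
  suppressWarnings(cor(m))
}

#' Classify the pleiotropy of a variant
#'
#' Compares the signed relative change a variant causes in neuronal firing
#' with the change in pacemaking: same sign outside the dead-band is
#' `"analogous"`, opposite sign `"non-analogous"`, and any change inside
#' the dead-band `"neutral"`.  The dead-band absorbs numerically tiny
#' changes that carry no reliable sign.
#'
#' @param neuron_change,san_change Signed relative changes vs control
#'   (vectorised).
#' @param dead_band Relative dead-band (default 0.01 = 1%).
#' @return Character vector of classifications.
#' @export
classify_pleiotropy <- function(neuron_change, san_change, dead_band = 0.01) {
  stopifnot(length(neuron_change) == length(san_change), dead_band >= 0)
  out <- character(length(neuron_change))
  small <- abs(neuron_change) <= dead_band | abs(san_change) <= dead_band
  same <- sign(neuron_change) == sign(san_change)
  out[small] <- "neutral"
  out[!small & same] <- "analogous"
  out[!small & !same] <- "non-analogous"
  out[is.na(neuron_change) | is.na(san_change)] <- NA_character_
  out
}

#' Summarise pleiotropy classifications
#'
#' Cross-tabulates classifications by gene class.
#'
#' @param table Outcome table with `class` column.
#' @param classification Vector from [classify_pleiotropy()].
#' @return A contingency table.
#' @export
pleiotropy_summary <- function(table, classification) {
  table(gene_class = table$class, pleiotropy = classification,
        useNA = "ifany")
}
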