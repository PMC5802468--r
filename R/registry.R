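#' Model registry
#'
#' Lists the model builders shipped with the package, with a provenance
#' note per entry.  `build_model()` constructs a control model by id;
#' control builds are deterministic.
#'
#' @return `model_registry()`: data frame with columns `id`, `family`,
#'   `provenance`.
#' @export
model_registry <- function() {
  data.frame(
    id = c("neuron-reduced", "san-mouse", "san-rabbit"),
    family = c("neuron", "san", "san"),
    provenance = c(
      build_neuron()$provenance,
      "reduced mouse-type sinoatrial pacemaker (HCN4-like I_f: V1/2 -106.8 mV, slope 16.3 mV, Erev -24 mV)",
      "reduced rabbit-type sinoatrial pacemaker (HCN1/4-mix I_f: V1/2 -52.5 mV, slope 9.0 mV, Erev -4 mV)"),
    stringsAsFactors = FALSE)
}

#' @rdname model_registry
#' @param id One of `"neuron-reduced"`, `"san-mouse"`, `"san-rabbit"`.
#' @export
build_model <- function(id) {
  switch(id,
         "neuron-reduced" = build_neuron(),
         "san-mouse" = build_san("mouse"),
         "san-rabbit" = build_san("rabbit"),
         stop("unknown model id: ", id))
}
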