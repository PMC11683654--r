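#' Published reference benchmark scores
#'
#' Reference precision/recall/F1 tables for rare-disease entity and relation
#' extraction on the RareDis2023 benchmark, as reported for a fine-tuned
#' BioClinicalBERT baseline (`BioClinicalBERT`), a plain instruction-driven
#' GPT-4 baseline (`BaseLLM`) and the ontology-enhanced pipeline this
#' package implements (`OntologyEnhanced`), together with the prompt
#' ablation table (entity/relation F1 with knowledge, exemplars or the
#' notice block removed). These are inputs for reporting arithmetic — for
#' example reproducing each overall F1 as the mean of its entity and
#' relation F1 via [overall_score()], or recall improvements as differences
#' — not outputs of this package.
#'
#' @param table `"main"` (per-type scores) or `"ablation"`.
#' @return A data.frame.
#' @export
reference_scores <- function(table = c("main", "ablation")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_scores_", table, ".csv"),
                      package = "raremine")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
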