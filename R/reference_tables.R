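#' Benchmark closed-loop contingency tables
#'
#' Published benchmark 2x2 tables for the closed-loop evaluation statistics:
#' five subjects' movement-type decoding tables (cells a..d = grasp/grasp,
#' grasp/open, open/grasp, open/open by instruction x inferred type) and five
#' onset-detection section tables (a..d = TP, FP, FN, TN). Useful as fixed
#' inputs for [contingency_accuracy()] and [fisher_exact_one_tailed()].
#'
#' @return Data frame with columns `table` (`"type"` or `"onset"`),
#'   `subject`, and cells `a`, `b`, `c`, `d`.
#' @export
reference_closed_loop_tables <- function() {
  path <- system.file("extdata", "closed_loop_reference_tables.csv",
                      package = "smfdecode", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
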