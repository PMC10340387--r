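#' The bundled SIG-33 reference coefficient table
#'
#' The published 33-miRNA head-and-neck SCC tumor signature used as a worked
#' example for the reduction rules: per-precursor elastic-net coefficient,
#' the tumor-vs-control direction call observed in each of the three
#' evaluation datasets (surrogate tissue, rare-tumor cells, exosomes), and
#' the recorded strong-expression flag (mean read share above 0.1 percent of
#' total reads in the rare tumor or rare control group).
#'
#' @return data.frame with columns `feature`, `beta`, `dir_surrogate`,
#'   `dir_rare`, `dir_exo`, `abundant`, ordered by decreasing |beta|.
#' @export
sig33_reference <- function() {
  path <- system.file("extdata", "sig33_reference.tsv", package = "surrosig",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
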