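#' The shipped 18-pair pancreatic-cancer signature
#'
#' An 18-pair immune-related gene-pair signature for pancreatic cancer with
#' its lasso-Cox coefficients, shipped as plain text under
#' `inst/extdata/signature_18_irgp.tsv`. It is the package's worked example
#' of a frozen signature: [risk_score()] applied with it needs nothing but a
#' raw expression matrix containing its 31 genes, on any platform. A sample
#' in which every first gene outranks its partner scores the coefficient sum
#' (1.093); one where only ERAP2 exceeds SSTR1 scores 0.739.
#'
#' @return An `irgp_signature` `data.frame` (`gene_a`, `gene_b`,
#'   `coefficient`).
#' @export
example_signature <- function() {
  read_signature(system.file("extdata", "signature_18_irgp.tsv",
                             package = "irgpair", mustWork = TRUE))
}
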