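#' Published candidate-region summary for the pepper anthocyanin cross
#'
#' The reported candidate regions of the worked example this package is
#' validated against: seven Euclidean-distance regions (chromosomes 05 and
#' 10) and three SNP-index regions (chromosome 10), with the reported
#' interval sizes, gene counts and SNP counts. Shipped as a plain TSV under
#' `extdata`; used by the tests and the acceptance script to reproduce the
#' reported arithmetic (interval sizes, totals, intersection).
#'
#' @param method Optional filter: `"ed"` or `"snp_index"`.
#' @return Tibble `method`, `chrom`, `start`, `end`, `size_mb`, `n_genes`,
#'   `n_snps`.
#' @export
published_regions <- function(method = NULL) {
  path <- system.file("extdata", "pepper_candidate_regions.tsv",
                      package = "bsamapr", mustWork = TRUE)
  x <- tibble::as_tibble(utils::read.delim(path))
  if (!is.null(method)) x <- x[x$method == method, , drop = FALSE]
  x
}
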