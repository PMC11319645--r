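# Catalog of the public CRISPR/Cas9 on-target efficiency datasets this
# package is designed around, with the curation bookkeeping figures the
# leakage filter is expected to reproduce on the real data. The datasets
# themselves are external downloads; only their metadata ships here.

#' Catalog of supported public efficiency datasets
#'
#' One row per public dataset: the three per-enzyme high-throughput guide
#' libraries (WT / eSpCas9 / SpCas9-HF1), the CRISPRon high-throughput set,
#' twelve functional screens, and one endogenous T-cell dataset, with their
#' published sizes. The per-enzyme sizes are internally consistent with the
#' reported combined count (see [reported_curation_counts()]), which the
#' acceptance checks verify.
#'
#' @return a tibble with columns `dataset`, `type`, `species`, `cell_type`,
#'   `size`.
#' @export
dataset_catalog <- function() {
  path <- system.file("extdata", "dataset_catalog.tsv", package = "crisprtl")
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Published curation bookkeeping counts
#'
#' The combined sample counts before and after the Hamming-distance leakage
#' filter against the target datasets, as published for the real source
#' datasets. Reproducing the post-filter counts requires downloading the
#' source and target datasets; the identity between the per-enzyme sizes in
#' [dataset_catalog()] and the combined pre-filter count is checkable
#' offline.
#'
#' @return named list of integer counts.
#' @export
reported_curation_counts <- function() {
  path <- system.file("extdata", "curation_counts.json", package = "crisprtl")
  lapply(jsonlite::read_json(path), as.integer)
}
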