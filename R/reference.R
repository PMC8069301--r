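#' Published common-driver reference table
#'
#' The 42-row driver table of the OSA/dementia reference study, shipped as
#' a plain-TSV fixture: driver gene, supporting dementia genes, supporting
#' OSA genes, olfactory/GPCR pathway flags and the reported permutation
#' p-value. Useful for arithmetic cross-checks (the reported p-values are
#' integer multiples of 1/361000, i.e. of 1/(100 * 3610 candidates)) and
#' for exercising report-shaped downstream code.
#'
#' @return Data frame with columns `gene`, `dementia_genes`, `osa_genes`,
#'   `olfactory` (0/1), `gpcr` (0/1), `p_value`.
#' @export
reference_driver_table <- function() {
  path <- system.file("extdata", "table2_common_drivers.tsv",
                      package = "nicd", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer", "integer", "numeric"))
}

#' Reference disease queries (dementia umbrella and OSA)
#'
#' The CUI lists used by the reference study: 14 dementia-related and 3
#' obstructive-sleep-apnea-related UMLS CUIs, shipped as plain text under
#' `extdata`. Combine with externally downloaded DisGeNET dump files and a
#' PCNet edge-list export to rerun the full reproduction profile.
#'
#' @return List with [disease_query()] elements `dementia` and `osa`.
#' @export
reference_disease_queries <- function() {
  list(
    dementia = read_disease_query(
      system.file("extdata", "dementia_cuis.txt", package = "nicd",
                  mustWork = TRUE), label = "dementia"),
    osa = read_disease_query(
      system.file("extdata", "osa_cuis.txt", package = "nicd",
                  mustWork = TRUE), label = "OSA")
  )
}
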