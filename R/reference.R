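#' Published reference table of maturating connections
#'
#' The 12 connections of an 11-network preterm connectome (a family of
#' 55 edge-wise paired tests) reported as significantly maturating between
#' 33 and 40 weeks gestational age, with their published raw and
#' FDR-adjusted p-values and edge-weight differences. The raw p-values
#' serve as inputs when validating the multiplicity arithmetic: feeding
#' them to [bh_fdr()] with `m = 55` (the 43 unprinted tests assumed
#' larger) reproduces the published adjusted values at the upper ranks.
#'
#' @return A tibble: `region_1`, `region_2`, `p_fdr_published`, `p_raw`,
#'   `ewd`.
#' @export
reference_coi_table <- function() {
  path <- system.file("extdata", "reference_coi_table.tsv",
                      package = "accordnet", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
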