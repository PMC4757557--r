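## Loaders for the bundled APL cohort tables (inst/extdata): the published
## per-stage filter counts, the recurrence-enriched gene frequencies and
## their functional categories. They serve as worked-example inputs and as
## regression anchors for the statistics.

.extdata <- function(name) {
  system.file("extdata", name, package = "CoMutNet", mustWork = TRUE)
}

#' Bundled APL cohort tables
#'
#' `aplFilterAudit()` returns the published five-patient discovery-cohort
#' filter cascade as a [FilterAudit-class]. `aplEnrichedGenes()` returns
#' the 15 recurrence-enriched genes of the 25-patient extended cohort with
#' cohort and 1000 Genomes carrier frequencies (fractions), plus the
#' reference as a [ReferenceFrequencies-class]. `aplCategoryMap()` returns
#' their functional-category labels. `aplCandidateGenes()` names the eight
#' prioritized candidate genes. `aplCohortMatrix()` reconstructs a binary
#' 25-patient mutation matrix whose per-gene carrier counts equal
#' `round(frequency * 25)` — sufficient for every carrier-count-based
#' statistic (which patients carry which gene is not published).
#'
#' @return see above; `aplEnrichedGenes()` gives a list with `table`
#'   (data.frame gene, cohort_freq, ref_freq), `ref`
#'   (ReferenceFrequencies) and `n` (cohort size, 25).
#' @export
aplFilterAudit <- function() {
  readFilterAudit(.extdata("apl_filter_audit.tsv"), mode = "matched")
}

#' @rdname aplFilterAudit
#' @export
aplEnrichedGenes <- function() {
  df <- .readTsv(.extdata("apl_reference_frequencies.tsv"))
  tab <- data.frame(gene = df$gene,
                    cohort_freq = df$cohort_frequency_pct / 100,
                    ref_freq = df$reference_frequency_pct / 100)
  list(table = tab,
       ref = readReferenceFrequencies(.extdata(
         "apl_reference_frequencies.tsv")),
       n = 25L)
}

#' @rdname aplFilterAudit
#' @export
aplCategoryMap <- function() {
  readCategoryMap(.extdata("apl_category_map.tsv"),
                  vocabulary = categoryVocabulary())
}

#' @rdname aplFilterAudit
#' @export
aplCandidateGenes <- function() {
  c("STAG2", "U2AF1", "SMC1A", "USP9X", "IKZF1", "LYN", "MYCBP2", "PTPN11")
}

#' @rdname aplFilterAudit
#' @export
aplCohortMatrix <- function() {
  x <- aplEnrichedGenes()
  k <- round(x$table$cohort_freq * x$n)
  m <- matrix(0L, nrow = x$n, ncol = nrow(x$table),
              dimnames = list(sprintf("APL%02d", seq_len(x$n)),
                              x$table$gene))
  for (j in seq_along(k))
    if (k[j] > 0) m[seq_len(k[j]), j] <- 1L
  MutationMatrix(m)
}
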