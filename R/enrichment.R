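#' Upper binomial tail P(X >= k)
#'
#' Exact one-sided binomial tail for X ~ Binomial(n, p0), computed through
#' the survival form of the cumulative distribution (numerically stable for
#' small p0 and large n; agrees with direct summation to at least 10
#' significant digits).
#'
#' @param k observed count (vectorized).
#' @param n number of trials.
#' @param p0 success probability under the null; `p0 = 0` is rejected —
#'   callers must apply the zero-frequency floor first.
#' @return P(X >= k).
#' @examples
#' binomialTail(11, 25, 0.03)
#' @export
binomialTail <- function(k, n, p0) {
  if (any(p0 <= 0) || any(p0 > 1))
    stop("p0 must lie in (0, 1]; floor zero frequencies before testing")
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Zero-frequency floor for reference carrier frequencies
#'
#' Genes absent from the reference cohort (frequency 0) would give a
#' degenerate p-value of 0 under the binomial model; the default floor
#' replaces 0 by `1 / (nRef + 1)`, the smallest frequency not excluded by
#' observing zero carriers among `nRef` individuals.
#'
#' @param f0 reference frequency (fraction).
#' @param nRef reference cohort size.
#' @param floor optional explicit floor value; default `1 / (nRef + 1)`.
#' @return max(f0, floor), vectorized.
#' @export
floorFrequency <- function(f0, nRef, floor = NULL) {
  if (is.null(floor)) floor <- 1 / (nRef + 1)
  pmax(ifelse(is.na(f0), 0, f0), floor)
}

#' Test one gene's cohort carrier frequency against the reference
#'
#' One-sided exact binomial test of the number of mutated patients against
#' the (zero-floored) reference carrier frequency: p = P(X >= k) for
#' X ~ Binomial(n, f0_used).
#'
#' @param gene gene symbol (must be present in `matrix`).
#' @param matrix a [MutationMatrix-class].
#' @param ref a [ReferenceFrequencies-class]; genes missing from it are
#'   treated as frequency 0 (then floored).
#' @param alpha significance level.
#' @param floor explicit zero-frequency floor (default `1/(nRef+1)`).
#' @return one-row data.frame: gene, n, k, cohort_freq, f0, f0_used,
#'   p_value, significant.
#' @export
enrichmentTest <- function(gene, matrix, ref, alpha = 0.05, floor = NULL) {
  if (!gene %in% geneNames(matrix))
    stop("gene '", gene, "' absent from the mutation matrix")
  n <- length(patientNames(matrix))
  k <- unname(carrierCounts(matrix)[gene])
  f0 <- unname(refFreq(ref)[gene])
  if (is.null(f0) || length(f0) == 0L) f0 <- NA_real_
  f0_used <- floorFrequency(f0, refCohortSize(ref), floor)
  p <- binomialTail(k, n, f0_used)
  data.frame(gene = gene, n = n, k = k, cohort_freq = k / n,
             f0 = ifelse(is.na(f0), 0, f0), f0_used = f0_used,
             p_value = p, significant = p <= alpha)
}

#' Screen every gene of a cohort for recurrence enrichment
#'
#' Runs [enrichmentTest()] (or a two-proportion Fisher variant) for every
#' gene of the matrix against the reference frequencies and returns the
#' full table sorted by p-value, then gene symbol. Raw-p thresholding at
#' `alpha` is the default decision rule (matching how small-cohort screens
#' are conventionally reported); Benjamini-Hochberg q-values are
#' always reported alongside.
#'
#' @param matrix a [MutationMatrix-class].
#' @param ref a [ReferenceFrequencies-class].
#' @param alpha significance level on the raw p-value.
#' @param method `"binomial"` (exact one-sided tail) or `"fisher"`
#'   (one-sided two-proportion Fisher exact test of k/n vs K/nRef, for
#'   sensitivity analysis).
#' @param floor explicit zero-frequency floor.
#' @return data.frame: gene, n, k, cohort_freq, f0, f0_used, p_value,
#'   q_value, significant.
#' @export
screenCohort <- function(matrix, ref, alpha = 0.05,
                         method = c("binomial", "fisher"), floor = NULL) {
  method <- match.arg(method)
  genes <- geneNames(matrix)
  n <- length(patientNames(matrix))
  k <- unname(carrierCounts(matrix)[genes])
  f0 <- refFreq(ref)[genes]
  f0[is.na(f0)] <- 0
  nRef <- refCohortSize(ref)
  f0_used <- floorFrequency(f0, nRef, floor)
  p <- if (method == "binomial") {
    binomialTail(k, n, f0_used)
  } else {
    K <- round(f0_used * nRef)
    vapply(seq_along(genes), function(i) {
      tab <- matrix(c(k[i], n - k[i], K[i], nRef - K[i]), nrow = 2L)
      fisher.test(tab, alternative = "greater")$p.value
    }, numeric(1))
  }
  res <- data.frame(gene = genes, n = n, k = k, cohort_freq = k / n,
                    f0 = unname(f0), f0_used = f0_used, p_value = p,
                    q_value = p.adjust(p, method = "BH"),
                    significant = p <= alpha)
  res <- res[order(res$p_value, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Write a Table-2-style enrichment screen as TSV
#'
#' Columns: gene, cohort frequency (%), reference frequency (%), p, q,
#' significant.
#'
#' @param screen result of [screenCohort()].
#' @param path output TSV.
#' @param meta optional `#` metadata lines.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(screen, path, meta = character()) {
  df <- data.frame(gene = screen$gene,
                   cohort_frequency_pct = 100 * screen$cohort_freq,
                   reference_frequency_pct = 100 * screen$f0,
                   p_value = screen$p_value,
                   q_value = screen$q_value,
                   significant = screen$significant)
  .writeTsv(df, path, meta)
  invisible(path)
}
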