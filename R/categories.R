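#' Default functional-category vocabulary
#'
#' The category labels used to group mutated genes by biological function
#' in the bundled APL fixtures.
#'
#' @return character vector of labels.
#' @export
categoryVocabulary <- function() {
  c("ubiquitination", "spliceosome", "cohesin complex", "signaling",
    "metabolism", "transmembrane protein", "protein kinase",
    "tyrosine-protein kinase", "transcription factor/regulator",
    "other cell functions")
}

#' Patient-by-category incidence from a mutation matrix
#'
#' Entry (patient, category) is 1 iff the patient carries a mutation in at
#' least one gene labelled with that category. Multi-label genes contribute
#' to each of their categories. Matrix genes absent from the map are
#' assigned `unmapped_label` with a warning.
#'
#' @param matrix a [MutationMatrix-class].
#' @param cmap a [categoryMap()].
#' @param unmapped_label label given to unmapped genes.
#' @return binary patients-by-categories matrix.
#' @export
assignCategories <- function(matrix, cmap,
                             unmapped_label = "other cell functions") {
  if (length(cmap) == 0L) stop("empty category map")
  X <- incidenceMatrix(matrix)
  genes <- colnames(X)
  unmapped <- setdiff(genes, names(cmap))
  if (length(unmapped)) {
    warning("genes without category, assigned '", unmapped_label, "': ",
            paste(unmapped, collapse = ", "))
    cmap <- c(cmap, setNames(as.list(rep(unmapped_label, length(unmapped))),
                             unmapped))
  }
  cats <- sort(unique(unlist(cmap[genes])))
  M <- matrix(0L, nrow = length(cats), ncol = length(genes),
              dimnames = list(cats, genes))
  for (g in genes)
    M[cmap[[g]], g] <- 1L
  out <- (X %*% t(M)) > 0L
  mode(out) <- "integer"
  out
}

#' Per-category gene counts under a map, restricted to a gene universe
#' @noRd
.categoryGeneCounts <- function(cmap, genes) {
  tab <- table(unlist(cmap[intersect(genes, names(cmap))]))
  setNames(as.integer(tab), names(tab))
}

#' Category mutation-burden excess test
#'
#' Tests whether a functional category accumulates more mutation hit-events
#' than its gene-count share predicts. A hit-event is one (patient, gene)
#' mutated pair; multi-label genes contribute one event per label. Under
#' the null model, events fall into categories proportionally to the number
#' of genes per category; each category is tested with a one-sided binomial
#' margin test. A patient-preserving gene-label permutation null is
#' available instead (it accounts for the multi-label inflation).
#'
#' @param matrix a [MutationMatrix-class].
#' @param cmap a [categoryMap()].
#' @param alpha significance level.
#' @param null `"binomial"` (gene-count-share margin test) or
#'   `"permutation"` (gene-label shuffle).
#' @param n_perm permutation count for the permutation null.
#' @param seed RNG seed for the permutation null.
#' @param unmapped_label label for unmapped genes.
#' @return data.frame per category: gene_count, mutated_samples,
#'   burden_ratio (mutated samples per gene), events, expected_events,
#'   p_value, excess.
#' @export
categoryExcess <- function(matrix, cmap, alpha = 0.05,
                           null = c("binomial", "permutation"),
                           n_perm = 1000, seed = 1L,
                           unmapped_label = "other cell functions") {
  null <- match.arg(null)
  X <- incidenceMatrix(matrix)
  genes <- colnames(X)
  unmapped <- setdiff(genes, names(cmap))
  if (length(unmapped))
    cmap <- c(cmap, setNames(as.list(rep(unmapped_label, length(unmapped))),
                             unmapped))
  gene_counts <- .categoryGeneCounts(cmap, genes)
  cats <- names(gene_counts)
  carrier <- colSums(X)                      # events per gene
  events <- vapply(cats, function(cc) {
    in_cat <- vapply(genes, function(g) cc %in% cmap[[g]], logical(1))
    sum(carrier[in_cat])
  }, numeric(1))
  total_events <- sum(events)
  share <- gene_counts / sum(gene_counts)
  expected <- total_events * share
  catm <- suppressWarnings(assignCategories(matrix, cmap, unmapped_label))
  mutated_samples <- setNames(integer(length(cats)), cats)
  ms <- colSums(catm)
  mutated_samples[names(ms)] <- ms
  if (null == "binomial") {
    p <- vapply(cats, function(cc) {
      if (share[cc] >= 1) 1 else
        binomialTail(events[cc], total_events, share[cc])
    }, numeric(1))
  } else {
    set.seed(seed)
    exceed <- setNames(numeric(length(cats)), cats)
    glabels <- genes
    for (r in seq_len(n_perm)) {
      perm <- setNames(cmap[sample(glabels)], glabels)
      ev <- vapply(cats, function(cc) {
        in_cat <- vapply(glabels, function(g) cc %in% perm[[g]], logical(1))
        sum(carrier[in_cat])
      }, numeric(1))
      exceed <- exceed + (ev >= events[cats])
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  data.frame(category = cats, gene_count = unname(gene_counts[cats]),
             mutated_samples = unname(mutated_samples[cats]),
             burden_ratio = unname(mutated_samples[cats] /
                                     gene_counts[cats]),
             events = unname(events[cats]),
             expected_events = unname(expected[cats]),
             p_value = unname(p), excess = unname(p <= alpha))
}

#' Compare per-category mutation rates against a reference population
#'
#' Two-proportion tests (without continuity correction) in both one-sided
#' directions; each category is labelled `more_mutated`, `less_mutated` or
#' `indistinguishable` at level `alpha`. Categories missing from the
#' reference are skipped with a warning.
#'
#' @param cohort_rates named numeric: fraction of cohort patients mutated
#'   per category (e.g. `colMeans(assignCategories(...))`).
#' @param n cohort size.
#' @param reference_rates named numeric: same fractions in the reference
#'   population.
#' @param n_ref reference cohort size.
#' @param alpha significance level.
#' @return data.frame: category, cohort_rate, reference_rate, p_greater,
#'   p_less, label.
#' @export
categoryVsReference <- function(cohort_rates, n, reference_rates, n_ref,
                                alpha = 0.05) {
  cats <- names(cohort_rates)
  missing <- setdiff(cats, names(reference_rates))
  if (length(missing)) {
    warning("categories missing from reference, skipped: ",
            paste(missing, collapse = ", "))
    cats <- setdiff(cats, missing)
  }
  res <- lapply(cats, function(cc) {
    x1 <- round(cohort_rates[[cc]] * n)
    x2 <- round(reference_rates[[cc]] * n_ref)
    pg <- suppressWarnings(
      prop.test(c(x1, x2), c(n, n_ref), alternative = "greater",
                correct = FALSE)$p.value)
    pl <- suppressWarnings(
      prop.test(c(x1, x2), c(n, n_ref), alternative = "less",
                correct = FALSE)$p.value)
    data.frame(category = cc, cohort_rate = x1 / n,
               reference_rate = x2 / n_ref,
               p_greater = pg, p_less = pl,
               label = if (pg <= alpha) "more_mutated"
                       else if (pl <= alpha) "less_mutated"
                       else "indistinguishable")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Category-level co-mutation analysis
#'
#' Tests every pair of functional categories for co-occurring mutation
#' burden across patients, re-using the pairwise chi-square machinery of the
#' gene-level co-occurrence network on the patient-by-category matrix.
#'
#' @param category_matrix binary patients-by-categories matrix from
#'   [assignCategories()].
#' @param alpha significance level.
#' @param method `"chi2"` or `"fisher"`.
#' @return data.frame of significant category pairs: category1, category2,
#'   n_xy (patients mutated in both), expected, statistic, p_value,
#'   direction.
#' @export
categoryComutation <- function(category_matrix, alpha = 0.05,
                               method = c("chi2", "fisher")) {
  method <- match.arg(method)
  if (ncol(category_matrix) < 2L)
    stop("need at least two categories")
  tests <- .allPairTests(category_matrix, method)
  sig <- tests[tests$p_value <= alpha, , drop = FALSE]
  sig <- sig[order(sig$p_value, sig$gene1, sig$gene2), , drop = FALSE]
  out <- data.frame(category1 = sig$gene1, category2 = sig$gene2,
                    n_xy = sig$a, expected = sig$expected_a,
                    statistic = sig$statistic, p_value = sig$p_value,
                    direction = sig$direction)
  rownames(out) <- NULL
  out
}
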