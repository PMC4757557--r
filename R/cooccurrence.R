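#' 2x2 contingency table for a gene pair
#'
#' Cross-tabulates the binary mutation indicators of two genes over the
#' cohort: `a` patients mutated in both, `b` in gene1 only, `c` in gene2
#' only, `d` in neither.
#'
#' @param matrix a [MutationMatrix-class].
#' @param gene1,gene2 distinct gene symbols present in the matrix.
#' @return named integer vector c(a, b, c, d).
#' @export
pairContingency <- function(matrix, gene1, gene2) {
  if (gene1 == gene2) stop("gene1 and gene2 must differ")
  g <- geneNames(matrix)
  if (!all(c(gene1, gene2) %in% g))
    stop("gene(s) absent from matrix: ",
         paste(setdiff(c(gene1, gene2), g), collapse = ", "))
  m <- incidenceMatrix(matrix)
  x <- m[, gene1]
  y <- m[, gene2]
  c(a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L))
}

#' Co-occurrence test on a 2x2 table
#'
#' Default is the chi-square test of independence with 1 degree of freedom
#' and no continuity correction (equivalently `statistic = n * phi^2` where
#' phi is the phi coefficient); with any zero margin the statistic is 0 and
#' p = 1. The Fisher method returns the two-sided exact p with direction
#' from the observed-vs-expected joint count.
#'
#' @param table c(a, b, c, d) as from [pairContingency()].
#' @param method `"chi2"` or `"fisher"`.
#' @return list: statistic, p_value, expected_a, direction ("above" iff
#'   a > expected_a, else "below").
#' @export
cooccurrenceTest <- function(table, method = c("chi2", "fisher")) {
  method <- match.arg(method)
  if (any(table < 0)) stop("negative cell counts")
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  m1 <- a + b; m2 <- a + c
  expected_a <- m1 * m2 / n
  direction <- if (a > expected_a) "above" else "below"
  if (method == "chi2") {
    denom <- as.numeric(m1) * (c + d) * m2 * (b + d)
    if (denom == 0) {
      stat <- 0
      p <- 1
    } else {
      stat <- n * (as.numeric(a) * d - as.numeric(b) * c)^2 / denom
      p <- pchisq(stat, df = 1L, lower.tail = FALSE)
    }
  } else {
    ft <- fisher.test(matrix(c(a, c, b, d), nrow = 2L))
    stat <- unname(ft$estimate)
    p <- ft$p.value
  }
  list(statistic = unname(stat), p_value = unname(p),
       expected_a = unname(expected_a), direction = direction)
}

## Vectorized chi-square over all gene pairs of a binary matrix.
## Returns a data.frame of all tested pairs (both genes with >= 1 carrier).
.allPairTests <- function(X, method = "chi2") {
  n <- nrow(X)
  carriers <- colSums(X)
  keep <- carriers >= 1L
  X <- X[, keep, drop = FALSE]
  G <- ncol(X)
  if (G < 2L)
    return(data.frame(gene1 = character(), gene2 = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), expected_a = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      direction = character()))
  A <- crossprod(X)                 # joint carrier counts
  mcol <- colSums(X)
  iu <- which(upper.tri(A), arr.ind = TRUE)
  a <- A[iu]
  m1 <- mcol[iu[, 1L]]
  m2 <- mcol[iu[, 2L]]
  b <- m1 - a
  c_ <- m2 - a
  d <- n - a - b - c_
  expected_a <- m1 * m2 / n
  if (method == "chi2") {
    denom <- as.numeric(m1) * (n - m1) * m2 * (n - m2)
    stat <- ifelse(denom == 0, 0,
                   n * (as.numeric(a) * d - as.numeric(b) * c_)^2 / denom)
    p <- ifelse(denom == 0, 1, pchisq(stat, df = 1L, lower.tail = FALSE))
  } else {
    stat <- numeric(length(a))
    p <- numeric(length(a))
    for (i in seq_along(a)) {
      ft <- fisher.test(matrix(c(a[i], c_[i], b[i], d[i]), nrow = 2L))
      stat[i] <- unname(ft$estimate)
      p[i] <- ft$p.value
    }
  }
  g1 <- colnames(X)[iu[, 1L]]
  g2 <- colnames(X)[iu[, 2L]]
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  tmpn <- b[swap]; b[swap] <- c_[swap]; c_[swap] <- tmpn
  data.frame(gene1 = g1, gene2 = g2, a = a, b = b, c = c_, d = d,
             expected_a = expected_a, statistic = stat, p_value = p,
             direction = ifelse(a > expected_a, "above", "below"))
}

#' Build the significant co-occurrence network of a cohort
#'
#' Tests every unordered pair of genes mutated in at least one patient for
#' co-occurrence and keeps edges with `p <= alpha` (and, optionally, joint
#' carrier count `a >= min_pair_count`). Each kept edge carries its joint
#' count (the edge label in network renderings) and direction; the node
#' summary carries the significant-degree per gene (node size).
#'
#' @param matrix a [MutationMatrix-class] with at least one gene; with a
#'   single gene the edge set is empty.
#' @param alpha significance level on the raw p-value (no multiple-testing
#'   correction by default; BH q-values are reported in the edge table).
#' @param min_pair_count minimum joint carrier count for a kept edge.
#' @param method `"chi2"` (default, no continuity correction) or
#'   `"fisher"`.
#' @return a [CooccurrenceNetwork-class].
#' @export
buildCooccurrenceNetwork <- function(matrix, alpha = 0.05,
                                     min_pair_count = 0,
                                     method = c("chi2", "fisher")) {
  method <- match.arg(method)
  X <- incidenceMatrix(matrix)
  n <- nrow(X)
  tests <- .allPairTests(X, method)
  tests$q_value <- p.adjust(tests$p_value, method = "BH")
  sig <- tests[tests$p_value <= alpha & tests$a >= min_pair_count, ,
               drop = FALSE]
  sig <- sig[order(sig$p_value, sig$gene1, sig$gene2), , drop = FALSE]
  rownames(sig) <- NULL
  carriers <- colSums(X)
  degree <- setNames(integer(ncol(X)), colnames(X))
  if (nrow(sig)) {
    t1 <- table(sig$gene1)
    t2 <- table(sig$gene2)
    degree[names(t1)] <- degree[names(t1)] + as.integer(t1)
    degree[names(t2)] <- degree[names(t2)] + as.integer(t2)
  }
  nodes <- data.frame(gene = colnames(X), carriers = unname(carriers),
                      sig_degree = unname(degree))
  new("CooccurrenceNetwork", edges = sig, nodes = nodes, alpha = alpha,
      n = as.integer(n), method = method, tested = nrow(tests))
}

#' Export a co-occurrence network
#'
#' Writes the edge table as TSV and, optionally, SIF and GraphML renderings
#' (node attribute `sig_degree`, edge attributes joint count and
#' direction) for Cytoscape-style visualization.
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param tsv,sif,graphml output paths (each `NULL` to skip).
#' @param meta optional `#` metadata lines for the TSV.
#' @return invisible NULL.
#' @export
writeCooccurrenceNetwork <- function(net, tsv = NULL, sif = NULL,
                                     graphml = NULL, meta = character()) {
  e <- edgeTable(net)
  if (!is.null(tsv))
    .writeTsv(e[, c("gene1", "gene2", "a", "expected_a", "statistic",
                    "p_value", "q_value", "direction")], tsv, meta)
  if (!is.null(sif) && nrow(e))
    writeSif(e[, c("gene1", "gene2")], sif, relation = "co")
  if (!is.null(graphml))
    writeGraphML(e[, c("gene1", "gene2", "a", "p_value", "direction")],
                 graphml, nodes = nodeTable(net))
  invisible(NULL)
}
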