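# Builders for small in-code fixtures shared across test files.

# A variant call row with passing defaults; override any field.
makeCalls <- function(n = 1, ...) {
  cols <- list(
    chrom = "chr1",
    pos = seq_len(n) * 100L,
    ref = "A",
    alt = "G",
    gene = sprintf("G%02d", seq_len(n)),
    consequence = "nonsynonymous",
    depth = 200,
    alt_depth = 60,
    qual = 80,
    strand_bias = 0.1,
    known = FALSE,
    pop_freq = NA_real_,
    deleterious = TRUE
  )
  over <- list(...)
  for (nm in names(over)) cols[[nm]] <- over[[nm]]
  df <- data.frame(lapply(cols, rep_len, n), stringsAsFactors = FALSE)
  variantCalls(df)
}

# A binary patients x genes matrix from per-gene carrier index lists.
makeMatrix <- function(n_patients, carriers) {
  genes <- names(carriers)
  m <- matrix(0L, n_patients, length(genes),
              dimnames = list(sprintf("P%02d", seq_len(n_patients)), genes))
  for (g in genes) m[carriers[[g]], g] <- 1L
  MutationMatrix(m)
}

# Direct-summation oracle for the upper binomial tail, independent of
# stats::pbinom (log-space term-wise summation of the complement).
sumBinomTail <- function(k, n, p0) {
  if (k == 0) return(1)
  terms <- vapply(k:n, function(i) {
    exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0))
  }, numeric(1))
  sum(terms)
}

# Seed-component partition of a seed set over an igraph, computed
# independently of the package's MCN machinery: seeds are joined iff
# directly adjacent or sharing a neighbour (distance <= 2 through one
# intermediate); components via igraph on that seed graph.
oracleSeedPartition <- function(seeds, g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  idx <- match(seeds, rownames(A))
  k <- length(idx)
  B <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    B[i, j] <- A[idx[i], idx[j]] ||
      any(A[idx[i], ] & A[idx[j], ] & !(seq_len(nrow(A)) %in% idx))
  }
  gg <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  comp <- igraph::components(gg)$membership
  match(comp, unique(comp))
}
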