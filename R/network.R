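## Minimal connected network (MCN) over a protein-protein interactome:
## seed-induced edges plus single non-seed intermediates linking seed pairs
## that lack a direct interaction. The shared core works on a dense logical
## adjacency matrix so the resampling null can reuse it cheaply.

.adjacencyLogical <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE)) > 0
  diag(A) <- FALSE
  # canonical node order, so results are invariant to input edge order
  ord <- order(rownames(A))
  A[ord, ord, drop = FALSE]
}

## Core construction for seed indices over adjacency A.
## Returns qualifying intermediates, the seed-connectivity matrix B
## (TRUE iff two seeds are joined directly or through one intermediate),
## and per-seed degree within the MCN.
.mcnCore <- function(A, seedIdx) {
  n <- nrow(A)
  S <- sort(seedIdx)
  notS <- setdiff(seq_len(n), S)
  A_SS <- A[S, S, drop = FALSE]
  A_SV <- A[S, notS, drop = FALSE]
  cnt <- colSums(A_SV)
  cand <- which(cnt >= 2L)
  qual <- logical(length(cand))
  for (i in seq_along(cand)) {
    ns <- which(A_SV[, cand[i]])
    k <- length(ns)
    # qualifies iff some pair of its seed neighbours lacks a direct edge
    qual[i] <- sum(A_SS[ns, ns]) < k * (k - 1L)
  }
  Q <- cand[qual]
  B <- A_SS
  if (length(Q)) {
    via <- tcrossprod(A_SV[, Q, drop = FALSE] * 1L) > 0
    B <- B | via
  }
  diag(B) <- FALSE
  seedDegree <- rowSums(A_SS) +
    (if (length(Q)) rowSums(A_SV[, Q, drop = FALSE]) else 0)
  list(S = S, notS = notS, Q = Q, A_SS = A_SS, A_SV = A_SV, B = B,
       seedDegree = seedDegree)
}

## Connected-component membership of seeds from the seed-connectivity
## matrix; returns an integer vector (component ids, canonical order).
.seedComponentsFromB <- function(B) {
  nS <- nrow(B)
  comp <- seq_len(nS)
  # label propagation on a small matrix
  repeat {
    newcomp <- comp
    for (i in seq_len(nS)) {
      nb <- which(B[i, ])
      if (length(nb))
        newcomp[i] <- min(newcomp[i], newcomp[nb])
    }
    if (identical(newcomp, comp)) break
    comp <- newcomp
  }
  match(comp, unique(comp))
}

.statsFromCore <- function(core) {
  comp <- .seedComponentsFromB(core$B)
  sizes <- tabulate(comp)
  c(connected_seed_count = sum(sizes[comp] >= 2L),
    components = length(sizes),
    mean_seed_degree = mean(core$seedDegree))
}

#' Build the minimal connected network of a seed gene set
#'
#' The MCN contains every interactome edge between two seeds, plus every
#' non-seed node (with its seed-incident edges) that is adjacent to at
#' least two seeds of which some pair lacks a direct interaction — i.e.
#' single intermediates on length-2 paths between seeds. Optional
#' minimality pruning then removes as many intermediates as possible
#' without changing how the seeds partition into connected components
#' (exact minimum-cardinality search with lexicographic tie-break; above 20
#' intermediates per component a greedy most-redundant-first pass is used).
#'
#' @param seeds character vector of seed genes; genes absent from the
#'   interactome are reported in the result, not errors.
#' @param net an \pkg{igraph} undirected interactome (see
#'   [readInteractome()]).
#' @param prune apply minimality pruning of intermediates.
#' @return an [MCNResult-class].
#' @export
buildMCN <- function(seeds, net, prune = FALSE) {
  nodes <- igraph::V(net)$name
  seeds <- unique(seeds)
  unmatched <- setdiff(seeds, nodes)
  seeds_in <- sort(intersect(seeds, nodes))
  if (length(seeds_in) == 0L)
    stop("no seed maps to the interactome; unmatched: ",
         paste(unmatched, collapse = ", "))
  A <- .adjacencyLogical(net)
  idx <- match(seeds_in, rownames(A))
  core <- .mcnCore(A, idx)
  Qnames <- rownames(A)[core$notS[core$Q]]

  if (prune && length(core$Q)) {
    keepQ <- .pruneIntermediates(core, rownames(A))
    core$Q <- keepQ
    Qnames <- rownames(A)[core$notS[keepQ]]
    core$B <- core$A_SS
    if (length(keepQ)) {
      via <- tcrossprod(core$A_SV[, keepQ, drop = FALSE] * 1L) > 0
      core$B <- core$B | via
    }
    diag(core$B) <- FALSE
    core$seedDegree <- rowSums(core$A_SS) +
      (if (length(keepQ)) rowSums(core$A_SV[, keepQ, drop = FALSE]) else 0)
  }

  ss <- which(core$A_SS & upper.tri(core$A_SS), arr.ind = TRUE)
  e1 <- data.frame(from = seeds_in[ss[, 1L]], to = seeds_in[ss[, 2L]])
  si <- which(core$A_SV[, core$Q, drop = FALSE], arr.ind = TRUE)
  e2 <- if (nrow(si)) data.frame(from = seeds_in[si[, 1L]],
                                 to = Qnames[si[, 2L]])
        else data.frame(from = character(), to = character())
  edges <- rbind(e1, e2)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  comp <- .seedComponentsFromB(core$B)
  roles <- c(setNames(rep("seed", length(seeds_in)), seeds_in),
             setNames(rep("intermediate", length(Qnames)), Qnames))
  new("MCNResult", seeds = seeds_in, intermediates = sort(Qnames),
      edges = edges, roles = roles,
      seedComponents = setNames(as.integer(comp), seeds_in),
      unmatched = unmatched, pruned = prune)
}

## Minimum-cardinality intermediate subset preserving the seed-component
## partition. Subsets are scanned in increasing size, lexicographic node
## order, so the result is deterministic.
.pruneIntermediates <- function(core, nodeNames) {
  Q <- core$Q
  target <- .seedComponentsFromB(core$B)
  partitionOf <- function(sub) {
    B <- core$A_SS
    if (length(sub)) {
      via <- tcrossprod(core$A_SV[, sub, drop = FALSE] * 1L) > 0
      B <- B | via
    }
    diag(B) <- FALSE
    .seedComponentsFromB(B)
  }
  ord <- order(nodeNames[core$notS[Q]])
  Q <- Q[ord]                                     # lexicographic tie-break
  if (length(Q) > 20L) {
    # greedy most-redundant-first fallback for large candidate sets
    keep <- Q
    repeat {
      removable <- keep[vapply(seq_along(keep), function(i) {
        identical(partitionOf(keep[-i]), target)
      }, logical(1))]
      if (!length(removable)) break
      keep <- setdiff(keep, removable[1L])
    }
    return(keep)
  }
  for (size in 0:length(Q)) {
    subs <- if (size == 0L) list(integer(0))
            else asplit(combn(Q, size), 2L)
    for (s in subs) {
      if (identical(partitionOf(as.integer(s)), target))
        return(as.integer(s))
    }
  }
  Q
}

#' Connectivity statistics of an MCN
#'
#' @param result an [MCNResult-class].
#' @return named numeric: `connected_seed_count` (seeds in components of
#'   size >= 2), `components` (connected components among seeds),
#'   `mean_seed_degree` (mean seed degree within the MCN).
#' @export
setGeneric("mcnStatistics", function(result) standardGeneric("mcnStatistics"))

#' @rdname mcnStatistics
#' @export
setMethod("mcnStatistics", "MCNResult", function(result) {
  comp <- result@seedComponents
  sizes <- tabulate(comp)
  deg <- setNames(numeric(length(result@seeds)), result@seeds)
  if (nrow(result@edges)) {
    tab <- table(c(result@edges$from, result@edges$to))
    common <- intersect(names(tab), result@seeds)
    deg[common] <- as.numeric(tab[common])
  }
  c(connected_seed_count = sum(sizes[comp] >= 2L),
    components = length(sizes),
    mean_seed_degree = mean(deg))
})

## Degree bins used by the degree-matched null (powers of two).
.degreeBin <- function(deg) {
  cut(deg, breaks = c(-0.5, 0.5, 1.5, 3.5, 7.5, 15.5, 31.5, 63.5, Inf),
      labels = FALSE)
}

#' Sample the MCN connectivity null
#'
#' Draws `M` random seed sets from the interactome (uniformly without
#' replacement, or matched to the observed seeds' degree bins), runs each
#' through the MCN construction, and returns the three connectivity
#' statistics per draw. Fully reproducible given `rng_seed`.
#'
#' @param net interactome (igraph).
#' @param seed_size number of nodes per random seed set (for uniform mode),
#'   or ignored when `observed_seeds` is given in degree-matched mode.
#' @param M number of null draws.
#' @param mode `"uniform"` or `"degree_matched"`.
#' @param rng_seed integer RNG seed.
#' @param observed_seeds required for degree-matched mode: the observed
#'   seed genes whose degree-bin profile the null reproduces.
#' @return data.frame with M rows: connected_seed_count, components,
#'   mean_seed_degree; the seed is stored as attribute `"rng_seed"`.
#' @export
sampleNull <- function(net, seed_size, M = 99L,
                       mode = c("uniform", "degree_matched"),
                       rng_seed = 1L, observed_seeds = NULL) {
  mode <- match.arg(mode)
  stopifnot(M >= 1L)
  A <- .adjacencyLogical(net)
  n <- nrow(A)
  if (mode == "uniform" && seed_size > n)
    stop("seed_size exceeds interactome size")
  if (mode == "degree_matched") {
    if (is.null(observed_seeds))
      stop("degree_matched mode requires observed_seeds")
    deg <- rowSums(A)
    bins <- .degreeBin(deg)
    obs_idx <- match(intersect(observed_seeds, rownames(A)), rownames(A))
    need <- table(bins[obs_idx])
    avail <- table(bins)
    short <- names(need)[need > avail[names(need)]]
    if (length(short))
      stop("degree-matched sampling infeasible in degree bin(s): ",
           paste(short, collapse = ", "))
  }
  set.seed(rng_seed)
  out <- matrix(NA_real_, nrow = M, ncol = 3L,
                dimnames = list(NULL, c("connected_seed_count", "components",
                                        "mean_seed_degree")))
  for (i in seq_len(M)) {
    idx <- if (mode == "uniform") {
      sample.int(n, seed_size)
    } else {
      unlist(lapply(names(need), function(b) {
        pool <- which(bins == as.integer(b))
        pool[sample.int(length(pool), need[[b]])]
      }))
    }
    out[i, ] <- .statsFromCore(.mcnCore(A, idx))
  }
  res <- as.data.frame(out)
  attr(res, "rng_seed") <- rng_seed
  res
}

#' Add-one empirical p-value for an MCN statistic
#'
#' `(1 + #{null at least as connected as observed}) / (M + 1)`; for
#' `components`, fewer components means more connected, so the comparison
#' is reversed.
#'
#' @param observed observed statistic value.
#' @param null_values numeric vector of M null draws of the statistic.
#' @param statistic statistic name.
#' @return empirical p-value in `[1/(M+1), 1]`.
#' @export
mcnPValue <- function(observed, null_values,
                      statistic = c("connected_seed_count", "components",
                                    "mean_seed_degree")) {
  statistic <- match.arg(statistic)
  M <- length(null_values)
  exceed <- if (statistic == "components") sum(null_values <= observed)
            else sum(null_values >= observed)
  (1 + exceed) / (M + 1)
}

#' Test a seed set's MCN connectivity against the resampling null
#'
#' Builds the observed MCN, draws `M` random seed sets of the same size,
#' and summarizes the chosen connectivity statistic with an add-one
#' empirical p-value.
#'
#' @param seeds seed genes.
#' @param net interactome (igraph).
#' @param M null draws.
#' @param mode `"uniform"` (default) or `"degree_matched"`.
#' @param statistic connectivity statistic to test.
#' @param rng_seed integer RNG seed.
#' @return a [NullSummary-class].
#' @export
testMcnConnectivity <- function(seeds, net, M = 99L,
                                mode = c("uniform", "degree_matched"),
                                statistic = c("connected_seed_count",
                                              "components",
                                              "mean_seed_degree"),
                                rng_seed = 1L) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  mcn <- buildMCN(seeds, net)
  obs <- mcnStatistics(mcn)[[statistic]]
  nv <- sampleNull(net, seed_size = length(mcn@seeds), M = M, mode = mode,
                   rng_seed = rng_seed, observed_seeds = mcn@seeds)
  p <- mcnPValue(obs, nv[[statistic]], statistic)
  new("NullSummary", statistic = statistic, observed = obs,
      nullValues = nv[[statistic]], pValue = p,
      rngSeed = as.integer(rng_seed), mode = mode)
}

#' Prioritize candidate driver genes
#'
#' Intersects network connectivity with recurrence enrichment: candidates
#' are seed genes that lie in an MCN component of size >= 2 — provided the
#' MCN as a whole is more connected than the resampling null at level
#' `alpha` — and whose cohort carrier frequency is enrichment-significant.
#' Enrichment-significant genes absent from the interactome are reported
#' separately, not silently dropped.
#'
#' @param mcn an [MCNResult-class].
#' @param null_summary a [NullSummary-class] for the same seed set.
#' @param enrichment result of [screenCohort()].
#' @param alpha significance level applied to the MCN empirical p-value.
#' @param cooccurrence optional [CooccurrenceNetwork-class]; when supplied,
#'   candidates are annotated with their significant co-occurrence degree.
#' @return list with `candidates` (data.frame sorted by enrichment
#'   p-value: gene, k, n, cohort_freq, p_value, sig_degree) and
#'   `not_in_interactome` (enrichment-significant genes outside the
#'   interactome seed set).
#' @export
prioritizeCandidates <- function(mcn, null_summary, enrichment,
                                 alpha = 0.05, cooccurrence = NULL) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  comp <- mcn@seedComponents
  sizes <- tabulate(comp)
  connected <- names(comp)[sizes[comp] >= 2L]
  cand_genes <- if (nullPValue(null_summary) <= alpha && alpha > 0)
    intersect(connected, sig$gene) else character(0)
  candidates <- sig[sig$gene %in% cand_genes,
                    c("gene", "k", "n", "cohort_freq", "p_value"),
                    drop = FALSE]
  candidates <- candidates[order(candidates$p_value, candidates$gene), ,
                           drop = FALSE]
  candidates$sig_degree <- if (!is.null(cooccurrence)) {
    nd <- nodeTable(cooccurrence)
    nd$sig_degree[match(candidates$gene, nd$gene)]
  } else rep(NA_integer_, nrow(candidates))
  rownames(candidates) <- NULL
  not_in <- setdiff(sig$gene, c(mcn@seeds))
  list(candidates = candidates, not_in_interactome = not_in)
}

#' Export an MCN with role attributes
#'
#' SIF plus GraphML with a `role` node attribute (seed / intermediate), and
#' the null summary as a JSON report embedding the RNG seed and M.
#'
#' @param mcn an [MCNResult-class].
#' @param sif,graphml,json output paths (`NULL` to skip).
#' @param null_summary optional [NullSummary-class] for the JSON report.
#' @return invisible NULL.
#' @export
writeMCN <- function(mcn, sif = NULL, graphml = NULL, json = NULL,
                     null_summary = NULL) {
  if (!is.null(sif) && nrow(mcn@edges)) writeSif(mcn@edges, sif)
  if (!is.null(graphml)) {
    nodes <- data.frame(name = names(mcn@roles),
                        role = unname(mcn@roles))
    writeGraphML(mcn@edges, graphml, nodes = nodes)
  }
  if (!is.null(json)) {
    rep <- list(seeds = mcn@seeds, intermediates = mcn@intermediates,
                unmatched_seeds = mcn@unmatched,
                statistics = as.list(mcnStatistics(mcn)))
    if (!is.null(null_summary))
      rep$null <- list(statistic = null_summary@statistic,
                       observed = null_summary@observed,
                       M = length(null_summary@nullValues),
                       p_value = null_summary@pValue,
                       rng_seed = null_summary@rngSeed,
                       mode = null_summary@mode,
                       null_values = null_summary@nullValues)
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), json)
  }
  invisible(NULL)
}
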