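edgeGraph <- function(...) {
  igraph::simplify(igraph::graph_from_edgelist(
    matrix(c(...), ncol = 2, byrow = TRUE), directed = FALSE))
}

test_that("an intermediate connecting two unlinked seeds is retained", {
  g <- edgeGraph("PTPN11", "STAT1", "STAT1", "PML")
  mcn <- buildMCN(c("PTPN11", "PML"), g)
  expect_equal(mcn@intermediates, "STAT1")
  st <- mcnStatistics(mcn)
  expect_equal(unname(st["connected_seed_count"]), 2)
  expect_equal(unname(st["components"]), 1)
  expect_equal(mcn@roles[["STAT1"]], "intermediate")
})

test_that("a seed triangle is returned whole with no intermediates", {
  g <- edgeGraph("A", "B", "B", "C", "A", "C", "A", "X")
  mcn <- buildMCN(c("A", "B", "C"), g)
  expect_equal(nrow(mcn@edges), 3)
  expect_equal(length(mcn@intermediates), 0)
  # X touches only one seed: not an intermediate
  expect_false("X" %in% names(mcn@roles))
})

test_that("non-seed nodes qualify only when some seed pair lacks an edge", {
  # V adjacent to A and B which are themselves connected: no value added
  g <- edgeGraph("A", "B", "A", "V", "B", "V")
  mcn <- buildMCN(c("A", "B"), g)
  expect_equal(length(mcn@intermediates), 0)
  # remove the direct edge: V becomes the connector
  g2 <- edgeGraph("A", "V", "B", "V")
  mcn2 <- buildMCN(c("A", "B"), g2)
  expect_equal(mcn2@intermediates, "V")
})

test_that("every retained intermediate touches at least two seeds", {
  set.seed(17)
  for (r in 1:25) {
    g <- igraph::sample_gnp(30, 0.12)
    igraph::V(g)$name <- sprintf("N%02d", 1:30)
    seeds <- sample(igraph::V(g)$name, 6)
    mcn <- buildMCN(seeds, g)
    for (v in mcn@intermediates) {
      deg <- sum(mcn@edges$from == v | mcn@edges$to == v)
      expect_gte(deg, 2)
    }
    # every MCN edge touches at least one seed
    expect_true(all(mcn@edges$from %in% seeds | mcn@edges$to %in% seeds))
  }
})

test_that("seed components match an independent distance-2 partition", {
  set.seed(23)
  for (r in 1:25) {
    g <- igraph::sample_gnp(25, 0.08)
    igraph::V(g)$name <- sprintf("N%02d", 1:25)
    seeds <- sort(sample(igraph::V(g)$name, 5))
    mcn <- buildMCN(seeds, g)
    expect_equal(unname(mcn@seedComponents[seeds]),
                 oracleSeedPartition(seeds, g))
  }
})

test_that("MCN construction is invariant to node and edge input order", {
  set.seed(29)
  el <- matrix(sprintf("N%02d", sample(14, 40, TRUE)), ncol = 2)
  el <- el[el[, 1] != el[, 2], ]
  g1 <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  perm <- sample(nrow(el))
  g2 <- igraph::simplify(igraph::graph_from_edgelist(
    el[perm, c(2, 1)], directed = FALSE))
  seeds <- unique(el[1:4, 1])
  m1 <- buildMCN(seeds, g1, prune = TRUE)
  m2 <- buildMCN(seeds, g2, prune = TRUE)
  expect_equal(m1@edges, m2@edges)
  expect_equal(m1@intermediates, m2@intermediates)
  expect_equal(m1@seedComponents, m2@seedComponents)
})

test_that("unmapped seeds are reported; an empty intersection errors", {
  g <- edgeGraph("A", "B")
  mcn <- buildMCN(c("A", "B", "GHOST"), g)
  expect_equal(mcn@unmatched, "GHOST")
  expect_error(buildMCN(c("GHOST", "PHANTOM"), g), "GHOST")
})

test_that("pruning keeps the seed partition with a minimal connector set", {
  # D1 and D2 each connect the same seed pair; only one survives pruning
  g <- edgeGraph("A", "D1", "B", "D1", "A", "D2", "B", "D2")
  mcn <- buildMCN(c("A", "B"), g, prune = TRUE)
  expect_equal(mcn@intermediates, "D1")   # lexicographic tie-break
  expect_equal(unname(mcn@seedComponents), c(1L, 1L))
})

test_that("pruned connector sets are minimum-cardinality (exhaustive
           check on random small graphs)", {
  set.seed(41)
  for (r in 1:60) {
    n <- sample(8:12, 1)
    g <- igraph::sample_gnp(n, 0.25)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    seeds <- sort(sample(igraph::V(g)$name, sample(3:5, 1)))
    full <- buildMCN(seeds, g)
    pruned <- buildMCN(seeds, g, prune = TRUE)
    expect_equal(pruned@seedComponents, full@seedComponents)
    # exhaustive search over subsets of the unpruned intermediates
    Q <- full@intermediates
    target <- unname(full@seedComponents[seeds])
    best <- length(Q)
    if (length(Q)) {
      for (size in 0:(length(Q) - 1)) {
        combs <- utils::combn(Q, size, simplify = FALSE)
        hit <- FALSE
        for (s in combs) {
          sub <- igraph::induced_subgraph(
            g, union(seeds, s))
          if (identical(oracleSeedPartition(seeds, sub), target)) {
            best <- size; hit <- TRUE; break
          }
        }
        if (hit) break
      }
    }
    expect_equal(length(pruned@intermediates), best)
  }
})

test_that("statistics recompute identically from the edge list", {
  set.seed(53)
  for (r in 1:20) {
    g <- igraph::sample_gnp(40, 0.07)
    igraph::V(g)$name <- sprintf("N%02d", 1:40)
    seeds <- sample(igraph::V(g)$name, 8)
    mcn <- buildMCN(seeds, g)
    st <- mcnStatistics(mcn)
    # independent recount from the edge table
    deg <- vapply(mcn@seeds, function(s)
      sum(mcn@edges$from == s | mcn@edges$to == s), numeric(1))
    expect_equal(unname(st["mean_seed_degree"]), mean(deg))
    comp <- mcn@seedComponents
    expect_equal(unname(st["components"]), length(unique(comp)))
    expect_equal(unname(st["connected_seed_count"]),
                 sum(table(comp)[comp] >= 2))
  }
})

test_that("fully isolated seeds score zero connectivity", {
  g <- edgeGraph("A", "X", "B", "Y", "C", "Z")
  mcn <- buildMCN(c("A", "B", "C"), g)
  st <- mcnStatistics(mcn)
  expect_equal(unname(st["connected_seed_count"]), 0)
  expect_equal(unname(st["components"]), 3)
})

test_that("null sampling is reproducible and p-values respect add-one
           bounds", {
  g <- generateInteractome(interactomeSpec(60, 0.08, seed = 2))
  n1 <- sampleNull(g, 8, M = 25, rng_seed = 77)
  n2 <- sampleNull(g, 8, M = 25, rng_seed = 77)
  expect_identical(n1, n2)
  n3 <- sampleNull(g, 8, M = 25, rng_seed = 78)
  expect_false(identical(n1, n3))
  # observed above every draw: p = 1/(M+1)
  expect_equal(mcnPValue(1e9, n1$connected_seed_count,
                         "connected_seed_count"), 1 / 26)
  expect_equal(mcnPValue(-1, n1$connected_seed_count,
                         "connected_seed_count"), 1)
  # components reverses the comparison (smaller = more connected)
  expect_equal(mcnPValue(0, n1$components, "components"), 1 / 26)
  expect_error(sampleNull(g, 100, M = 2), "exceeds")
})

test_that("degree-matched sampling reproduces the seeds' degree bins", {
  g <- generateInteractome(interactomeSpec(100, 0.06, seed = 4))
  seeds <- igraph::V(g)$name[order(-igraph::degree(g))][1:6]
  ns <- testMcnConnectivity(seeds, g, M = 19, mode = "degree_matched",
                            rng_seed = 5)
  expect_s4_class(ns, "NullSummary")
  expect_length(nullValues(ns), 19)
  expect_error(sampleNull(g, 5, M = 5, mode = "degree_matched"),
               "observed_seeds")
})

test_that("prioritization intersects connectivity with enrichment", {
  sc <- plantedModuleScenario(seed = 11)
  cand <- sc$run()
  expect_setequal(cand, sc$planted)
  # alpha = 0 gives an empty candidate list
  screen <- screenCohort(sc$matrix, sc$ref, alpha = 0.01)
  cc <- carrierCounts(sc$matrix)
  seeds <- names(cc)[cc >= 2]
  mcn <- buildMCN(seeds, sc$interactome)
  ns <- testMcnConnectivity(seeds, sc$interactome, M = 19,
                            statistic = "mean_seed_degree", rng_seed = 1)
  pr0 <- prioritizeCandidates(mcn, ns, screen, alpha = 0)
  expect_equal(nrow(pr0$candidates), 0)
})

test_that("enrichment-significant genes outside the interactome are
           reported separately", {
  g <- edgeGraph("A", "B")
  mcn <- buildMCN(c("A", "B"), g)
  ns <- new("NullSummary", statistic = "connected_seed_count",
            observed = 2, nullValues = rep(0, 19), pValue = 0.05,
            rngSeed = 1L, mode = "uniform")
  screen <- data.frame(gene = c("A", "OFFGRID"), n = 25, k = c(5, 5),
                       cohort_freq = 0.2, f0 = 0.01, f0_used = 0.01,
                       p_value = c(1e-4, 1e-5), q_value = 1e-4,
                       significant = TRUE)
  pr <- prioritizeCandidates(mcn, ns, screen)
  expect_equal(pr$candidates$gene, "A")
  expect_equal(pr$not_in_interactome, "OFFGRID")
})

test_that("MCN exports carry roles and the null report", {
  g <- edgeGraph("A", "V", "B", "V")
  mcn <- buildMCN(c("A", "B"), g)
  ns <- testMcnConnectivity(c("A", "B"), g, M = 9, rng_seed = 3)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  js <- withr::local_tempfile(fileext = ".json")
  writeMCN(mcn, sif = sif, graphml = gml, json = js, null_summary = ns)
  expect_length(readLines(sif), 2)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(gg)$role[igraph::V(gg)$name == "V"],
                  "intermediate")
  rep <- jsonlite::read_json(js)
  expect_equal(rep$null$M, 9)
  expect_equal(rep$null$rng_seed, 3)
})
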