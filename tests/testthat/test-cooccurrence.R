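test_that("pair contingency cross-tabulates the two columns", {
  mm <- makeMatrix(25, list(A = 1:2, B = 1:2))
  expect_equal(pairContingency(mm, "A", "B"),
               c(a = 2, b = 0, c = 0, d = 23))
  mm2 <- makeMatrix(25, list(A = 1:3, B = 4:7))
  expect_equal(pairContingency(mm2, "A", "B"),
               c(a = 0, b = 3, c = 4, d = 18))
  expect_error(pairContingency(mm, "A", "A"), "differ")
  expect_error(pairContingency(mm, "A", "Z"), "absent")
})

test_that("pair contingency equals a brute-force per-patient loop", {
  set.seed(5)
  m <- matrix(rbinom(30 * 6, 1, 0.3), 30, 6,
              dimnames = list(sprintf("P%02d", 1:30),
                              sprintf("G%02d", 1:6)))
  mm <- MutationMatrix(m)
  for (pair in list(c(1, 2), c(3, 6), c(4, 5))) {
    g1 <- colnames(m)[pair[1]]; g2 <- colnames(m)[pair[2]]
    a <- b <- c <- d <- 0
    for (i in 1:30) {
      x <- m[i, g1]; y <- m[i, g2]
      if (x && y) a <- a + 1 else if (x) b <- b + 1
      else if (y) c <- c + 1 else d <- d + 1
    }
    expect_equal(pairContingency(mm, g1, g2), c(a = a, b = b, c = c, d = d))
  }
})

test_that("observed-equals-expected tables give statistic 0, p 1", {
  r <- cooccurrenceTest(c(a = 4, b = 6, c = 6, d = 9))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$expected_a, 4)
  expect_equal(r$direction, "below")  # above only when strictly exceeding
})

test_that("perfect association gives chi-square = n", {
  r <- cooccurrenceTest(c(a = 2, b = 0, c = 0, d = 23))
  expect_equal(r$statistic, 25)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$direction, "above")
  expect_error(cooccurrenceTest(c(a = -1, b = 0, c = 0, d = 5)), "negative")
})

test_that("zero margins yield statistic 0 and p 1", {
  r <- cooccurrenceTest(c(a = 0, b = 0, c = 3, d = 22))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("chi-square equals n * phi^2 on random tables", {
  set.seed(7)
  for (i in 1:200) {
    tab <- c(a = rpois(1, 3), b = rpois(1, 4), c = rpois(1, 4),
             d = rpois(1, 12))
    n <- sum(tab)
    if (n == 0) next
    r <- cooccurrenceTest(tab)
    m1 <- tab[["a"]] + tab[["b"]]; m2 <- tab[["a"]] + tab[["c"]]
    denom <- sqrt(as.numeric(m1) * (n - m1) * m2 * (n - m2))
    phi <- if (denom == 0) 0 else
      (tab[["a"]] * tab[["d"]] - tab[["b"]] * tab[["c"]]) / denom
    expect_equal(r$statistic, n * phi^2, tolerance = 1e-12)
  }
})

test_that("chi-square matches stats::chisq.test without correction", {
  set.seed(12)
  for (i in 1:50) {
    tab <- c(a = rpois(1, 5) + 1, b = rpois(1, 5) + 1,
             c = rpois(1, 5) + 1, d = rpois(1, 10) + 1)
    r <- cooccurrenceTest(tab)
    ct <- suppressWarnings(chisq.test(matrix(tab[c("a", "c", "b", "d")], 2),
                                      correct = FALSE))
    expect_equal(r$statistic, unname(ct$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square and Fisher p-values agree in rank on well-filled
           tables", {
  set.seed(19)
  ps_chi <- ps_f <- numeric(0)
  while (length(ps_chi) < 500) {
    tab <- c(a = rpois(1, 10), b = rpois(1, 10), c = rpois(1, 10),
             d = rpois(1, 10))
    n <- sum(tab)
    m1 <- tab[["a"]] + tab[["b"]]; m2 <- tab[["a"]] + tab[["c"]]
    e <- c(m1 * m2, m1 * (n - m2), (n - m1) * m2,
           (n - m1) * (n - m2)) / n
    if (any(e < 5)) next
    ps_chi <- c(ps_chi, cooccurrenceTest(tab, "chi2")$p_value)
    ps_f <- c(ps_f, cooccurrenceTest(tab, "fisher")$p_value)
  }
  expect_gte(cor(-log(ps_chi), -log(ps_f), method = "spearman"), 0.95)
})

test_that("a planted perfectly co-occurring pair is found, direction above", {
  set.seed(31)
  found <- 0
  for (r in 1:20) {
    mm <- generateCohort(cohortSpec(
      25, sprintf("G%02d", 1:20),
      background_rate = c(0.04, 0.04, rep(0.08, 18)),
      planted_pairs = data.frame(gene1 = "G01", gene2 = "G02", count = 3),
      seed = 800 + r))
    e <- edgeTable(buildCooccurrenceNetwork(mm))
    found <- found + any(e$gene1 == "G01" & e$gene2 == "G02" &
                           e$direction == "above")
  }
  expect_gte(found / 20, 0.9)
})

test_that("network respects alpha, the pair bound, and symmetry", {
  set.seed(40)
  m <- matrix(rbinom(25 * 15, 1, 0.25), 25, 15,
              dimnames = list(sprintf("P%02d", 1:25),
                              sprintf("G%02d", 1:15)))
  mm <- MutationMatrix(m)
  net <- buildCooccurrenceNetwork(mm, alpha = 0.1)
  e <- edgeTable(net)
  expect_true(all(e$p_value <= 0.1))
  expect_lte(net@tested, choose(15, 2))
  expect_true(all(e$gene1 < e$gene2))
  # invariance to patient row order and gene column order
  net2 <- buildCooccurrenceNetwork(
    MutationMatrix(m[sample(25), sample(15)]), alpha = 0.1)
  e2 <- edgeTable(net2)
  expect_equal(e[order(e$gene1, e$gene2),
                 c("gene1", "gene2", "a", "p_value")],
               e2[order(e2$gene1, e2$gene2),
                  c("gene1", "gene2", "a", "p_value")],
               ignore_attr = TRUE)
  # min_pair_count restricts to edges carried by enough patients
  net3 <- buildCooccurrenceNetwork(mm, alpha = 0.1, min_pair_count = 3)
  expect_true(all(edgeTable(net3)$a >= 3))
})

test_that("a single-gene matrix gives an empty edge set", {
  mm <- makeMatrix(10, list(G1 = 1:3))
  net <- buildCooccurrenceNetwork(mm)
  expect_equal(nrow(edgeTable(net)), 0)
})

test_that("significant-degree summarizes edges per gene", {
  mm <- makeMatrix(25, list(A = 1:5, B = 1:5, C = 1:5, D = 20:22))
  net <- buildCooccurrenceNetwork(mm)
  nd <- nodeTable(net)
  # A, B, C co-occur perfectly pairwise: degree 2 each; D independent
  expect_equal(nd$sig_degree[nd$gene %in% c("A", "B", "C")], rep(2L, 3))
  expect_equal(nd$sig_degree[nd$gene == "D"], 0L)
})

test_that("network exports write edge tables, SIF and GraphML", {
  mm <- makeMatrix(25, list(A = 1:5, B = 1:5, C = 10:12))
  net <- buildCooccurrenceNetwork(mm)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeCooccurrenceNetwork(net, tsv = tsv, sif = sif, graphml = gml)
  tab <- read.delim(tsv)
  expect_equal(tab$gene1, "A")
  expect_equal(tab$gene2, "B")
  expect_match(readLines(sif), "A\tco\tB")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
})
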