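test_that("matched remission subtraction removes shared variants", {
  diag <- makeCalls(10)
  # remission shares the first 3 loci at heterozygous VAF
  rem <- makeCalls(3, alt_depth = 90)
  pair <- samplePair("P1", diag, rem)
  kept <- subtractMatchedRemission(pair)
  expect_equal(nrow(kept), 7)
  expect_setequal(kept$pos, diag$pos[4:10])
})

test_that("thresholded absence retains calls seen at zero alt reads in CR", {
  diag <- makeCalls(2)
  rem <- makeCalls(2, depth = 40, alt_depth = 0)
  kept <- subtractMatchedRemission(samplePair("P1", diag, rem))
  expect_equal(nrow(kept), 2)
  # one supporting read is still "absent" under the default threshold
  rem2 <- makeCalls(2, depth = 60, alt_depth = 1)
  expect_equal(nrow(subtractMatchedRemission(samplePair("P1", diag, rem2))),
               2)
  # but several supporting reads are not
  rem3 <- makeCalls(2, depth = 60, alt_depth = 5)
  expect_equal(nrow(subtractMatchedRemission(samplePair("P1", diag, rem3))),
               0)
})

test_that("subtraction on an unmatched pair directs to the heuristic", {
  expect_error(subtractMatchedRemission(samplePair("P1", makeCalls(2))),
               "germlineHeuristic")
})

test_that("allele parsimony strips shared padding around indels", {
  # extra anchored context trims to the same minimal representation
  nz1 <- normalizeAlleles(100, "GCA", "GCAA")
  nz2 <- normalizeAlleles(101, "CA", "CAA")
  expect_equal(nz1, nz2)
  expect_equal(nz1$ref, "C")
  expect_equal(nz1$alt, "CA")
  expect_equal(nz1$pos, 101L)
  # padded SNV representation reduces to the single changed base
  nzs <- normalizeAlleles(100, "TA", "TG")
  expect_equal(nzs, data.frame(pos = 101L, ref = "A", alt = "G"))
  # already-minimal alleles are untouched
  expect_equal(normalizeAlleles(50, "A", "G"),
               data.frame(pos = 50L, ref = "A", alt = "G"))
})

test_that("germline heuristic removes common and band-VAF calls", {
  calls <- makeCalls(4,
                     pop_freq = c(0.05, NA, NA, NA),
                     alt_depth = c(60, 100, 60, 196),  # VAF .3 .5 .3 .98
                     depth = 200)
  kept <- germlineHeuristic(calls, max_pop_freq = 0.01)
  expect_setequal(kept$gene, c("G03"))
  # frequency below the cutoff is retained
  kept2 <- germlineHeuristic(makeCalls(1, pop_freq = 0.005))
  expect_equal(nrow(kept2), 1)
  # empty input passes through
  expect_equal(nrow(germlineHeuristic(makeCalls(0))), 0)
})

test_that("germline heuristic removes >=90% of planted germline calls", {
  calls <- generateUnmatchedCalls(4000, germline_fraction = 0.3, seed = 9)
  kept <- germlineHeuristic(calls)
  removed <- 1 - sum(kept$is_germline) / sum(calls$is_germline)
  expect_gte(removed, 0.9)
  # somatic calls at sub-heterozygous VAF survive almost entirely
  expect_gte(sum(!kept$is_germline) / sum(!calls$is_germline), 0.95)
})

test_that("site filters apply the >=10-read coverage rule at the boundary", {
  calls <- makeCalls(2, depth = c(9, 10), alt_depth = c(3, 3))
  kept <- applySiteFilters(calls)
  expect_equal(kept$depth, 10)
})

test_that("vacuous site thresholds are the identity", {
  calls <- makeCalls(20, qual = runif(20, 0, 100),
                     strand_bias = runif(20),
                     depth = sample(5:50, 20, TRUE),
                     alt_depth = 2)
  expect_equal(applySiteFilters(calls, min_depth = 0, min_qual = 0,
                                max_strand_bias = 1, min_vaf = 0),
               calls)
})

test_that("site filters agree with a predicate-by-predicate rescan", {
  set.seed(11)
  n <- 1000
  depth <- sample(1:60, n, TRUE)
  calls <- makeCalls(n,
                     gene = "G01",
                     depth = depth,
                     alt_depth = vapply(depth, function(d) sample(0:d, 1L),
                                        integer(1)),
                     qual = runif(n, 0, 100),
                     strand_bias = runif(n),
                     pop_freq = NA_real_)
  kept <- applySiteFilters(calls, 10, 30, 0.9, 0.05)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    x <- calls[i, ]
    if (x$depth < 10) ok[i] <- FALSE
    if (x$qual < 30) ok[i] <- FALSE
    if (x$strand_bias > 0.9) ok[i] <- FALSE
    if (x$alt_depth / x$depth < 0.05) ok[i] <- FALSE
  }
  expect_equal(nrow(kept), sum(ok))
  expect_equal(kept$pos, calls$pos[ok])
})

test_that("consequence filter keeps the coding classes", {
  calls <- makeCalls(3, consequence = c("synonymous", "nonsynonymous",
                                        "ncRNA"))
  expect_equal(filterConsequence(calls)$consequence, "nonsynonymous")
  expect_error(filterConsequence(calls, keep = c("nonsynonymous", "bogus")),
               "unknown consequence")
})

test_that("extended-cohort consequence composition retains 218 of 219", {
  comp <- c(rep("nonsynonymous", 192), rep("frameshift", 3),
            rep("stop_gain", 14), rep("splice_site", 9), "ncRNA")
  calls <- makeCalls(219, gene = "G01", consequence = comp)
  expect_equal(nrow(filterConsequence(calls)), 218)
})

test_that("truncating consequences are deleterious regardless of the flag", {
  calls <- makeCalls(3, consequence = c("stop_gain", "nonsynonymous",
                                        "frameshift"),
                     deleterious = FALSE)
  kept <- filterDeleterious(calls)
  expect_setequal(kept$consequence, c("stop_gain", "frameshift"))
})

test_that("cascade audit is monotone, labelled, and deterministic", {
  dir <- withr::local_tempdir()
  fx <- generateVariantFixtures(dir, n_patients = 3, seed = 21)
  res <- runCascade(fx$pairs, cascadeConfig(mode = "matched"))
  cm <- auditCounts(res$audit)
  expect_true(all(apply(cm, 2, function(x) all(diff(x) <= 0))))
  expect_equal(auditTotals(res$audit), rowSums(cm))
  # serialization carries exactly the seven canonical stage labels
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFilterAudit(res$audit, f)
  tab <- read.delim(f, comment.char = "#")
  expect_equal(tab$Filter,
               c("Variants detected", "Somatic", "Absent in CR",
                 "High quality", "Coding (SNVs+indels)",
                 "Deleterious (SNVs+indels)", "Unknown in dbSNP"))
  expect_equal(tab$Total, unname(auditTotals(res$audit)))
  # identical input + config => identical audit and retained sets
  res2 <- runCascade(fx$pairs, cascadeConfig(mode = "matched"))
  expect_identical(auditCounts(res2$audit), cm)
  expect_identical(res2$retained, res$retained)
})

test_that("cascade removals match the planted stage labels exactly", {
  dir <- withr::local_tempdir()
  failures <- c(Somatic = 3L, AbsentInCR = 2L, HighQuality = 4L,
                Coding = 1L, Deleterious = 3L, UnknownInDbSNP = 2L)
  fx <- generateVariantFixtures(dir, n_patients = 4, n_pass = 6,
                                stage_failures = failures, seed = 5,
                                n_remission_zero_alt = 2)
  res <- runCascade(fx$pairs, cascadeConfig(mode = "matched"))
  cm <- auditCounts(res$audit)
  removals <- -apply(cm, 2, diff)
  for (p in colnames(cm)) {
    expect_equal(removals[c("Somatic", "AbsentInCR", "HighQuality",
                            "Coding", "Deleterious", "UnknownInDbSNP"), p],
                 c(failures), ignore_attr = TRUE)
    expect_true(all(res$retained[[p]]$sim_fail == "PASS"))
  }
})

test_that("unmatched cascade runs the germinality screen, skips CR stage", {
  calls <- rbind(makeCalls(6),
                 makeCalls(2, pop_freq = 0.2, pos = c(9000L, 9100L)))
  pairs <- list(samplePair("U1", calls))
  res <- runCascade(pairs, cascadeConfig(mode = "unmatched"))
  cm <- auditCounts(res$audit)
  expect_equal(cm["Somatic", "U1"], 6L)
  expect_equal(cm["AbsentInCR", "U1"], cm["Somatic", "U1"])
  expect_error(runCascade(pairs, cascadeConfig(mode = "matched")),
               "without remission")
})

test_that("Ti/Tv counts transitions strand-symmetrically", {
  calls <- makeCalls(4, ref = c("C", "G", "A", "C"),
                     alt = c("T", "A", "G", "A"))
  r <- tiTvRatio(calls)
  expect_equal(r$transitions, 3)
  expect_equal(r$transversions, 1)
  expect_equal(r$ratio, 3)
  # complementing every change leaves the ratio unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cc <- makeCalls(4, ref = comp[c("C", "G", "A", "C")],
                  alt = comp[c("T", "A", "G", "A")])
  expect_equal(tiTvRatio(cc)$ratio, r$ratio)
})

test_that("Ti/Tv is flagged undefined without transversions", {
  calls <- makeCalls(2, ref = c("A", "C"), alt = c("G", "T"))
  r <- tiTvRatio(calls)
  expect_false(r$defined)
  expect_true(is.na(r$ratio))
})

test_that("a 63:100 transition:transversion composition gives 0.63", {
  calls <- makeCalls(163,
                     ref = c(rep("C", 63), rep("C", 100)),
                     alt = c(rep("T", 63), rep("A", 100)))
  expect_equal(tiTvRatio(calls)$ratio, 0.63)
})

test_that("mutation matrix collapses calls and accepts extra events", {
  retained <- list(
    P1 = makeCalls(2, gene = c("TP53", "TP53")),
    P2 = makeCalls(1, gene = "FLT3"),
    P3 = makeCalls(0))
  mm <- toMutationMatrix(retained,
                         extra_events = data.frame(patient = "P3",
                                                   gene = "PML"))
  m <- incidenceMatrix(mm)
  expect_equal(m["P1", "TP53"], 1L)
  expect_equal(m["P3", "PML"], 1L)
  expect_equal(sum(m), 3L)
})

test_that("per-gene counts equal an independent tally over calls", {
  set.seed(3)
  genes <- sprintf("G%02d", 1:12)
  retained <- lapply(1:8, function(i) {
    k <- sample(0:6, 1)
    makeCalls(k, gene = sample(genes, k, replace = TRUE))
  })
  names(retained) <- sprintf("P%02d", 1:8)
  mm <- toMutationMatrix(retained, genes = genes)
  tally <- sapply(genes, function(g)
    sum(vapply(retained, function(df) any(df$gene == g), logical(1))))
  expect_equal(carrierCounts(mm)[genes], tally)
})

test_that("filter outputs are always subsets of their inputs", {
  set.seed(8)
  for (r in 1:20) {
    n <- 50
    depth <- sample(1:40, n, TRUE)
    calls <- makeCalls(n, gene = "G01",
                       depth = depth,
                       alt_depth = rbinom(n, depth, runif(n, 0.05, 0.95)),
                       qual = runif(n, 0, 100),
                       strand_bias = runif(n),
                       pop_freq = ifelse(runif(n) < 0.5, runif(n), NA),
                       consequence = sample(consequenceVocabulary(), n,
                                            TRUE),
                       known = runif(n) < 0.3,
                       deleterious = runif(n) < 0.5)
    for (f in list(function(x) germlineHeuristic(x),
                   function(x) applySiteFilters(x),
                   function(x) filterConsequence(x),
                   function(x) filterDeleterious(x))) {
      out <- f(calls)
      expect_true(all(out$pos %in% calls$pos))
      expect_lte(nrow(out), nrow(calls))
    }
  }
})

test_that("variant call validation enforces its invariants", {
  expect_error(makeCalls(1, pos = 0L), "1-based")
  expect_error(makeCalls(1, alt_depth = 300), "alt_depth")
  expect_error(makeCalls(1, strand_bias = 1.2), "strand_bias")
  expect_error(makeCalls(1, pop_freq = 2), "pop_freq")
  expect_error(makeCalls(1, consequence = "missense"), "unknown consequence")
  expect_equal(variantClass(c("A", "A", "AT"), c("G", "AT", "A")),
               c("SNV", "insertion", "deletion"))
})
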