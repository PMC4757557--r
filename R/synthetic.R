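#' Specification of a synthetic cohort mutation matrix
#'
#' Describes the cohort the generator emulates: by default 25 patients and
#' 72 genes (the scale of a targeted-resequencing leukemia cohort), with
#' per-gene background carrier rates, optionally planted enriched genes
#' (elevated rates) and planted co-occurring gene pairs (forced joint
#' carriers, so the truth value of the joint count is exact).
#'
#' @param n_patients cohort size.
#' @param genes gene symbols.
#' @param background_rate scalar or per-gene vector of Bernoulli carrier
#'   rates.
#' @param planted_enriched named numeric vector: gene -> rate multiplier
#'   applied to its background rate (capped at 1).
#' @param planted_pairs data.frame with columns gene1, gene2, count: pairs
#'   forced to be jointly mutated in `count` patients.
#' @param seed integer RNG seed, recorded in the output metadata.
#' @return list of class `cohort_spec`.
#' @export
cohortSpec <- function(n_patients = 25L, genes = sprintf("G%02d", 1:72),
                       background_rate = 0.08,
                       planted_enriched = numeric(0),
                       planted_pairs = NULL, seed = 1L) {
  rates <- rep_len(background_rate, length(genes))
  names(rates) <- genes
  stopifnot(all(rates >= 0 & rates <= 1))
  if (length(planted_enriched)) {
    bad <- setdiff(names(planted_enriched), genes)
    if (length(bad)) stop("planted genes outside gene list: ",
                          paste(bad, collapse = ", "))
    rates[names(planted_enriched)] <-
      pmin(1, rates[names(planted_enriched)] * planted_enriched)
  }
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene1", "gene2", "count") %in% names(planted_pairs)))
    if (any(planted_pairs$count > n_patients))
      stop("planted pair joint-carrier count exceeds cohort size")
    bad <- setdiff(c(planted_pairs$gene1, planted_pairs$gene2), genes)
    if (length(bad)) stop("planted pair genes outside gene list: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients), genes = genes,
                 rates = rates,
                 planted_enriched = names(planted_enriched),
                 planted_pairs = planted_pairs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort mutation matrix with planted structure
#'
#' Independent Bernoulli gene columns at the spec's rates; planted pairs
#' are then realized by forcing both genes to 1 in `count` randomly chosen
#' patients. Truth labels (planted enriched genes, forced patients per
#' pair, rates, seed) travel in `metadata()` of the result.
#'
#' @param spec a [cohortSpec()].
#' @return a [MutationMatrix-class] with truth labels in its metadata.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  patients <- sprintf("P%02d", seq_len(n))
  m <- vapply(spec$genes,
              function(g) rbinom(n, 1L, spec$rates[[g]]),
              integer(n))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(patients, spec$genes)
  forced <- list()
  if (!is.null(spec$planted_pairs)) {
    for (i in seq_len(nrow(spec$planted_pairs))) {
      pp <- spec$planted_pairs[i, ]
      rows <- sample.int(n, pp$count)
      m[rows, pp$gene1] <- 1L
      m[rows, pp$gene2] <- 1L
      forced[[paste(pp$gene1, pp$gene2, sep = "|")]] <- patients[rows]
    }
  }
  MutationMatrix(m, metadata = list(
    truth = list(planted_enriched = spec$planted_enriched,
                 forced_patients = forced, rates = spec$rates,
                 seed = spec$seed),
    spec = spec))
}

#' Generate a reference carrier-frequency table
#'
#' Stands in for a population repository frequency table; zero frequencies
#' are allowed so the floor rule can be exercised.
#'
#' @param genes gene symbols.
#' @param freq scalar or per-gene carrier frequencies (fractions).
#' @param n_ref stated reference cohort size.
#' @return a [ReferenceFrequencies-class].
#' @export
generateReference <- function(genes, freq, n_ref = 2504L) {
  ReferenceFrequencies(setNames(rep_len(freq, length(genes)), genes),
                       nRef = n_ref)
}

#' Specification of a synthetic interactome
#'
#' A background Erdos-Renyi graph plus a densified planted module, so that
#' seed sets drawn from the module are measurably more connected than
#' random node sets.
#'
#' @param n_nodes node count.
#' @param background_p background edge probability.
#' @param module_nodes node names of the planted module.
#' @param module_p within-module edge probability.
#' @param node_names node names; default `N001..`; `module_nodes` must be a
#'   subset.
#' @param seed integer RNG seed.
#' @return list of class `interactome_spec`.
#' @export
interactomeSpec <- function(n_nodes = 300L, background_p = 0.01,
                            module_nodes = character(0), module_p = 0.8,
                            node_names = NULL, seed = 1L) {
  stopifnot(background_p >= 0, background_p <= 1,
            module_p >= 0, module_p <= 1)
  if (is.null(node_names))
    node_names <- sprintf("N%03d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  bad <- setdiff(module_nodes, node_names)
  if (length(bad)) stop("module nodes outside node set: ",
                        paste(bad, collapse = ", "))
  structure(list(n_nodes = as.integer(n_nodes),
                 background_p = background_p,
                 module_nodes = module_nodes, module_p = module_p,
                 node_names = node_names, seed = as.integer(seed)),
            class = "interactome_spec")
}

#' Generate a synthetic interactome with a planted module
#'
#' @param spec an [interactomeSpec()].
#' @return an \pkg{igraph} simple undirected graph with the spec stored in
#'   its `spec` graph attribute.
#' @export
generateInteractome <- function(spec) {
  stopifnot(inherits(spec, "interactome_spec"))
  set.seed(spec$seed)
  g <- igraph::sample_gnp(spec$n_nodes, spec$background_p, directed = FALSE)
  igraph::V(g)$name <- spec$node_names
  if (length(spec$module_nodes) >= 2L) {
    pairs <- combn(spec$module_nodes, 2L)
    draw <- runif(ncol(pairs)) < spec$module_p
    if (any(draw))
      g <- igraph::add_edges(g, as.vector(pairs[, draw, drop = FALSE]))
  }
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "spec", spec)
  g
}

#' Generate matched diagnosis/remission VCF fixtures with planted
#' stage-specific failures
#'
#' Writes one diagnosis and one remission VCF per patient in which every
#' variant carries a `SIMFAIL` truth tag naming the cascade stage at which
#' it must be removed (or `PASS`). Each planted failure violates exactly
#' its own stage's predicate and passes all earlier stages, so the cascade
#' audit on the fixture must reproduce the planted per-stage removal
#' counts exactly.
#'
#' @param dir output directory (created if needed).
#' @param n_patients number of diagnosis/remission pairs.
#' @param n_pass passing (true somatic deleterious) variants per patient.
#' @param stage_failures named integer vector of planted failures per
#'   patient; names from `Somatic`, `AbsentInCR`, `HighQuality`, `Coding`,
#'   `Deleterious`, `UnknownInDbSNP`.
#' @param genes gene symbols to draw from.
#' @param n_remission_zero_alt per patient, passing variants additionally
#'   written to the remission VCF with zero alt reads (exercising
#'   thresholded absence; they must still be retained).
#' @param seed integer RNG seed (recorded in the VCF headers).
#' @return list: `pairs` (list of [samplePair()]s re-read from disk),
#'   `paths` (data.frame of written files), `truth` (per-patient named
#'   removal counts).
#' @export
generateVariantFixtures <- function(dir, n_patients = 3L, n_pass = 8L,
                                    stage_failures = c(Somatic = 2L,
                                                       AbsentInCR = 2L,
                                                       HighQuality = 2L,
                                                       Coding = 2L,
                                                       Deleterious = 2L,
                                                       UnknownInDbSNP = 2L),
                                    genes = sprintf("G%02d", 1:20),
                                    n_remission_zero_alt = 0L,
                                    seed = 1L) {
  fail_stages <- setdiff(names(.AUDIT_STAGES), "Detected")
  bad <- setdiff(names(stage_failures), fail_stages)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mkvariant <- function(n, stage) {
    n <- as.integer(n)
    if (n == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gene = character(), consequence = character(),
                        depth = integer(), alt_depth = integer(),
                        qual = numeric(), strand_bias = numeric(),
                        known = logical(), pop_freq = numeric(),
                        deleterious = logical(), sim_fail = character(),
                        stringsAsFactors = FALSE))
    depth <- rpois(n, 220)
    vaf <- 0.30
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    df <- data.frame(
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(5e7, n),
      ref = ref, alt = alt,
      gene = sample(genes, n, replace = TRUE),
      consequence = rep_len("nonsynonymous", n),
      depth = depth,
      alt_depth = pmax(1L, rbinom(n, depth, vaf)),
      qual = round(runif(n, 60, 99), 1),
      strand_bias = round(runif(n, 0, 0.4), 3),
      known = rep_len(FALSE, n),
      pop_freq = rep_len(NA_real_, n),
      deleterious = rep_len(TRUE, n),
      sim_fail = rep_len(stage, n),
      stringsAsFactors = FALSE)
    if (n == 0L) return(df)
    switch(stage,
           PASS = df,
           Somatic = { df$pop_freq <- 0.10; df },
           AbsentInCR = df,     # also written to remission below
           HighQuality = { df$depth <- 6L; df$alt_depth <- 2L; df },
           Coding = { df$consequence <- "synonymous"
                      df$deleterious <- FALSE; df },
           Deleterious = { df$deleterious <- FALSE; df },
           UnknownInDbSNP = { df$known <- TRUE; df })
  }
  paths <- data.frame(patient = character(), diagnosis = character(),
                      remission = character())
  pairs <- list()
  truth <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("SIM%02d", i)
    blocks <- c(list(mkvariant(n_pass, "PASS")),
                lapply(names(stage_failures), function(s)
                  mkvariant(stage_failures[[s]], s)))
    diag <- do.call(rbind, blocks)
    # guarantee unique loci within the patient
    diag$pos <- diag$pos + seq_len(nrow(diag))
    shared <- diag[diag$sim_fail == "AbsentInCR", , drop = FALSE]
    if (nrow(shared)) {
      shared$alt_depth <- pmax(2L, rbinom(nrow(shared), shared$depth, 0.45))
      shared$sim_fail <- NA_character_
    }
    zero <- if (n_remission_zero_alt > 0L) {
      z <- head(diag[diag$sim_fail == "PASS", , drop = FALSE],
                n_remission_zero_alt)
      z$alt_depth <- 0L
      z$sim_fail <- NA_character_
      z
    }
    rem_noise <- mkvariant(3L, "PASS")
    rem_noise$pos <- rem_noise$pos + 1e8L   # loci disjoint from diagnosis
    rem_noise$sim_fail <- NA_character_
    rem <- rbind(shared, zero, rem_noise)
    dpath <- file.path(dir, paste0(pid, "_diagnosis.vcf"))
    rpath <- file.path(dir, paste0(pid, "_remission.vcf"))
    meta <- c(paste0("##simulation_seed=", seed),
              paste0("##patient=", pid))
    writeVariantVcf(variantCalls(diag), dpath, meta = meta)
    writeVariantVcf(variantCalls(rem), rpath, meta = meta)
    pairs[[pid]] <- samplePair(pid, readVariantVcf(dpath),
                               readVariantVcf(rpath))
    paths <- rbind(paths, data.frame(patient = pid, diagnosis = dpath,
                                     remission = rpath))
    truth[[pid]] <- stage_failures
  }
  list(pairs = pairs, paths = paths, truth = truth)
}

#' Generate an unmatched cohort of annotated calls with planted germline
#' labels
#'
#' Emulates a targeted-panel cohort without matched remission samples:
#' a fraction of calls are germline (mostly catalogued in population
#' databases at frequency above 1%; VAF around 0.5 for heterozygous and
#' near 1 for homozygous carriers at panel-scale coverage), the rest
#' somatic at sub-heterozygous VAF. The truth label is the `is_germline`
#' column.
#'
#' @param n_calls total calls.
#' @param germline_fraction fraction of calls that are germline.
#' @param common_fraction fraction of germline calls catalogued with
#'   population frequency >= 1%.
#' @param hom_fraction fraction of germline calls that are homozygous.
#' @param mean_depth sequencing depth (Poisson mean).
#' @param seed RNG seed.
#' @return variant call table with `is_germline`.
#' @export
generateUnmatchedCalls <- function(n_calls = 1000L, germline_fraction = 0.3,
                                   common_fraction = 0.85,
                                   hom_fraction = 0.2,
                                   mean_depth = 220, seed = 1L) {
  set.seed(seed)
  n_g <- rbinom(1L, n_calls, germline_fraction)
  n_s <- n_calls - n_g
  bases <- c("A", "C", "G", "T")
  mk <- function(n, vaf_p, pop_freq, germ) {
    depth <- pmax(20L, rpois(n, mean_depth))
    ref <- sample(bases, n, replace = TRUE)
    data.frame(
      chrom = "chr1", pos = sample.int(1e8, n),
      ref = ref,
      alt = vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                   character(1)),
      gene = "GENE", consequence = "nonsynonymous",
      depth = depth,
      alt_depth = pmin(depth, pmax(1L, rbinom(n, depth, vaf_p))),
      qual = 80, strand_bias = 0.1, known = germ,
      pop_freq = pop_freq, deleterious = TRUE,
      is_germline = germ, stringsAsFactors = FALSE)
  }
  hom <- rbinom(1L, n_g, hom_fraction)
  het <- n_g - hom
  g_pf <- function(n) ifelse(runif(n) < common_fraction,
                             runif(n, 0.01, 0.5), NA_real_)
  calls <- rbind(
    mk(het, 0.5, g_pf(het), TRUE),
    mk(hom, 0.98, g_pf(hom), TRUE),
    mk(n_s, 0.25, NA_real_, FALSE))
  calls <- calls[sample.int(nrow(calls)), ]
  rownames(calls) <- NULL
  variantCalls(calls)
}

#' Planted-module validation scenario
#'
#' A full end-to-end scenario with known truth: a 25-patient cohort of 50
#' genes in which 8 "driver" genes carry mutations at rate 0.3 (the scale
#' of the most recurrent genes in a small leukemia cohort) against a
#' reference carrier frequency of 0.01, while the remaining 42 passenger
#' genes mutate at exactly the reference rate; plus a 300-node interactome
#' (background edge probability 0.01) in which the 8 drivers form a dense
#' planted module (within-module edge probability 0.8). Prioritization at
#' the strict level alpha = 0.01, with the `mean_seed_degree` null
#' statistic, recovers exactly the planted set in most replicates.
#'
#' @param seed integer RNG seed (cohort, interactome and the resampling
#'   null derive their streams from it).
#' @param M null draws for the connectivity test.
#' @return list: `matrix`, `ref`, `interactome`, `planted` (the true
#'   driver genes), `alpha` (0.01), and `run()`, a closure executing
#'   screen -> MCN -> null -> prioritization and returning the candidate
#'   gene vector.
#' @export
plantedModuleScenario <- function(seed = 1L, M = 99L) {
  planted <- sprintf("D%02d", 1:8)
  genes <- c(planted, sprintf("G%02d", 1:42))
  ref <- ReferenceFrequencies(setNames(rep(0.01, length(genes)), genes))
  mm <- generateCohort(cohortSpec(
    n_patients = 25L, genes = genes,
    background_rate = c(rep(0.3, 8), rep(0.01, 42)),
    planted_enriched = setNames(rep(1, 8), planted),  # rate set directly
    seed = seed))
  inet <- generateInteractome(interactomeSpec(
    n_nodes = 300L, background_p = 0.01,
    node_names = c(genes, sprintf("N%03d", seq_len(250))),
    module_nodes = planted, module_p = 0.8, seed = seed + 1L))
  alpha <- 0.01
  run <- function() {
    screen <- screenCohort(mm, ref, alpha = alpha)
    cc <- carrierCounts(mm)
    seeds <- names(cc)[cc >= 2L]
    mcn <- buildMCN(seeds, inet)
    ns <- testMcnConnectivity(seeds, inet, M = M,
                              statistic = "mean_seed_degree",
                              rng_seed = seed + 2L)
    prioritizeCandidates(mcn, ns, screen, alpha = alpha)$candidates$gene
  }
  list(matrix = mm, ref = ref, interactome = inet, planted = planted,
       alpha = alpha, run = run)
}
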