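#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated, serializable
#' object. `writePipelineConfig()` / `readPipelineConfig()` round-trip it
#' losslessly through YAML; [configHash()] of the object is embedded in
#' every output file header for provenance.
#'
#' @param filter a [cascadeConfig()] (or a named list of its fields).
#' @param enrichment_alpha significance level of the recurrence screen.
#' @param n_ref reference cohort size used when the reference table does
#'   not state one.
#' @param zero_floor explicit zero-frequency floor (`NULL` = `1/(n_ref+1)`).
#' @param cooc_alpha,cooc_method,min_pair_count co-occurrence settings.
#' @param null_M,null_mode,null_statistic MCN resampling-null settings.
#' @param seed global RNG seed.
#' @param paths named list of input/output paths (free-form; consumed by
#'   [runPipeline()]): `matrix`, `reference`, `category_map`,
#'   `interactome`, `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(filter = cascadeConfig(),
                           enrichment_alpha = 0.05, n_ref = 2504L,
                           zero_floor = NULL,
                           cooc_alpha = 0.05,
                           cooc_method = c("chi2", "fisher"),
                           min_pair_count = 0L,
                           null_M = 99L,
                           null_mode = c("uniform", "degree_matched"),
                           null_statistic = c("connected_seed_count",
                                              "components",
                                              "mean_seed_degree"),
                           seed = 1L, paths = list()) {
  cooc_method <- match.arg(cooc_method)
  null_mode <- match.arg(null_mode)
  null_statistic <- match.arg(null_statistic)
  if (is.list(filter) && !inherits(filter, "cascade_config"))
    filter <- do.call(cascadeConfig, filter)
  stopifnot(enrichment_alpha > 0, enrichment_alpha <= 1,
            cooc_alpha > 0, cooc_alpha <= 1,
            n_ref >= 1L, null_M >= 1L, min_pair_count >= 0L)
  structure(list(filter = filter,
                 enrichment_alpha = enrichment_alpha,
                 n_ref = as.integer(n_ref), zero_floor = zero_floor,
                 cooc_alpha = cooc_alpha, cooc_method = cooc_method,
                 min_pair_count = as.integer(min_pair_count),
                 null_M = as.integer(null_M), null_mode = null_mode,
                 null_statistic = null_statistic,
                 seed = as.integer(seed), paths = paths),
            class = "pipeline_config")
}

#' @rdname pipelineConfig
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$filter$germline_vaf_bands <- lapply(x$filter$germline_vaf_bands,
                                        as.numeric)
  do.call(pipelineConfig, x)
}

#' Run the full prioritization pipeline
#'
#' Executes screen -> co-occurrence -> categories (optional) -> MCN +
#' resampling null -> candidate prioritization on a mutation matrix, and
#' writes every artifact into `out_dir` with provenance headers (config
#' hash + RNG seed). Seeds for the MCN are the recurrently mutated genes
#' (carrier count >= `min_recurrence`) plus `extra_seed_genes`.
#'
#' @param matrix a [MutationMatrix-class].
#' @param ref a [ReferenceFrequencies-class].
#' @param interactome an igraph interactome.
#' @param config a [pipelineConfig()].
#' @param cmap optional [categoryMap()] for the functional-category module.
#' @param extra_seed_genes genes always added to the MCN seed set (e.g.
#'   fusion partners and ITD targets known from diagnostics).
#' @param min_recurrence carrier-count threshold defining recurrent genes.
#' @param out_dir output directory; `NULL` skips all file output.
#' @return list: screen, cooccurrence, categories (or NULL), mcn,
#'   null_summary, prioritization, audit-free run metadata.
#' @export
runPipeline <- function(matrix, ref, interactome,
                        config = pipelineConfig(), cmap = NULL,
                        extra_seed_genes = character(0),
                        min_recurrence = 2L, out_dir = NULL) {
  hash <- configHash(list(config = unclass(config),
                          filter = unclass(config$filter)))
  meta <- c(paste0("config_hash: ", hash),
            paste0("rng_seed: ", config$seed))

  screen <- screenCohort(matrix, ref, alpha = config$enrichment_alpha,
                         floor = config$zero_floor)
  cooc <- buildCooccurrenceNetwork(matrix, alpha = config$cooc_alpha,
                                   min_pair_count = config$min_pair_count,
                                   method = config$cooc_method)
  cats <- NULL
  if (!is.null(cmap)) {
    catm <- suppressWarnings(assignCategories(matrix, cmap))
    cats <- list(matrix = catm,
                 excess = categoryExcess(matrix, cmap,
                                         alpha = config$enrichment_alpha),
                 comutation = categoryComutation(catm,
                                                 alpha = config$cooc_alpha))
  }
  seeds <- union(names(carrierCounts(matrix))[
    carrierCounts(matrix) >= min_recurrence], extra_seed_genes)
  mcn <- buildMCN(seeds, interactome)
  nullsum <- testMcnConnectivity(seeds, interactome, M = config$null_M,
                                 mode = config$null_mode,
                                 statistic = config$null_statistic,
                                 rng_seed = config$seed)
  prio <- prioritizeCandidates(mcn, nullsum, screen,
                               alpha = config$enrichment_alpha,
                               cooccurrence = cooc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeMutationMatrix(matrix, file.path(out_dir, "mutation_matrix.tsv"),
                        meta)
    writeEnrichmentTable(screen, file.path(out_dir, "enrichment.tsv"), meta)
    writeCooccurrenceNetwork(cooc,
                             tsv = file.path(out_dir, "cooccurrence.tsv"),
                             sif = file.path(out_dir, "cooccurrence.sif"),
                             graphml = file.path(out_dir,
                                                 "cooccurrence.graphml"),
                             meta = meta)
    if (!is.null(cats)) {
      .writeTsv(cats$excess, file.path(out_dir, "category_excess.tsv"),
                meta)
      .writeTsv(cats$comutation,
                file.path(out_dir, "category_comutation.tsv"), meta)
    }
    writeMCN(mcn, sif = file.path(out_dir, "mcn.sif"),
             graphml = file.path(out_dir, "mcn.graphml"),
             json = file.path(out_dir, "mcn_null.json"),
             null_summary = nullsum)
    .writeTsv(prio$candidates, file.path(out_dir, "candidates.tsv"), meta)
    log <- list(config_hash = hash, rng_seed = config$seed,
                package_version = as.character(utils::packageVersion(
                  "CoMutNet")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."),
                n_patients = length(patientNames(matrix)),
                n_genes = length(geneNames(matrix)),
                n_seeds = length(seeds),
                mcn_p_value = nullPValue(nullsum))
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "run_log.json"))
  }
  list(screen = screen, cooccurrence = cooc, categories = cats,
       mcn = mcn, null_summary = nullsum, prioritization = prio,
       config_hash = hash)
}
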