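#' Configuration of the somatic filter cascade
#'
#' Collects every threshold of the cascade with the package defaults.
#' `min_depth = 10` encodes coverage by at least 10 reads; "absence" in the
#' remission sample is thresholded (at most `absence_max_alt_reads`
#' supporting reads and VAF below `absence_max_vaf`) rather than literal
#' zero, which is unstable at exome-scale coverage. The germinality
#' heuristic used in unmatched mode removes calls that are common in
#' population databases (`max_pop_freq`) or whose VAF falls in a germline
#' band (heterozygous around 0.5, homozygous near 1).
#'
#' @param mode `"matched"` (diagnosis/remission pairs), `"unmatched"`, or
#'   `"mixed"` (explicitly allows a cohort with both).
#' @param max_pop_freq population-frequency cutoff for the germline screen.
#' @param germline_vaf_bands list of closed intervals of VAF treated as
#'   germline in unmatched mode.
#' @param absence_max_alt_reads,absence_max_vaf thresholded absence in the
#'   remission sample.
#' @param min_depth,min_qual,max_strand_bias,min_vaf site-quality filters.
#' @param coding_keep consequence classes retained at the coding stage.
#' @return a named list of class `cascade_config`.
#' @export
cascadeConfig <- function(mode = c("matched", "unmatched", "mixed"),
                          max_pop_freq = 0.01,
                          germline_vaf_bands = list(c(0.45, 0.55),
                                                    c(0.95, 1.0)),
                          absence_max_alt_reads = 1,
                          absence_max_vaf = 0.02,
                          min_depth = 10, min_qual = 30,
                          max_strand_bias = 0.9, min_vaf = 0.05,
                          coding_keep = .CODING_KEEP) {
  mode <- match.arg(mode)
  stopifnot(max_pop_freq >= 0, absence_max_alt_reads >= 0,
            absence_max_vaf >= 0, min_depth >= 0, min_qual >= 0,
            max_strand_bias >= 0, max_strand_bias <= 1, min_vaf >= 0)
  bad <- setdiff(coding_keep, .CONSEQUENCES)
  if (length(bad))
    stop("coding_keep contains unknown consequence label(s): ",
         paste(bad, collapse = ", "))
  structure(list(mode = mode, max_pop_freq = max_pop_freq,
                 germline_vaf_bands = germline_vaf_bands,
                 absence_max_alt_reads = absence_max_alt_reads,
                 absence_max_vaf = absence_max_vaf,
                 min_depth = min_depth, min_qual = min_qual,
                 max_strand_bias = max_strand_bias, min_vaf = min_vaf,
                 coding_keep = coding_keep),
            class = "cascade_config")
}

#' A diagnosis / remission sample pair
#'
#' @param patient_id unique patient label.
#' @param diagnosis variant call table of the diagnostic sample.
#' @param remission optional variant call table of the matched
#'   complete-remission sample (the germline control); `NULL` in unmatched
#'   (extended-cohort) mode.
#' @return list of class `sample_pair`.
#' @export
samplePair <- function(patient_id, diagnosis, remission = NULL) {
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  structure(list(patient_id = patient_id,
                 diagnosis = variantCalls(diagnosis),
                 remission = if (!is.null(remission)) variantCalls(remission)),
            class = "sample_pair")
}

#' Subtract the matched remission sample (germline control)
#'
#' Retains diagnosis calls whose locus + alleles (after parsimony
#' normalization) are absent from the remission sample, where absence is
#' thresholded: at most `absence_max_alt_reads` alt-supporting reads AND
#' remission VAF below `absence_max_vaf`, or the locus unobserved in the
#' remission calls at all.
#'
#' @param pair a [samplePair()] with a remission sample.
#' @param absence_max_alt_reads,absence_max_vaf absence thresholds.
#' @return the retained subset of `pair$diagnosis`.
#' @export
subtractMatchedRemission <- function(pair, absence_max_alt_reads = 1,
                                     absence_max_vaf = 0.02) {
  if (is.null(pair$remission))
    stop("patient '", pair$patient_id, "' has no matched remission sample; ",
         "run in unmatched mode with germlineHeuristic() instead")
  stopifnot(absence_max_alt_reads >= 0, absence_max_vaf >= 0)
  diag <- pair$diagnosis
  rem <- pair$remission
  if (nrow(diag) == 0L) return(diag)
  dkey <- .variantKey(diag)
  rkey <- .variantKey(rem)
  idx <- match(dkey, rkey)
  present <- !is.na(idx)
  absent_by_threshold <- rep(TRUE, nrow(diag))
  if (any(present)) {
    r <- rem[idx[present], ]
    absent_by_threshold[present] <-
      r$alt_depth <= absence_max_alt_reads &
      (is.na(r$vaf) | r$vaf < absence_max_vaf)
  }
  diag[absent_by_threshold, , drop = FALSE]
}

#' Germinality heuristic for unmatched samples
#'
#' Classifies likely germline calls when no matched remission sample exists:
#' removes calls whose population carrier frequency is at least
#' `max_pop_freq`, and calls whose VAF lies in any germline band
#' (heterozygous ~0.5, homozygous ~1 by default). Calls with missing
#' `pop_freq` are retained unless excluded by a VAF band.
#'
#' @param calls variant call table.
#' @param max_pop_freq population-frequency cutoff.
#' @param germline_vaf_bands list of closed VAF intervals.
#' @return the retained subset of `calls`.
#' @export
germlineHeuristic <- function(calls, max_pop_freq = 0.01,
                              germline_vaf_bands = list(c(0.45, 0.55),
                                                        c(0.95, 1.0))) {
  if (nrow(calls) == 0L) return(calls)
  common <- !is.na(calls$pop_freq) & calls$pop_freq >= max_pop_freq
  in_band <- rep(FALSE, nrow(calls))
  for (b in germline_vaf_bands)
    in_band <- in_band | (!is.na(calls$vaf) &
                          calls$vaf >= b[1] & calls$vaf <= b[2])
  calls[!(common | in_band), , drop = FALSE]
}

#' Site-quality filters
#'
#' Retains calls covered by at least `min_depth` reads, with call quality at
#' least `min_qual`, strand-bias probability at most `max_strand_bias`, and
#' VAF at least `min_vaf`.
#'
#' @param calls variant call table.
#' @param min_depth,min_qual,max_strand_bias,min_vaf thresholds; degenerate
#'   (vacuous) values are allowed.
#' @return the retained subset of `calls`.
#' @export
applySiteFilters <- function(calls, min_depth = 10, min_qual = 30,
                             max_strand_bias = 0.9, min_vaf = 0.05) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$depth >= min_depth &
    calls$qual >= min_qual &
    calls$strand_bias <= max_strand_bias &
    !is.na(calls$vaf) & calls$vaf >= min_vaf
  calls[keep, , drop = FALSE]
}

#' Consequence-class filter (coding stage)
#'
#' @param calls variant call table.
#' @param keep consequence classes to retain; defaults to the coding set
#'   (nonsynonymous, stop gain, frameshift, in-frame indel, splice site).
#' @return the retained subset of `calls`.
#' @export
filterConsequence <- function(calls, keep = .CODING_KEEP) {
  bad <- setdiff(keep, .CONSEQUENCES)
  if (length(bad))
    stop("unknown consequence label(s) in keep-set: ",
         paste(bad, collapse = ", "))
  calls[calls$consequence %in% keep, , drop = FALSE]
}

#' Deleteriousness filter
#'
#' Retains calls flagged deleterious by upstream annotation, or carrying a
#' truncating / splice-disrupting consequence (stop gain, frameshift, splice
#' site), which are treated as deleterious regardless of the flag.
#'
#' @param calls variant call table.
#' @return the retained subset of `calls`.
#' @export
filterDeleterious <- function(calls) {
  keep <- calls$deleterious | calls$consequence %in% .TRUNCATING
  calls[keep, , drop = FALSE]
}

#' Run the full somatic filter cascade over a cohort
#'
#' Applies the seven-stage cascade (detected, somatic population screen,
#' remission subtraction, site quality, coding consequence, deleteriousness,
#' dbSNP-unknown) to every patient and returns the per-stage audit alongside
#' the retained calls. In unmatched mode the somatic stage applies the full
#' germinality heuristic and the remission stage passes through.
#'
#' @param cohort list of [samplePair()] objects.
#' @param config a [cascadeConfig()].
#' @return list with `audit` (a [FilterAudit-class]) and `retained`, a named
#'   per-patient list of retained variant call tables (each with a
#'   `filter_history` column naming the stages survived).
#' @export
runCascade <- function(cohort, config = cascadeConfig()) {
  stopifnot(inherits(config, "cascade_config"), length(cohort) >= 1L)
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort")
  has_rem <- vapply(cohort, function(p) !is.null(p$remission), logical(1))
  if (config$mode == "matched" && !all(has_rem))
    stop("matched mode but patients without remission sample: ",
         paste(ids[!has_rem], collapse = ", "))
  if (config$mode == "unmatched" && any(has_rem))
    stop("unmatched mode but remission samples supplied for: ",
         paste(ids[has_rem], collapse = ", "),
         " (use mode = 'mixed' to allow both)")

  stages <- names(.AUDIT_STAGES)
  counts <- matrix(0L, nrow = length(stages), ncol = length(ids),
                   dimnames = list(stages, ids))
  retained <- setNames(vector("list", length(ids)), ids)

  for (j in seq_along(cohort)) {
    pair <- cohort[[j]]
    matched <- !is.null(pair$remission)
    calls <- pair$diagnosis
    hist <- rep("Detected", nrow(calls))
    counts["Detected", j] <- nrow(calls)

    # Somatic: population-database screen; full germinality heuristic when
    # no matched germline control exists.
    calls <- if (matched) {
      germlineHeuristic(calls, config$max_pop_freq,
                        germline_vaf_bands = list())
    } else {
      germlineHeuristic(calls, config$max_pop_freq,
                        config$germline_vaf_bands)
    }
    counts["Somatic", j] <- nrow(calls)

    calls <- if (matched) {
      subtractMatchedRemission(pair = list(patient_id = pair$patient_id,
                                           diagnosis = calls,
                                           remission = pair$remission),
                               config$absence_max_alt_reads,
                               config$absence_max_vaf)
    } else calls
    counts["AbsentInCR", j] <- nrow(calls)

    calls <- applySiteFilters(calls, config$min_depth, config$min_qual,
                              config$max_strand_bias, config$min_vaf)
    counts["HighQuality", j] <- nrow(calls)

    calls <- filterConsequence(calls, config$coding_keep)
    counts["Coding", j] <- nrow(calls)

    calls <- filterDeleterious(calls)
    counts["Deleterious", j] <- nrow(calls)

    calls <- calls[!calls$known, , drop = FALSE]
    counts["UnknownInDbSNP", j] <- nrow(calls)

    if (nrow(calls))
      calls$filter_history <- paste(stages, collapse = "|")
    retained[[j]] <- calls
  }

  list(audit = FilterAudit(counts, mode = config$mode), retained = retained)
}

#' Transition/transversion ratio of a call set
#'
#' Computed over SNVs only. Transitions are purine-purine (A<->G) and
#' pyrimidine-pyrimidine (C<->T) changes; every other single-base change is
#' a transversion, so the ratio is invariant under strand complementation
#' (C>T and G>A count alike).
#'
#' @param calls variant call table.
#' @return list with `transitions`, `transversions`, `ratio` (`NA` when
#'   undefined) and `defined` (FALSE when there are no transversions).
#' @export
tiTvRatio <- function(calls) {
  snv <- calls[calls$vclass == "SNV", , drop = FALSE]
  change <- paste0(toupper(snv$ref), ">", toupper(snv$alt))
  ti_set <- c("A>G", "G>A", "C>T", "T>C")
  ti <- sum(change %in% ti_set)
  tv <- nrow(snv) - ti
  list(transitions = ti, transversions = tv,
       ratio = if (tv > 0) ti / tv else NA_real_,
       defined = tv > 0)
}

#' Collapse retained calls into a binary MutationMatrix
#'
#' Entry (patient, gene) is 1 iff the patient has at least one retained call
#' in the gene, or an injected gene-level extra event (e.g. PML/RARA fusion
#' partners or FLT3-ITD status from diagnostics, which are gene hits without
#' point-mutation calls).
#'
#' @param retained named per-patient list of variant call tables (the
#'   `retained` element of [runCascade()]).
#' @param extra_events optional data.frame with columns `patient`, `gene` of
#'   additional gene-level events.
#' @param genes optional character vector fixing the gene universe (columns);
#'   defaults to all genes observed.
#' @return a [MutationMatrix-class].
#' @export
toMutationMatrix <- function(retained, extra_events = NULL, genes = NULL) {
  patients <- names(retained)
  if (is.null(patients)) stop("retained must be a named per-patient list")
  hits <- do.call(rbind, c(
    lapply(patients, function(p) {
      g <- retained[[p]]$gene
      g <- g[nzchar(g)]
      if (length(g)) data.frame(patient = p, gene = unique(g)) else NULL
    }),
    list(if (!is.null(extra_events) && nrow(extra_events))
      data.frame(patient = as.character(extra_events$patient),
                 gene = as.character(extra_events$gene)))))
  if (is.null(genes))
    genes <- if (is.null(hits)) character(0) else sort(unique(hits$gene))
  m <- matrix(0L, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  if (!is.null(hits) && nrow(hits)) {
    unknown <- setdiff(unique(hits$gene), genes)
    if (length(unknown))
      stop("events in genes outside the declared universe: ",
           paste(unknown, collapse = ", "))
    m[cbind(hits$patient, hits$gene)] <- 1L
  }
  MutationMatrix(m)
}

#' Write a Table-1-style audit report
#'
#' Serializes a [FilterAudit-class] as TSV with the seven canonical stage
#' labels as rows, one column per patient, and a final `Total` column.
#'
#' @param audit a `FilterAudit`.
#' @param path output TSV path.
#' @param meta optional `#`-prefixed comment lines (config hash, seed).
#' @return `path`, invisibly.
#' @export
writeFilterAudit <- function(audit, path, meta = character()) {
  tab <- cbind(Filter = unname(.AUDIT_STAGES),
               as.data.frame(auditCounts(audit)),
               Total = unname(auditTotals(audit)))
  .writeTsv(tab, path, meta)
  invisible(path)
}

#' Read an audit report written by [writeFilterAudit()]
#'
#' @param path TSV path.
#' @param mode cascade mode recorded in the returned object.
#' @return a [FilterAudit-class].
#' @export
readFilterAudit <- function(path, mode = "matched") {
  tab <- .readTsv(path)
  if (!identical(tab[[1L]], unname(.AUDIT_STAGES)))
    stop("audit table '", path, "' does not carry the seven canonical ",
         "stage labels")
  patients <- setdiff(names(tab), c("Filter", "Total"))
  m <- as.matrix(tab[, patients, drop = FALSE])
  rownames(m) <- names(.AUDIT_STAGES)
  FilterAudit(m, mode = mode)
}
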