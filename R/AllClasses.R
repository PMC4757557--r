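#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats pbinom pchisq fisher.test prop.test p.adjust setNames
#'   rbinom runif rpois
#' @importFrom utils read.delim write.table combn head
NULL

## Canonical filter-cascade stages: internal ids -> report labels.
.AUDIT_STAGES <- c(
  Detected       = "Variants detected",
  Somatic        = "Somatic",
  AbsentInCR     = "Absent in CR",
  HighQuality    = "High quality",
  Coding         = "Coding (SNVs+indels)",
  Deleterious    = "Deleterious (SNVs+indels)",
  UnknownInDbSNP = "Unknown in dbSNP"
)

.CONSEQUENCES <- c("nonsynonymous", "synonymous", "stop_gain", "frameshift",
                   "inframe_indel", "splice_site", "ncRNA", "intergenic",
                   "other")

## Consequences counted as coding, and those deleterious irrespective of the
## annotation flag (truncating / splice-disrupting).
.CODING_KEEP <- c("nonsynonymous", "stop_gain", "frameshift", "inframe_indel",
                  "splice_site")
.TRUNCATING <- c("stop_gain", "frameshift", "splice_site")

#' MutationMatrix: binary patient-by-gene mutation incidence
#'
#' The common currency of all cohort-level statistics: a binary incidence
#' matrix recording, for every patient and gene, whether the patient carries
#' at least one retained somatic variant (or injected diagnostic event) in
#' that gene. Internally stored as a
#' \linkS4class{SummarizedExperiment} with genes as rows, patients as
#' columns and a single \code{"incidence"} assay, so the usual Bioconductor
#' machinery (subsetting, \code{metadata()}) applies.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [MutationMatrix()], [incidenceMatrix()], [carrierCounts()]
#' @export
setClass("MutationMatrix", contains = "SummarizedExperiment")

setValidity("MutationMatrix", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (length(a) != 1L || !identical(SummarizedExperiment::assayNames(object),
                                    "incidence"))
    return("MutationMatrix must carry exactly one assay named 'incidence'")
  m <- a[[1L]]
  if (!all(m %in% c(0L, 1L)))
    return("incidence entries must be 0 or 1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("gene (row) and patient (column) names are required")
  if (anyDuplicated(rownames(m)))
    return("duplicate gene symbols")
  if (anyDuplicated(colnames(m)))
    return("duplicate patient labels")
  TRUE
})

#' Construct a MutationMatrix
#'
#' @param incidence numeric/logical matrix of 0/1 entries with patients in
#'   rows and genes in columns (the layout used by the TSV interchange
#'   format; it is transposed into the genes-by-patients assay internally).
#' @param metadata optional list stored in `metadata()` (e.g. generator truth
#'   labels, RNG seed).
#' @return a [MutationMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("GENE1", "GENE2")))
#' mm <- MutationMatrix(m)
#' carrierCounts(mm)
#' @export
MutationMatrix <- function(incidence, metadata = list()) {
  stopifnot(is.matrix(incidence))
  storage <- t(incidence)
  mode(storage) <- "integer"
  new("MutationMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(incidence = storage), metadata = metadata))
}

#' @rdname MutationMatrix
#' @param x,object a `MutationMatrix`.
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname MutationMatrix
#' @export
setMethod("incidenceMatrix", "MutationMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "incidence"))
})

#' @rdname MutationMatrix
#' @export
setGeneric("patientNames", function(x) standardGeneric("patientNames"))

#' @rdname MutationMatrix
#' @export
setMethod("patientNames", "MutationMatrix", function(x) colnames(x))

#' @rdname MutationMatrix
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname MutationMatrix
#' @export
setMethod("geneNames", "MutationMatrix", function(x) rownames(x))

#' @rdname MutationMatrix
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))

#' Per-gene carrier counts (number of mutated patients)
#' @rdname MutationMatrix
#' @export
setMethod("carrierCounts", "MutationMatrix", function(x) {
  rowSums(SummarizedExperiment::assay(x, "incidence"))
})

setMethod("show", "MutationMatrix", function(object) {
  cc <- carrierCounts(object)
  cat("MutationMatrix:", ncol(object), "patients x", nrow(object), "genes\n")
  cat("  mutated genes (>=1 carrier):", sum(cc > 0L), "\n")
  cat("  recurrent genes (>=2 carriers):", sum(cc >= 2L), "\n")
})

#' FilterAudit: per-stage, per-patient surviving-variant counts
#'
#' Records how many variant calls survive each stage of the somatic filter
#' cascade in every patient, in cascade order. Totals are derived, never
#' stored. Stage ids are `names(auditStages())`.
#'
#' @slot counts integer matrix, stages in rows (canonical order), patients in
#'   columns.
#' @slot mode `"matched"`, `"unmatched"` or `"mixed"`.
#' @seealso [runCascade()], [writeFilterAudit()]
#' @export
setClass("FilterAudit",
         representation(counts = "matrix", mode = "character"))

setValidity("FilterAudit", function(object) {
  m <- object@counts
  if (!identical(rownames(m), names(.AUDIT_STAGES)))
    return("counts rows must be the seven canonical stages in order")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("unique patient column labels required")
  if (any(m < 0)) return("negative counts")
  if (any(apply(m, 2L, function(x) any(diff(x) > 0))))
    return("per-patient counts must be non-increasing across stages")
  TRUE
})

#' Canonical cascade stage ids and their report labels
#' @return named character vector: names are stage ids, values the labels
#'   used in serialized audit tables.
#' @export
auditStages <- function() .AUDIT_STAGES

#' Construct a FilterAudit from a stages-by-patients count matrix
#' @param counts integer matrix with one row per canonical stage id (in
#'   cascade order) and one column per patient.
#' @param mode cohort mode the cascade ran in.
#' @export
FilterAudit <- function(counts, mode = "matched") {
  rownames(counts) <- names(.AUDIT_STAGES)
  new("FilterAudit", counts = counts, mode = mode)
}

#' @rdname FilterAudit
#' @param x,object a `FilterAudit`.
#' @export
setGeneric("auditCounts", function(x) standardGeneric("auditCounts"))

#' @rdname FilterAudit
#' @export
setMethod("auditCounts", "FilterAudit", function(x) x@counts)

#' @rdname FilterAudit
#' @export
setGeneric("auditTotals", function(x) standardGeneric("auditTotals"))

#' Per-stage totals over patients
#' @rdname FilterAudit
#' @export
setMethod("auditTotals", "FilterAudit", function(x) rowSums(x@counts))

setMethod("show", "FilterAudit", function(object) {
  tab <- cbind(object@counts, Total = auditTotals(object))
  rownames(tab) <- unname(.AUDIT_STAGES)
  cat("FilterAudit (", object@mode, " mode)\n", sep = "")
  print(tab)
})

#' ReferenceFrequencies: per-gene carrier frequencies in a reference cohort
#'
#' Carrier frequencies (fraction of individuals with at least one qualifying
#' variant in the gene) observed in a reference population of `nRef`
#' individuals, e.g. the 1000 Genomes cohort (`nRef = 2504`). Frequencies of
#' exactly zero are permitted; enrichment tests floor them at
#' `1 / (nRef + 1)`.
#'
#' @slot freq named numeric vector of frequencies as fractions in [0, 1].
#' @slot nRef reference cohort size (individuals).
#' @export
setClass("ReferenceFrequencies",
         representation(freq = "numeric", nRef = "integer"))

setValidity("ReferenceFrequencies", function(object) {
  f <- object@freq
  if (is.null(names(f)) || anyDuplicated(names(f)))
    return("freq must be named by unique gene symbols")
  if (any(f < 0 | f > 1, na.rm = TRUE)) return("frequencies must lie in [0,1]")
  if (length(object@nRef) != 1L || object@nRef < 1L)
    return("nRef must be a single count >= 1")
  TRUE
})

#' Construct ReferenceFrequencies
#' @param freq named numeric vector of carrier frequencies (fractions).
#' @param nRef reference cohort size; 2504 is the 1000 Genomes phase-3 panel.
#' @export
ReferenceFrequencies <- function(freq, nRef = 2504L) {
  new("ReferenceFrequencies", freq = freq, nRef = as.integer(nRef))
}

#' @rdname ReferenceFrequencies
#' @param x,object a `ReferenceFrequencies`.
#' @export
setGeneric("refFreq", function(x) standardGeneric("refFreq"))

#' @rdname ReferenceFrequencies
#' @export
setMethod("refFreq", "ReferenceFrequencies", function(x) x@freq)

#' @rdname ReferenceFrequencies
#' @export
setGeneric("refCohortSize", function(x) standardGeneric("refCohortSize"))

#' @rdname ReferenceFrequencies
#' @export
setMethod("refCohortSize", "ReferenceFrequencies", function(x) x@nRef)

setMethod("show", "ReferenceFrequencies", function(object) {
  cat("ReferenceFrequencies:", length(object@freq), "genes, cohort size",
      object@nRef, "\n")
})

#' CooccurrenceNetwork: significant pairwise gene co-occurrence
#'
#' Result of testing all gene pairs of a cohort for co-occurring mutations.
#' `edges` holds the significant pairs with their 2x2 tables, chi-square (or
#' Fisher) statistic, p-value and direction (above/below the expectation
#' under independence); `nodes` carries the significant-degree per gene used
#' for node sizing in network renderings.
#'
#' @slot edges data.frame: gene1, gene2, a, b, c, d, expected_a, statistic,
#'   p_value, q_value, direction.
#' @slot nodes data.frame: gene, carriers, sig_degree.
#' @slot alpha significance level used.
#' @slot n cohort size.
#' @slot method "chi2" or "fisher".
#' @slot tested number of gene pairs tested.
#' @export
setClass("CooccurrenceNetwork",
         representation(edges = "data.frame", nodes = "data.frame",
                        alpha = "numeric", n = "integer", method = "character",
                        tested = "integer"))

#' @rdname CooccurrenceNetwork
#' @param x,object a `CooccurrenceNetwork`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname CooccurrenceNetwork
#' @export
setMethod("edgeTable", "CooccurrenceNetwork", function(x) x@edges)

#' @rdname CooccurrenceNetwork
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname CooccurrenceNetwork
#' @export
setMethod("nodeTable", "CooccurrenceNetwork", function(x) x@nodes)

setMethod("show", "CooccurrenceNetwork", function(object) {
  e <- object@edges
  cat("CooccurrenceNetwork:", nrow(e), "significant edges (alpha =",
      object@alpha, ") out of", object@tested, "tested pairs\n")
  cat("  above expectation:", sum(e$direction == "above"),
      "| below expectation:", sum(e$direction == "below"), "\n")
})

#' MCNResult: minimal connected network over an interactome
#'
#' The subnetwork connecting a seed gene set over a protein-protein
#' interactome, allowing one non-seed intermediate between seeds that lack a
#' direct interaction. Every retained intermediate is adjacent to at least
#' two seeds.
#'
#' @slot seeds seed genes present in the interactome.
#' @slot intermediates retained non-seed connector genes.
#' @slot edges data.frame (from, to) of retained undirected edges.
#' @slot roles named character, "seed" or "intermediate" per node.
#' @slot seedComponents named integer: connected-component id of each seed
#'   within the MCN.
#' @slot unmatched seed genes absent from the interactome.
#' @slot pruned whether minimality pruning of intermediates was applied.
#' @seealso [buildMCN()], [mcnStatistics()]
#' @export
setClass("MCNResult",
         representation(seeds = "character", intermediates = "character",
                        edges = "data.frame", roles = "character",
                        seedComponents = "integer", unmatched = "character",
                        pruned = "logical"))

setValidity("MCNResult", function(object) {
  if (length(intersect(object@seeds, object@intermediates)))
    return("a node cannot be both seed and intermediate")
  if (!all(sort(names(object@seedComponents)) == sort(object@seeds)))
    return("seedComponents must be named by exactly the seeds")
  TRUE
})

setMethod("show", "MCNResult", function(object) {
  st <- mcnStatistics(object)
  cat("MCNResult:", length(object@seeds), "seeds,",
      length(object@intermediates), "intermediates,",
      nrow(object@edges), "edges",
      if (object@pruned) "(pruned)" else "", "\n")
  cat("  connected seeds:", st[["connected_seed_count"]],
      "| seed components:", st[["components"]], "\n")
  if (length(object@unmatched))
    cat("  seeds absent from interactome:",
        paste(object@unmatched, collapse = ", "), "\n")
})

#' NullSummary: resampling null for an MCN connectivity statistic
#'
#' Holds the observed value of a connectivity statistic, the values of the
#' same statistic over M random seed sets, and the add-one empirical p-value
#' `(1 + #{null at least as extreme}) / (M + 1)` (extremeness reversed for
#' `components`, where smaller means more connected).
#'
#' @slot statistic one of "connected_seed_count", "components",
#'   "mean_seed_degree".
#' @slot observed observed statistic value.
#' @slot nullValues numeric vector of length M.
#' @slot pValue add-one empirical p-value.
#' @slot rngSeed integer seed used for the resampling.
#' @slot mode null sampling mode ("uniform" or "degree_matched").
#' @export
setClass("NullSummary",
         representation(statistic = "character", observed = "numeric",
                        nullValues = "numeric", pValue = "numeric",
                        rngSeed = "integer", mode = "character"))

setMethod("show", "NullSummary", function(object) {
  cat("NullSummary:", object@statistic, "=", object@observed,
      "vs", length(object@nullValues), "null draws (", object@mode, ")\n")
  cat("  empirical p =", object@pValue, "(rng seed", object@rngSeed, ")\n")
})

#' @rdname NullSummary
#' @param x,object a `NullSummary`.
#' @export
setGeneric("nullPValue", function(x) standardGeneric("nullPValue"))

#' @rdname NullSummary
#' @export
setMethod("nullPValue", "NullSummary", function(x) x@pValue)

#' @rdname NullSummary
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname NullSummary
#' @export
setMethod("nullValues", "NullSummary", function(x) x@nullValues)
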