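## Annotated variant calls are carried as plain data.frames with a fixed
## column contract; variantCalls() validates and derives vclass/VAF.

.VC_REQUIRED <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                  "depth", "alt_depth", "qual", "strand_bias", "known",
                  "pop_freq", "deleterious")

#' Assemble and validate a table of annotated variant calls
#'
#' One row per variant observation in one sample. Coordinates follow the VCF
#' convention (1-based, `ref`/`alt` allele strings). `vclass` (SNV /
#' insertion / deletion) is derived from the allele lengths; a variant is an
#' SNV iff both alleles have length 1.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence` (one of the vocabulary returned by
#'   [consequenceVocabulary()]), `depth`, `alt_depth`, `qual`, `strand_bias`
#'   (probability-scale, in [0,1]), `known` (logical, present in a
#'   dbSNP-style catalogue), `pop_freq` (population carrier frequency,
#'   fraction, `NA` allowed), `deleterious` (logical, from upstream
#'   annotation).
#' @return the validated data.frame with derived `vclass` and `vaf` columns.
#' @export
variantCalls <- function(df) {
  missing <- setdiff(.VC_REQUIRED, names(df))
  if (length(missing))
    stop("variant call table lacks columns: ", paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based)")
    if (any(df$alt_depth < 0 | df$alt_depth > df$depth))
      stop("alt_depth must lie in [0, depth]")
    if (any(df$strand_bias < 0 | df$strand_bias > 1))
      stop("strand_bias must lie in [0, 1]")
    bad_pf <- !is.na(df$pop_freq) & (df$pop_freq < 0 | df$pop_freq > 1)
    if (any(bad_pf)) stop("pop_freq must lie in [0, 1] when present")
    unknown <- setdiff(unique(df$consequence), .CONSEQUENCES)
    if (length(unknown))
      stop("unknown consequence label(s): ", paste(unknown, collapse = ", "))
  }
  df$vclass <- variantClass(df$ref, df$alt)
  df$vaf <- ifelse(df$depth > 0, df$alt_depth / df$depth, NA_real_)
  df
}

#' @rdname variantCalls
#' @param ref,alt allele strings.
#' @export
variantClass <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' The consequence vocabulary accepted in variant call tables
#' @return character vector of valid consequence labels.
#' @export
consequenceVocabulary <- function() .CONSEQUENCES

#' Reference-free allele parsimony normalization
#'
#' Trims bases shared by `ref` and `alt` (common suffix first, then common
#' prefix, advancing `pos` accordingly, always keeping at least one base per
#' allele) so that the same indel written with different padding compares
#' equal. True left-alignment across repeat tracts requires the reference
#' genome and is out of scope; annotated calls from a single caller are
#' normalized consistently by parsimony alone.
#'
#' @param pos,ref,alt vectors of 1-based positions and allele strings.
#' @return data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalizeAlleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = pos, ref = ref, alt = alt)
}

## Variant identity key used for remission subtraction.
.variantKey <- function(calls) {
  nz <- normalizeAlleles(calls$pos, calls$ref, calls$alt)
  paste(calls$chrom, nz$pos, nz$ref, nz$alt, sep = ":")
}

#' Read annotated variant calls from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) whose INFO field carries the
#' annotation the cascade consumes. The INFO key mapping is configurable;
#' the defaults match the files written by [writeVariantVcf()] and
#' [generateVariantFixtures()].
#'
#' @param path VCF file.
#' @param info_keys named list mapping the logical fields `gene`,
#'   `consequence`, `depth`, `alt_depth`, `strand_bias`, `pop_freq`,
#'   `deleterious`, `known` to INFO keys. `known` and `deleterious` are
#'   Flag-style (presence = TRUE).
#' @return a validated variant call table (see [variantCalls()]); the
#'   simulation truth tag, when present, is exposed as a `sim_fail` column.
#' @export
readVariantVcf <- function(path,
                           info_keys = list(gene = "GENE", consequence = "CSQ",
                                            depth = "DP", alt_depth = "AD",
                                            strand_bias = "SB",
                                            pop_freq = "PF",
                                            deleterious = "DLT",
                                            known = "KNOWN")) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variantCalls(data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   gene = character(),
                                   consequence = character(),
                                   depth = numeric(), alt_depth = numeric(),
                                   qual = numeric(), strand_bias = numeric(),
                                   known = logical(), pop_freq = numeric(),
                                   deleterious = logical())))
  }
  info1 <- function(key, numeric = TRUE) {
    x <- unname(vcfR::extract.info(v, element = key))
    if (numeric) suppressWarnings(as.numeric(x)) else as.character(x)
  }
  flag <- function(key) {
    # Flag-type INFO keys: presence (with or without '=1') means TRUE
    info <- fix$INFO
    grepl(paste0("(^|;)", key, "(=1)?(;|$)"), info)
  }
  df <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info1(info_keys$gene, numeric = FALSE),
    consequence = info1(info_keys$consequence, numeric = FALSE),
    depth = info1(info_keys$depth),
    alt_depth = info1(info_keys$alt_depth),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    strand_bias = info1(info_keys$strand_bias),
    known = flag(info_keys$known),
    pop_freq = info1(info_keys$pop_freq),
    deleterious = flag(info_keys$deleterious),
    stringsAsFactors = FALSE
  )
  df$gene[is.na(df$gene)] <- ""
  sim <- suppressWarnings(vcfR::extract.info(v, element = "SIMFAIL"))
  if (!all(is.na(sim))) df$sim_fail <- sim
  variantCalls(df)
}

#' Write annotated variant calls as a VCF file
#'
#' Emits a minimal VCF 4.2 file carrying the annotation columns as INFO
#' keys (the mapping mirrors [readVariantVcf()] defaults). Used both by the
#' fixture generator and to export retained calls with their filter
#' history.
#'
#' @param calls variant call table ([variantCalls()] contract). Optional
#'   columns `sim_fail` (truth tag) and `filter_history` (semicolon-joined
#'   stages survived) are serialized as `SIMFAIL` and `FHIST`.
#' @param path output file.
#' @param meta extra `##`-header lines (e.g. generator seed).
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(calls, path, meta = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           meta,
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
           "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias probability\">",
           "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Population carrier frequency\">",
           "##INFO=<ID=DLT,Number=0,Type=Flag,Description=\"Annotated deleterious\">",
           "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Present in known-variant catalogue\">",
           "##INFO=<ID=SIMFAIL,Number=1,Type=String,Description=\"Synthetic truth: first failing cascade stage\">",
           "##INFO=<ID=FHIST,Number=1,Type=String,Description=\"Cascade stages survived\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    parts <- c(paste0("GENE=", x$gene),
               paste0("CSQ=", x$consequence),
               paste0("DP=", x$depth),
               paste0("AD=", x$alt_depth),
               paste0("SB=", x$strand_bias),
               if (!is.na(x$pop_freq)) paste0("PF=", x$pop_freq),
               if (isTRUE(x$deleterious)) "DLT",
               if (isTRUE(x$known)) "KNOWN",
               if (!is.null(x$sim_fail) && !is.na(x$sim_fail))
                 paste0("SIMFAIL=", x$sim_fail),
               if (!is.null(x$filter_history))
                 paste0("FHIST=", x$filter_history))
    paste(parts, collapse = ";")
  }, character(1))
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          calls$qual, "PASS", info, sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
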