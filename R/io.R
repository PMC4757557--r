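## TSV conventions shared by all writers: one header line, tab-delimited,
## UTF-8, '.' decimal, optional leading '#' metadata lines.

.writeTsv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, dec = ".")
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Hash a configuration object for provenance headers
#'
#' Serializes the object to canonical JSON and returns its MD5 digest, so
#' every output file can embed the exact configuration that produced it.
#'
#' @param config any JSON-serializable R object.
#' @return hex digest string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read a binary mutation matrix as TSV
#'
#' Patients in rows (first column `patient`), genes in columns, 0/1 entries.
#'
#' @param mm a [MutationMatrix-class].
#' @param path TSV path.
#' @param meta optional `#` metadata lines.
#' @return `path` (writer) or a `MutationMatrix` (reader).
#' @export
writeMutationMatrix <- function(mm, path, meta = character()) {
  m <- incidenceMatrix(mm)
  df <- data.frame(patient = rownames(m), m, check.names = FALSE)
  .writeTsv(df, path, meta)
  invisible(path)
}

#' @rdname writeMutationMatrix
#' @export
readMutationMatrix <- function(path) {
  df <- .readTsv(path)
  if (names(df)[1L] != "patient")
    stop("mutation matrix '", path, "' must have a leading 'patient' column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(m %in% c(0L, 1L)))
    stop("mutation matrix '", path, "' has non-binary entries")
  rownames(m) <- df$patient
  MutationMatrix(m)
}

#' Read a reference-population carrier-frequency table
#'
#' Two-column TSV (gene, frequency). Whether frequencies are percentages or
#' fractions is decided by the header token (a `%` or `_pct` suffix marks
#' percentages), never by magnitude heuristics. The reference cohort size
#' may be given as a `# n_ref: <N>` metadata line or via the `n_ref`
#' argument.
#'
#' @param path TSV path.
#' @param n_ref reference cohort size; overrides any metadata line.
#' @return a [ReferenceFrequencies-class].
#' @export
readReferenceFrequencies <- function(path, n_ref = NULL) {
  if (is.null(n_ref)) {
    hdr <- readLines(path, n = 50L)
    m <- regmatches(hdr, regexpr("#\\s*n_ref:\\s*[0-9]+", hdr))
    n_ref <- if (length(m)) as.integer(sub(".*n_ref:\\s*", "", m[[1L]]))
             else 2504L
  }
  df <- .readTsv(path)
  if (ncol(df) < 2L) stop("reference table '", path, "' needs >= 2 columns")
  # in multi-column tables (e.g. cohort + reference frequencies side by
  # side) the reference column is picked by name, never by magnitude
  j <- grep("^reference", names(df), ignore.case = TRUE)
  j <- if (length(j)) j[1L] else 2L
  freq_col <- names(df)[j]
  f <- as.numeric(df[[j]])
  if (grepl("%|_pct|\\bpct\\b", freq_col, ignore.case = TRUE)) f <- f / 100
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("reference frequencies in '", path, "' fall outside [0,1] after ",
         "unit conversion; check the header unit token")
  ReferenceFrequencies(setNames(f, df[[1L]]), nRef = n_ref)
}

#' @rdname readReferenceFrequencies
#' @param ref a `ReferenceFrequencies`.
#' @param percent write frequencies as percentages (header announces the
#'   unit either way).
#' @param meta optional `#` metadata lines.
#' @export
writeReferenceFrequencies <- function(ref, path, percent = FALSE,
                                      meta = character()) {
  f <- refFreq(ref)
  df <- data.frame(gene = names(f),
                   freq = if (percent) 100 * f else f)
  names(df)[2L] <- if (percent) "frequency_pct" else "frequency"
  .writeTsv(df, path, c(paste0("n_ref: ", refCohortSize(ref)), meta))
  invisible(path)
}

#' Read a gene-to-functional-category map
#'
#' Two-column TSV (gene, category); repeated gene rows assign multiple
#' labels. The label vocabulary defaults to the labels present in the file.
#'
#' @param path TSV path.
#' @param vocabulary optional declared label vocabulary; labels outside it
#'   are a configuration error.
#' @return named list gene -> character vector of labels, with the
#'   vocabulary as attribute `"vocabulary"`.
#' @export
readCategoryMap <- function(path, vocabulary = NULL) {
  df <- .readTsv(path)
  if (ncol(df) < 2L) stop("category map '", path, "' needs 2 columns")
  categoryMap(setNames(as.character(df[[2L]]), as.character(df[[1L]])),
              vocabulary = vocabulary)
}

#' Build a category map from a named label vector or list
#'
#' @param labels either a named character vector (repeated names allowed)
#'   or a named list of character vectors, gene -> labels.
#' @param vocabulary optional declared vocabulary.
#' @return named list gene -> labels with attribute `"vocabulary"`.
#' @export
categoryMap <- function(labels, vocabulary = NULL) {
  cm <- if (is.list(labels)) labels
        else split(unname(labels), names(labels))
  cm <- lapply(cm, unique)
  if (length(cm) == 0L) stop("empty category map")
  labs <- unique(unlist(cm))
  if (is.null(vocabulary)) vocabulary <- sort(labs)
  bad <- setdiff(labs, vocabulary)
  if (length(bad))
    stop("category labels outside the declared vocabulary: ",
         paste(bad, collapse = ", "))
  structure(cm, vocabulary = vocabulary)
}

#' Read an undirected interactome from SIF or two-column TSV
#'
#' SIF lines are `A <relation> B` (whitespace-separated); two-column TSV
#' has a header and one edge per row. Self-loops and duplicate edges are
#' dropped so the result is a simple undirected graph.
#'
#' @param path SIF or TSV file.
#' @return an \pkg{igraph} undirected simple graph.
#' @export
readInteractome <- function(path) {
  if (!file.exists(path)) stop("interactome file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("interactome '", path, "' has no edges")
  parts <- strsplit(trimws(lines), "[\t ]+")
  w <- lengths(parts)
  if (all(w == 3L) && length(unique(vapply(parts, `[`, "", 2L))) <= 3L) {
    ft <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 3L))
  } else if (all(w == 2L)) {
    ft <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
    # drop a header row if present (detected by repeat occurrence as node)
    if (ft[1L, 1L] %in% c("gene1", "from", "source"))
      ft <- ft[-1L, , drop = FALSE]
  } else {
    stop("interactome '", path, "' line ", which(!w %in% c(2L, 3L))[1L],
         ": expected 'A pp B' (SIF) or two columns")
  }
  g <- igraph::graph_from_edgelist(ft, directed = FALSE)
  igraph::simplify(g)
}

#' Write an interactome or MCN edge set as SIF
#'
#' @param edges two-column data.frame or matrix of endpoints, or an igraph.
#' @param path output path.
#' @param relation SIF relation label.
#' @return `path`, invisibly.
#' @export
writeSif <- function(edges, path, relation = "pp") {
  if (inherits(edges, "igraph"))
    edges <- igraph::as_edgelist(edges)
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  writeLines(paste(edges[, 1L], relation, edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export a network with node/edge attributes as GraphML
#'
#' Canonicalizes node and edge order so identical inputs serialize
#' byte-identically.
#'
#' @param edges data.frame whose first two columns are endpoints; remaining
#'   columns become edge attributes.
#' @param nodes optional data.frame whose first column is the node name;
#'   remaining columns become node attributes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(edges, path, nodes = NULL) {
  e <- as.data.frame(edges)
  if (nrow(e)) {
    swap <- e[[1L]] > e[[2L]]
    tmp <- e[[1L]][swap]; e[[1L]][swap] <- e[[2L]][swap]; e[[2L]][swap] <- tmp
    e <- e[order(e[[1L]], e[[2L]]), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = if (!is.null(nodes))
      nodes[order(nodes[[1L]]), , drop = FALSE])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
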