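#' Read a samples x OTUs count table
#'
#' Reads an OTU abundance table from tab-separated text or BIOM format and
#' returns an integer-like matrix oriented samples x OTUs. Both deposition
#' conventions (OTUs as rows or as columns) occur in practice, so the
#' orientation can be stated or auto-detected.
#'
#' @param path file path.
#' @param format `"tsv"` (first column holds row ids) or `"biom"`.
#' @param orientation `"auto"`, `"samples_rows"` or `"otus_rows"`. Under
#'   `"auto"`, the longer dimension is taken to be the OTUs (tables hold
#'   many more taxa than samples); a tie falls back to samples-as-rows.
#' @return numeric matrix, samples as rows, OTUs as columns.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("auto", "samples_rows", "otus_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat package required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples in BIOM
    counts <- t(m)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate row ids in count table")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in table")
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) stop("duplicate column ids in count table")
    counts <- switch(orientation,
      samples_rows = m,
      otus_rows = t(m),
      auto = if (nrow(m) > ncol(m)) t(m) else m)
  }
  if (any(counts < 0)) stop("negative counts: malformed count table")
  validate_counts(counts)
  counts
}

#' Write a count table as TSV (samples as rows)
#'
#' @param counts samples x OTUs matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted binary phylogeny of OTUs
#'
#' Reads Newick, optionally prunes to a tip set, and enforces the rooted
#' binary shape the balance transform requires. Polytomies can be resolved
#' deterministically (random bifurcation under a fixed seed, zero-length
#' inserted branches).
#'
#' @param path Newick file.
#' @param tips optional character vector; tree is pruned to these tips.
#' @param resolve resolve polytomies (and root trifurcations) if `TRUE`.
#' @param seed seed for the deterministic resolution.
#' @return an [ape::phylo] tree, rooted and binary.
#' @export
read_tree <- function(path, tips = NULL, resolve = FALSE, seed = 1L) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (!is.null(tips)) {
    missing <- setdiff(tips, tr$tip.label)
    if (length(missing))
      stop("tips absent from tree: ", paste(head(missing, 5L), collapse = ", "))
    tr <- ape::keep.tip(tr, tips)
  }
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    if (!resolve)
      stop("tree is not rooted and binary; set resolve = TRUE to bifurcate")
    set.seed(seed)
    tr <- ape::multi2di(tr, random = TRUE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a correlation network to disk
#'
#' Writes GraphML (via igraph) or a plain edge-list TSV. The TSV carries a
#' `# nodes:` header line so that isolated nodes survive a round trip.
#'
#' @param graph an igraph object; edges carry a signed `weight`.
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(graph, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ",
                    paste(igraph::V(graph)$name, collapse = "\t")), con)
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!nrow(el)) {
    writeLines("from\tto\tweight", con)
  } else {
    if (is.null(el$weight)) el$weight <- 1
    writeLines("from\tto\tweight", con)
    writeLines(paste(el$from, el$to, format(el$weight, digits = 15),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return an igraph object with signed edge weights.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  nodes <- character(0)
  if (length(lines) && startsWith(lines[1L], "# nodes:")) {
    payload <- sub("^# nodes: ?", "", lines[1L])
    if (nzchar(payload)) nodes <- strsplit(payload, "\t")[[1L]]
    lines <- lines[-1L]
  }
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = if (length(nodes)) nodes else NULL)
  g
}
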