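#' Read a protein-protein interaction network from an edge-list TSV
#'
#' The expected format is two tab-separated node identifiers per line, no
#' header — the common exchange format for interactome snapshots. GraphML and
#' SIF files are also accepted (detected from the file extension).
#'
#' @param path Path to an edge-list TSV, a `.graphml` file, or a `.sif` file.
#' @return An undirected, simple [igraph::graph] whose vertices are named by
#'   the protein identifiers.
#' @export
read_ppi_network <- function(path) {
  if (!file.exists(path)) abort_arg(sprintf("network file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else if (ext == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines[nzchar(lines)], "\t| +")
    ek <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) < 3L) abort_arg("SIF lines must be 'source relation target'")
      cbind(p[1L], p[3:length(p)])
    }))
    g <- igraph::graph_from_edgelist(ek, directed = FALSE)
  } else {
    el <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    if (ncol(el) < 2L) abort_arg("edge-list TSV needs two tab-separated columns")
    g <- igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
  }
  as_ppi_network(g)
}

#' Coerce a graph to the simple undirected form used throughout the package
#'
#' Drops self-loops and duplicate edges and forgets edge directions.
#'
#' @param g An [igraph::graph].
#' @return An undirected simple igraph with named vertices.
#' @export
as_ppi_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Write a network as an edge-list TSV
#'
#' @param net An igraph network.
#' @param path Output path. Two tab-separated node IDs per line, no header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a disease seed-protein list (one identifier per line)
#'
#' @param path Path to a plain-text file, one protein ID per line.
#' @return Character vector of unique identifiers.
#' @export
read_seed_list <- function(path) {
  x <- readLines(path)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' Write a seed-protein list, one identifier per line
#' @param ids Character vector of protein IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Export a graph in SIF (simple interaction format)
#'
#' One line per edge: `source <TAB> relation <TAB> target`.
#'
#' @param net An igraph network.
#' @param path Output path.
#' @param relation Relation label placed in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, relation = "interacts") {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1L], relation, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export a graph in GraphML
#' @param net An igraph network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
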