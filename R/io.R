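#' Read an edge list file
#'
#' Parses whitespace-, tab- or comma-delimited edge lists (the SNAP dialect:
#' one edge per line, `#` comments). The result is coerced to an undirected
#' simple graph: duplicate and reversed edge lines are collapsed and
#' self-loops are dropped with a message reporting their count. Node labels
#' are kept verbatim as character strings.
#'
#' @param path file path.
#' @param comment comment prefix (lines starting with it are ignored).
#' @param sep delimiter: `NULL` (any whitespace) or a single character such
#'   as `","`.
#' @return An undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path, comment = "#", sep = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  lines <- trimws(lines[keep])
  if (length(lines) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- if (is.null(sep)) strsplit(lines, "[[:space:]]+")
           else strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad))
    stop("malformed edge line ", which(keep)[bad[1]], ": ",
         lines[bad[1]])
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  loops <- from == to
  if (any(loops))
    message("dropped ", sum(loops), " self-loop line(s)")
  from <- from[!loops]; to <- to[!loops]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a square adjacency matrix from CSV
#'
#' Expects a header row and a first column of region/node labels. An edge is
#' present whenever either of the two mirrored entries is positive
#' (symmetrisation by OR); weights are discarded and diagonal entries
#' ignored.
#'
#' @param path file path.
#' @return An undirected simple `igraph` graph.
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(M) != ncol(M))
    stop("adjacency matrix is not square (", nrow(M), " x ", ncol(M), ")")
  storage.mode(M) <- "double"
  A <- (M > 0) | (t(M) > 0)
  diag(A) <- FALSE
  dimnames(A) <- NULL
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "max")
  igraph::V(g)$name <- labels
  g
}

#' Read a two-column interaction table
#'
#' Generic loader for tab-delimited interaction tables (for example
#' protein-complex interaction exports): two identifier columns define the
#' edges, all other columns are ignored.
#'
#' @param path file path.
#' @param id_cols integer positions of the two identifier columns.
#' @param sep field separator.
#' @param header whether the file has a header line.
#' @return An undirected simple `igraph` graph.
#' @export
read_interaction_table <- function(path, id_cols = c(1, 2), sep = "\t",
                                   header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  from <- as.character(df[[id_cols[1]]])
  to <- as.character(df[[id_cols[2]]])
  loops <- from == to
  if (any(loops)) message("dropped ", sum(loops), " self-interaction(s)")
  g <- igraph::graph_from_edgelist(cbind(from[!loops], to[!loops]),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; among size-tied
#' components the one containing the lexicographically smallest node label
#' wins.
#'
#' @param graph an `igraph` graph.
#' @return An `igraph` graph.
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    nm <- graph_names(graph)
    min_label <- vapply(best, function(b)
      min(nm[comp$membership == b]), character(1))
    best <- best[order(min_label)][1]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' Write a graph as GraphML
#'
#' Thin wrapper for visualisation exports.
#'
#' @param graph an `igraph` graph.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write/read an edge list
#'
#' @param graph an `igraph` graph.
#' @param path file path.
#' @param sep delimiter used between the two endpoints.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, sep = "\t") {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = sep), path)
  invisible(path)
}
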