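#' Multifractal generating measure
#'
#' Constructs the parameter object of the multifractal network generator
#' (MFNG). A measure consists of `m` base categories, a recursion depth `k`,
#' a symmetric `m x m` matrix `P` of base link probabilities and a length-`m`
#' probability vector `L` over categories. Every node carries a length-`k`
#' category sequence; the probability of a link between two nodes is the
#' product over levels of the `P` entries indexed by their category pair.
#'
#' Entries of `P` are clamped into `[clamp, 1 - clamp]` so that all log
#' likelihood terms stay finite and gradient ascent cannot push a probability
#' onto the boundary.
#'
#' @param m integer >= 2, number of base categories.
#' @param k integer >= 1, recursion depth.
#' @param P numeric `m x m` symmetric matrix with entries in (0, 1).
#' @param L numeric length-`m` vector of category weights summing to 1.
#'   Defaults to the uniform vector. `L` is held fixed during fitting; only
#'   `P` is optimised.
#' @param clamp numeric, half-width of the forbidden zone around 0 and 1.
#' @return An object of class `mfng_measure` with fields `m`, `k`, `P`, `L`,
#'   `clamp`.
#' @examples
#' mfng_measure(2, 3, matrix(c(0.5, 0.2, 0.2, 0.9), 2))
#' @export
mfng_measure <- function(m, k, P, L = rep(1 / m, m), clamp = 1e-4) {
  m <- as.integer(m)
  k <- as.integer(k)
  if (m < 2L) stop("'m' must be at least 2")
  if (k < 1L) stop("'k' must be at least 1")
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) != m || ncol(P) != m)
    stop("'P' must be a numeric ", m, " x ", m, " matrix")
  if (max(abs(P - t(P))) > 1e-12) stop("'P' must be symmetric")
  if (!is.numeric(clamp) || clamp <= 0 || clamp >= 0.5)
    stop("'clamp' must lie in (0, 0.5)")
  P <- clamp_probability(P, clamp)
  P <- (P + t(P)) / 2
  L <- as.numeric(L)
  if (length(L) != m || any(L < 0)) stop("'L' must be a nonnegative length-", m, " vector")
  if (abs(sum(L) - 1) > 1e-9) stop("'L' must sum to 1 (tolerance 1e-9)")
  structure(list(m = m, k = k, P = P, L = L, clamp = clamp),
            class = "mfng_measure")
}

clamp_probability <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

#' @export
print.mfng_measure <- function(x, ...) {
  cat("MFNG generating measure: m =", x$m, ", k =", x$k,
      "(", x$m^x$k, "category sequences )\n")
  cat("P:\n")
  print(round(x$P, 4))
  cat("L:", round(x$L, 4), "\n")
  invisible(x)
}

#' Draw a randomised generating measure
#'
#' Upper-triangle entries of `P` (diagonal included) are drawn i.i.d. from
#' `Uniform(range[1], range[2])` and symmetrised; `L` defaults to uniform.
#' Used both to generate ground-truth measures for synthetic studies and to
#' initialise EM runs.
#'
#' @inheritParams mfng_measure
#' @param range numeric length-2, bounds of the uniform draw.
#' @return An `mfng_measure`.
#' @export
random_mfng_measure <- function(m, k, range = c(0.1, 0.9), L = rep(1 / m, m),
                                clamp = 1e-4) {
  m <- as.integer(m)
  P <- matrix(0, m, m)
  up <- upper.tri(P, diag = TRUE)
  P[up] <- stats::runif(sum(up), range[1], range[2])
  P <- P + t(P) - diag(diag(P))
  mfng_measure(m, k, P, L, clamp)
}

#' Read/write a generating measure as JSON
#'
#' The on-disk form is a plain JSON document with fields `m`, `k`, `P`
#' (row-major), `L` and `clamp`; reading a written file round-trips exactly.
#'
#' @param measure an `mfng_measure`.
#' @param path file path.
#' @return `read_mfng_measure` returns an `mfng_measure`;
#'   `write_mfng_measure` returns `path` invisibly.
#' @export
write_mfng_measure <- function(measure, path) {
  stopifnot(inherits(measure, "mfng_measure"))
  doc <- list(m = measure$m, k = measure$k,
              P = as.numeric(t(measure$P)),  # row-major
              L = measure$L, clamp = measure$clamp)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mfng_measure
#' @export
read_mfng_measure <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.integer(doc$m)
  P <- matrix(as.numeric(doc$P), m, m, byrow = TRUE)
  mfng_measure(m, doc$k, P, as.numeric(doc$L), as.numeric(doc$clamp))
}

#' Category assignment
#'
#' An assignment maps every node (observed node or latent slot) to a
#' length-`k` category sequence. It is stored as a `k x n` integer matrix
#' with one column per node; column names are the node identifiers.
#'
#' @param sequences integer `k x n` matrix with entries in `1..m`.
#' @param m number of base categories the sequences refer to.
#' @param nodes optional character vector of node identifiers (defaults to
#'   existing column names, or `v1..vn`).
#' @return An object of class `mfng_assignment` (an integer matrix with
#'   attribute `m`).
#' @export
mfng_assignment <- function(sequences, m, nodes = NULL) {
  sequences <- as.matrix(sequences)
  storage.mode(sequences) <- "integer"
  if (any(sequences < 1L) || any(sequences > m))
    stop("category levels must lie in 1..m")
  if (is.null(nodes)) nodes <- colnames(sequences)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(ncol(sequences)))
  if (length(nodes) != ncol(sequences) || anyDuplicated(nodes))
    stop("'nodes' must name each column uniquely")
  colnames(sequences) <- as.character(nodes)
  structure(sequences, m = as.integer(m), class = "mfng_assignment")
}

#' @export
print.mfng_assignment <- function(x, ...) {
  cat("MFNG assignment:", ncol(x), "nodes, k =", nrow(x),
      ", m =", attr(x, "m"), "\n")
  invisible(x)
}

assignment_nodes <- function(assignment) colnames(assignment)

#' Sample category sequences from the length measure
#'
#' Each level of each sequence is drawn independently from the categorical
#' distribution with weights `L`. This is the prior over assignments when
#' node categories are not enumerated.
#'
#' @param measure an `mfng_measure`.
#' @param n number of nodes.
#' @param nodes optional node identifiers.
#' @return An `mfng_assignment` over `n` nodes.
#' @export
sample_categories <- function(measure, n, nodes = NULL) {
  stopifnot(inherits(measure, "mfng_measure"), n >= 1)
  seqs <- matrix(sample.int(measure$m, measure$k * n, replace = TRUE,
                            prob = measure$L),
                 nrow = measure$k, ncol = n)
  mfng_assignment(seqs, measure$m, nodes)
}

#' Enumerate all category sequences exactly once
#'
#' Returns the assignment in which each of the `m^k` distinct category
#' sequences appears exactly once. This is the natural assignment for
#' networks whose size equals `m^k` (the default in the synthetic studies).
#'
#' @inheritParams sample_categories
#' @return An `mfng_assignment` over `m^k` nodes.
#' @export
enumerate_categories <- function(measure, nodes = NULL) {
  stopifnot(inherits(measure, "mfng_measure"))
  grid <- as.matrix(expand.grid(rep(list(seq_len(measure$m)), measure$k)))
  mfng_assignment(t(grid), measure$m, nodes)
}

#' Link probability between two category sequences
#'
#' The MFNG link probability is the product over recursion levels of the
#' base matrix entries indexed by the two sequences:
#' `p(ci, cj) = prod_l P[ci(l), cj(l)]`. It is symmetric in its arguments.
#'
#' @param measure an `mfng_measure`.
#' @param ci,cj integer vectors of length `k` with entries in `1..m`.
#' @return A probability in (0, 1).
#' @examples
#' g <- mfng_measure(2, 1, matrix(c(0.5, 0.2, 0.2, 0.9), 2))
#' link_probability(g, 1, 2)  # 0.2
#' @export
link_probability <- function(measure, ci, cj) {
  stopifnot(inherits(measure, "mfng_measure"))
  ci <- as.integer(ci); cj <- as.integer(cj)
  if (length(ci) != measure$k || length(cj) != measure$k)
    stop("category sequences must have length k = ", measure$k)
  if (any(ci < 1L | ci > measure$m) || any(cj < 1L | cj > measure$m))
    stop("category levels must lie in 1..m")
  prod(measure$P[cbind(ci, cj)])
}

#' Pairwise link-probability matrix for an assignment
#'
#' @param measure an `mfng_measure`.
#' @param assignment an `mfng_assignment`.
#' @return A symmetric `n x n` matrix of link probabilities (diagonal set to
#'   `NA`; self-links are never drawn).
#' @export
link_probability_matrix <- function(measure, assignment) {
  stopifnot(inherits(measure, "mfng_measure"))
  k <- measure$k
  if (nrow(assignment) != k)
    stop("assignment depth does not match measure k")
  n <- ncol(assignment)
  Pm <- matrix(1, n, n)
  for (l in seq_len(k)) {
    cl <- assignment[l, ]
    Pm <- Pm * measure$P[cl, cl, drop = FALSE]
  }
  dimnames(Pm) <- list(colnames(assignment), colnames(assignment))
  diag(Pm) <- NA_real_
  Pm
}

#' Sample a network from the model
#'
#' Links every unordered pair of assigned nodes independently with its MFNG
#' link probability; the result is an undirected simple graph with no
#' self-loops.
#'
#' @param measure an `mfng_measure`.
#' @param assignment an `mfng_assignment` giving each node its sequence.
#' @return An `igraph` graph whose vertex names are the assignment's nodes.
#' @export
sample_network <- function(measure, assignment) {
  Pm <- link_probability_matrix(measure, assignment)
  n <- ncol(Pm)
  A <- matrix(FALSE, n, n)
  up <- upper.tri(A)
  A[up] <- stats::runif(sum(up)) < Pm[up]
  A <- A | t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- colnames(Pm)
  g
}

# Adjacency matrix of `graph` with rows/cols in the order of `nodes`.
graph_adjacency <- function(graph, nodes = NULL) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  A[A > 1] <- 1
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(nrow(A)))
  dimnames(A) <- list(nm, nm)
  if (!is.null(nodes)) {
    if (!all(nodes %in% nm)) stop("graph is missing nodes named in the assignment")
    A <- A[nodes, nodes, drop = FALSE]
  }
  A
}

graph_names <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(graph))) else nm
}

#' Model log-likelihood of a graph
#'
#' Sum over linked pairs of `log p_ij` plus sum over unlinked pairs of
#' `log(1 - p_ij)`, with `p_ij` the MFNG link probability under the given
#' assignment. All vertices of `graph` must be assigned.
#'
#' @param measure an `mfng_measure`.
#' @param graph an undirected `igraph` graph.
#' @param assignment an `mfng_assignment` covering every vertex of `graph`.
#' @return The log-likelihood (a nonpositive number; 0 for a single node).
#' @export
model_log_likelihood <- function(measure, graph, assignment) {
  nodes <- graph_names(graph)
  if (!all(nodes %in% colnames(assignment)))
    stop("every node of the graph must appear in the assignment")
  sub <- mfng_assignment(assignment[, nodes, drop = FALSE], attr(assignment, "m"))
  A <- graph_adjacency(graph, nodes)
  Pm <- link_probability_matrix(measure, sub)
  up <- upper.tri(A)
  sum(A[up] * log(Pm[up]) + (1 - A[up]) * log1p(-Pm[up]))
}

#' Gradient of the model log-likelihood in the generating measure
#'
#' Returns the `m x m` symmetric matrix of partial derivatives of
#' [model_log_likelihood()] with respect to the free entries of `P` (one
#' parameter per unordered category pair; both matrix entries of an
#' off-diagonal pair carry the same derivative). For a linked pair the
#' contribution of category pair `{a,b}` is `n_ab / P[a,b]`, where `n_ab`
#' counts the levels at which the two sequences show that category pair; for
#' an unlinked pair it is `-n_ab * p / ((1 - p) * P[a,b])`.
#'
#' @inheritParams model_log_likelihood
#' @return An `m x m` numeric matrix.
#' @export
gradient_log_likelihood <- function(measure, graph, assignment) {
  nodes <- graph_names(graph)
  if (!all(nodes %in% colnames(assignment)))
    stop("every node of the graph must appear in the assignment")
  sub <- assignment[, nodes, drop = FALSE]
  A <- graph_adjacency(graph, nodes)
  gradient_from_adjacency(measure, A, sub)
}

# Core gradient: A is a 0/1 adjacency matrix aligned with the columns of
# `sequences` (k x n integer matrix).
gradient_from_adjacency <- function(measure, A, sequences) {
  m <- measure$m; k <- measure$k
  n <- ncol(sequences)
  if (n < 2)
    return(matrix(0, m, m))
  Pm <- matrix(1, n, n)
  for (l in seq_len(k)) {
    cl <- sequences[l, ]
    Pm <- Pm * measure$P[cl, cl, drop = FALSE]
  }
  diag(Pm) <- 0.5  # placeholder, masked below
  W <- A - (1 - A) * Pm / (1 - Pm)
  diag(W) <- 0
  C <- matrix(0, m, m)
  for (l in seq_len(k)) {
    Z <- matrix(0, n, m)
    Z[cbind(seq_len(n), sequences[l, ])] <- 1
    C <- C + crossprod(Z, W %*% Z)
  }
  G <- (C + t(C)) / 2
  diag(G) <- diag(G) / 2
  G / measure$P
}
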