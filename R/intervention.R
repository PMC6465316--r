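#' Adversarial intervention model
#'
#' The attacker removes one node per step; the victim at each step is drawn
#' with probability proportional to `degree^alpha`, evaluated on the current
#' residual network, so the removal process is a time-inhomogeneous Markov
#' chain. `alpha > 0` prioritises hubs, `alpha < 0` boundary nodes and
#' `alpha = 0` is a uniformly random attack. The discount factor `gamma`
#' weighs the attack term of the complete-data log-likelihood: `gamma = 0`
#' reproduces the attack-blind baseline, `gamma = 1` the full causal
#' likelihood.
#'
#' @param alpha real exponent of the removal distribution; `Inf`/`-Inf` are
#'   accepted and mean "always a maximum/minimum-degree node" (ties uniform).
#' @param gamma nonnegative weight of the attack log-likelihood term.
#' @return An object of class `intervention_model`.
#' @export
intervention_model <- function(alpha, gamma = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, !is.na(alpha))
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma), class = "intervention_model")
}

#' @export
print.intervention_model <- function(x, ...) {
  cat("Intervention model: alpha =", x$alpha, ", gamma =", x$gamma, "\n")
  invisible(x)
}

# Unnormalised removal weights for a degree vector. Conventions:
#   alpha == 0      -> every node has weight 1 (uniform attack);
#   alpha != 0      -> only nodes with d > 0 are eligible (0^alpha is 0 for
#                      alpha > 0 and undefined for alpha < 0; the model does
#                      not allow disconnected nodes);
#   alpha = +-Inf   -> point mass spread over the max/min positive degrees.
# Computed on a log scale so large |alpha| does not overflow.
attack_weights <- function(degrees, alpha) {
  w <- numeric(length(degrees))
  if (alpha == 0) {
    w[] <- 1
    return(w)
  }
  pos <- which(degrees > 0)
  if (length(pos) == 0) return(w)
  d <- degrees[pos]
  if (is.infinite(alpha)) {
    tgt <- if (alpha > 0) max(d) else min(d)
    w[pos][d == tgt] <- 1
  } else {
    lw <- alpha * log(d)
    w[pos] <- exp(lw - max(lw))
  }
  w
}

#' Per-node removal probabilities
#'
#' Probability of each node of `graph` to be the next victim under the
#' degree-power attack distribution with exponent `alpha`. Ineligible nodes
#' (isolated nodes when `alpha != 0`) receive probability 0.
#'
#' @param graph an undirected `igraph` graph.
#' @param alpha attack exponent.
#' @return A named probability vector over the vertices (sums to 1).
#' @examples
#' g <- igraph::graph_from_edgelist(cbind(c("a","a","b"), c("b","c","c")),
#'                                  directed = FALSE)
#' attack_distribution(g, 1)
#' @export
attack_distribution <- function(graph, alpha) {
  if (igraph::vcount(graph) == 0) stop("graph has no nodes")
  d <- igraph::degree(graph)
  w <- attack_weights(as.numeric(d), alpha)
  if (sum(w) == 0)
    stop("no eligible node: all nodes are isolated and alpha != 0")
  p <- w / sum(w)
  names(p) <- graph_names(graph)
  p
}

#' Removal trajectory
#'
#' The time-ordered record of an attack: one event per step holding the
#' victim's identifier, its incident edges (as the neighbor list at removal
#' time) and its degree at removal time. Applying the events in order to the
#' original network yields the residual network; the union of the event
#' subgraphs with the residual network reconstructs the original.
#'
#' @param events list of events, each a list with elements `victim`
#'   (character scalar), `neighbors` (character vector) and optionally
#'   `degree` (recomputed from `neighbors` if missing).
#' @param residual the residual `igraph` graph left after the last event
#'   (optional but required by [attack_log_likelihood()] and
#'   [reconstruct_original()]).
#' @return An object of class `removal_trajectory`.
#' @export
removal_trajectory <- function(events, residual = NULL) {
  events <- lapply(events, function(ev) {
    ev$victim <- as.character(ev$victim)
    ev$neighbors <- as.character(ev$neighbors)
    if (ev$victim %in% ev$neighbors) stop("self-loop in a removal event")
    ev$degree <- length(ev$neighbors)
    ev[c("victim", "neighbors", "degree")]
  })
  victims <- vapply(events, `[[`, character(1), "victim")
  if (anyDuplicated(victims)) stop("a node cannot be removed twice")
  structure(list(events = events, residual = residual),
            class = "removal_trajectory")
}

#' @export
length.removal_trajectory <- function(x) length(x$events)

#' @export
print.removal_trajectory <- function(x, ...) {
  cat("Removal trajectory:", length(x$events), "events\n")
  for (ev in utils::head(x$events, 5))
    cat("  -", ev$victim, "(degree", ev$degree, ")\n")
  if (length(x$events) > 5) cat("  ...\n")
  invisible(x)
}

trajectory_victims <- function(trajectory)
  vapply(trajectory$events, `[[`, character(1), "victim")

#' Rebuild the original network from a trajectory
#'
#' Restores the removed nodes and their incident edges, last removed first,
#' on top of the residual graph.
#'
#' @param trajectory a `removal_trajectory`.
#' @param residual the residual graph; defaults to the one stored in the
#'   trajectory.
#' @return The reconstructed original `igraph` graph.
#' @export
reconstruct_original <- function(trajectory, residual = trajectory$residual) {
  if (is.null(residual)) stop("no residual graph available")
  g <- residual
  for (ev in rev(trajectory$events)) {
    g <- igraph::add_vertices(g, 1, name = ev$victim)
    if (length(ev$neighbors)) {
      if (!all(ev$neighbors %in% graph_names(g)))
        stop("event neighbors not present when restoring node ", ev$victim)
      g <- igraph::add_edges(g, rbind(ev$victim, ev$neighbors))
    }
  }
  g
}

#' Simulate a sequential attack
#'
#' Runs `steps` removals: at each step the victim is drawn from
#' [attack_distribution()] of the *current* residual graph, then deleted
#' together with its incident edges.
#'
#' @param graph the original undirected `igraph` graph.
#' @param alpha attack exponent.
#' @param steps number of nodes to remove (`< vcount(graph)`).
#' @return A list with elements `residual` (the attacked graph) and
#'   `trajectory` (a `removal_trajectory` whose `residual` field is set).
#' @export
simulate_attack <- function(graph, alpha, steps) {
  n <- igraph::vcount(graph)
  stopifnot(steps >= 0, steps < n)
  nodes <- graph_names(graph)
  A <- graph_adjacency(graph, nodes)
  present <- rep(TRUE, n)
  deg <- rowSums(A)
  events <- vector("list", steps)
  for (s in seq_len(steps)) {
    w <- attack_weights(deg[present], alpha)
    if (sum(w) == 0)
      stop("no eligible node at step ", s, ": all remaining nodes are isolated")
    idx_present <- which(present)
    victim <- idx_present[sample.int(length(idx_present), 1, prob = w)]
    nbrs <- which(A[victim, ] > 0 & present)
    events[[s]] <- list(victim = nodes[victim], neighbors = nodes[nbrs])
    deg[nbrs] <- deg[nbrs] - 1
    deg[victim] <- 0
    present[victim] <- FALSE
  }
  residual <- igraph::induced_subgraph(graph, which(present))
  list(residual = residual,
       trajectory = removal_trajectory(events, residual = residual))
}

#' Log-likelihood of a removal trajectory under the attack model
#'
#' Sum over events of the log removal probability of the victim in the
#' residual graph at that step. Returns `-Inf` when any victim has zero
#' removal probability (for example degree 0), i.e. the trajectory has no
#' posterior mass under the attack model.
#'
#' @param trajectory a `removal_trajectory` with its residual graph set (or
#'   pass `residual`).
#' @param alpha attack exponent.
#' @param residual residual graph override.
#' @return A log-probability (0 for an empty trajectory).
#' @export
attack_log_likelihood <- function(trajectory, alpha,
                                  residual = trajectory$residual) {
  if (length(trajectory$events) == 0) return(0)
  g0 <- reconstruct_original(trajectory, residual)
  nodes <- graph_names(g0)
  A <- graph_adjacency(g0, nodes)
  present <- rep(TRUE, length(nodes))
  names(present) <- nodes
  deg <- rowSums(A)
  ll <- 0
  for (ev in trajectory$events) {
    dpres <- deg[present]
    w <- attack_weights(as.numeric(dpres), alpha)
    tot <- sum(w)
    pv <- if (tot > 0) unname(w[match(ev$victim, names(dpres))]) / tot else 0
    if (is.na(pv) || pv <= 0) return(-Inf)
    ll <- ll + log(pv)
    nb <- intersect(ev$neighbors, nodes[present])
    deg[nb] <- deg[nb] - 1
    deg[ev$victim] <- 0
    present[ev$victim] <- FALSE
  }
  ll
}

#' Serialise a removal trajectory as text
#'
#' Line-oriented format, one event per line: the step index, the victim
#' identifier and the comma-separated neighbor identifiers, separated by
#' tabs. Node identifiers must not contain tabs or commas.
#'
#' @param trajectory a `removal_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `removal_trajectory` (with `residual` attached if supplied).
#' @export
write_trajectory <- function(trajectory, path) {
  lines <- vapply(seq_along(trajectory$events), function(s) {
    ev <- trajectory$events[[s]]
    paste(s, ev$victim, paste(ev$neighbors, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param residual optional residual graph to attach on read.
#' @export
read_trajectory <- function(path, residual = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  events <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed trajectory line: ", ln)
    nbrs <- if (length(parts) < 3 || !nzchar(parts[3])) character(0)
            else strsplit(parts[3], ",", fixed = TRUE)[[1]]
    list(victim = parts[2], neighbors = nbrs)
  })
  removal_trajectory(events, residual = residual)
}

#' Select injected nodes
#'
#' Labels `ceiling(share * n)` existing nodes as injected, sampling without
#' replacement with weight `degree^alpha` computed once on the full,
#' unchanged graph. Injection is a labelling process, not a removal process,
#' so weights are never depleted. With `alpha` large this concentrates the
#' injected set on the hubs; `alpha = 0` is a uniform subset.
#'
#' @param graph an undirected `igraph` graph.
#' @param share fraction of nodes to inject, in `[0, 1]`.
#' @param alpha degree exponent of the injection weights.
#' @return A character vector of injected node identifiers.
#' @export
select_injected_nodes <- function(graph, share, alpha) {
  stopifnot(share >= 0, share <= 1)
  nodes <- graph_names(graph)
  n_pick <- ceiling(share * length(nodes))
  if (n_pick == 0) return(character(0))
  if (n_pick >= length(nodes)) return(nodes)
  w <- attack_weights(as.numeric(igraph::degree(graph)), alpha)
  chosen <- character(0)
  if (any(w > 0)) {
    n_w <- min(n_pick, sum(w > 0))
    chosen <- nodes[sample.int(length(nodes), n_w, prob = w)]
  }
  if (length(chosen) < n_pick) {   # weights exhausted: fill uniformly
    rest <- setdiff(nodes, chosen)
    chosen <- c(chosen, sample(rest, n_pick - length(chosen)))
  }
  chosen
}

#' Coverage of an injected set
#'
#' Fraction of non-injected nodes with at least one injected immediate
#' neighbor. When every node is injected the coverage is 1 by convention
#' (no exposed user remains uncovered).
#'
#' @param graph an undirected `igraph` graph.
#' @param injected character vector of injected node identifiers (must be a
#'   subset of the vertices).
#' @return A fraction in `[0, 1]`.
#' @export
coverage <- function(graph, injected) {
  nodes <- graph_names(graph)
  injected <- as.character(injected)
  if (!all(injected %in% nodes)) stop("injected nodes must belong to the graph")
  users <- setdiff(nodes, injected)
  if (length(users) == 0) return(1)
  if (length(injected) == 0) return(0)
  affected_users(graph, injected) / length(users)
}

#' @rdname coverage
#' @return `affected_users` returns the integer count of non-injected nodes
#'   adjacent to at least one injected node.
#' @export
affected_users <- function(graph, injected) {
  nodes <- graph_names(graph)
  injected <- as.character(injected)
  if (!all(injected %in% nodes)) stop("injected nodes must belong to the graph")
  if (length(injected) == 0) return(0L)
  nb <- igraph::adjacent_vertices(graph, injected)
  touched <- unique(unlist(lapply(nb, function(v) graph_names(graph)[as.integer(v)])))
  length(setdiff(touched, injected))
}
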