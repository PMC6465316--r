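# Shared fixtures, built in code.

toy_measure <- function() {
  mfng_measure(2, 1, matrix(c(0.5, 0.2, 0.2, 0.9), 2))
}

# Small residual graph a-b-c plus a fixed assignment over the observed
# nodes and `steps` latent slots (multiset 1,1,2,2,...).
tiny_instance <- function(steps = 2, k = 1) {
  obs <- igraph::graph_from_edgelist(cbind(c("a", "b"), c("b", "c")),
                                     directed = FALSE)
  nodes <- c("a", "b", "c", latent_slot_names(steps))
  codes <- rep(c(1L, 2L), length.out = length(nodes))
  asg <- mfng_assignment(matrix(rep(codes, each = k), nrow = k), 2, nodes)
  list(observed = obs,
       measure = mfng_measure(2, k,
                              matrix(c(0.6, 0.25, 0.25, 0.45), 2)),
       assignment = asg, steps = steps)
}

edge_key_set <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "~"))
}

# Empirical state distribution of a posterior pool.
pool_state_table <- function(pool, observed, steps) {
  keys <- vapply(pool$samples, posterior_state_key, character(1),
                 observed = observed, steps = steps)
  table(keys) / length(keys)
}

tv_distance <- function(emp, exact) {
  e <- as.numeric(emp[exact$state])
  e[is.na(e)] <- 0
  stray <- sum(as.numeric(emp[!(names(emp) %in% exact$state)]))
  0.5 * sum(abs(e - exact$prob)) + 0.5 * stray
}
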