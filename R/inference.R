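#' Names of the latent slots
#'
#' Removed nodes are anonymised: the sampler works with latent slots indexed
#' by removal time (slot `s` is the node removed at step `s`). These are the
#' identifiers used for slots throughout the inference interface.
#'
#' @param steps number of removed nodes `T`.
#' @return A character vector of length `steps`.
#' @export
latent_slot_names <- function(steps) {
  if (steps < 1) return(character(0))
  paste0("latent_", seq_len(steps))
}

# ---- internal sampler state ---------------------------------------------
#
# Nodes are ordered: observed nodes first (in graph order), then slots in
# removal order. `A` is the 0/1 adjacency of the candidate original network;
# the observed block is fixed, slot-incident entries are the latent part.
# Slot s is present in the residual graph before step r iff s >= r.

build_state <- function(measure, observed, assignment, steps, model,
                        trajectory = NULL) {
  obs_nodes <- graph_names(observed)
  slots <- latent_slot_names(steps)
  if (any(slots %in% obs_nodes))
    stop("observed node names clash with latent slot names")
  nodes <- c(obs_nodes, slots)
  if (!all(nodes %in% colnames(assignment)))
    stop("assignment must cover every observed node and latent slot")
  assignment <- assignment[, nodes, drop = FALSE]
  n_obs <- length(obs_nodes)
  N <- n_obs + steps
  A <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  if (n_obs > 0)
    A[seq_len(n_obs), seq_len(n_obs)] <- graph_adjacency(observed, obs_nodes)
  if (!is.null(trajectory)) {
    if (length(trajectory$events) != steps)
      stop("trajectory length does not match 'steps'")
    for (s in seq_len(steps)) {
      ev <- trajectory$events[[s]]
      if (!identical(ev$victim, slots[s]))
        stop("trajectory victims must be the latent slots in removal order")
      idx <- match(ev$neighbors, nodes)
      if (anyNA(idx)) stop("unknown neighbor in trajectory event ", s)
      bad <- idx > n_obs & idx <= n_obs + s - 1
      if (any(bad))
        stop("event ", s, " links to a slot already removed at that step")
      A[n_obs + s, idx] <- 1L
      A[idx, n_obs + s] <- 1L
    }
  }
  Pmat <- link_probability_matrix(measure,
                                  mfng_assignment(assignment, measure$m))
  diag(Pmat) <- 0
  list(measure = measure, model = model, nodes = nodes, n_obs = n_obs,
       T = steps, N = N, A = A, assign = assignment, Pmat = Pmat)
}

# Partner indices of slot s: nodes present just after its removal is undone
# (all observed nodes plus slots removed later).
slot_partners <- function(st, s) {
  c(seq_len(st$n_obs),
    if (s < st$T) st$n_obs + (s + 1L):st$T else integer(0))
}

state_model_ll <- function(st) {
  up <- upper.tri(st$A)
  sum(st$A[up] * log(st$Pmat[up]) + (1 - st$A[up]) * log1p(-st$Pmat[up]))
}

# Attack log-likelihood (unweighted by gamma) of the trajectory encoded in
# the state's adjacency; -Inf when some victim has zero removal probability.
state_attack_ll <- function(st) {
  deg <- rowSums(st$A)
  present <- rep(TRUE, st$N)
  ll <- 0
  for (s in seq_len(st$T)) {
    v <- st$n_obs + s
    w <- attack_weights(deg[present], st$model$alpha)
    tot <- sum(w)
    pv <- if (tot > 0) w[match(v, which(present))] / tot else 0
    if (is.na(pv) || pv <= 0) return(-Inf)
    ll <- ll + log(pv)
    nb <- which(st$A[v, ] > 0 & present)
    deg[nb] <- deg[nb] - 1
    deg[v] <- 0
    present[v] <- FALSE
  }
  ll
}

state_complete_ll <- function(st) {
  att <- state_attack_ll(st)
  if (!is.finite(att)) return(-Inf)
  state_model_ll(st) + st$model$gamma * att
}

state_trajectory <- function(st, observed) {
  events <- lapply(seq_len(st$T), function(s) {
    partners <- slot_partners(st, s)
    nbrs <- partners[st$A[st$n_obs + s, partners] == 1L]
    list(victim = st$nodes[st$n_obs + s], neighbors = st$nodes[nbrs])
  })
  removal_trajectory(events, residual = observed)
}

#' One posterior sample of the latent structure
#'
#' Bundles a removal trajectory over latent slots, a category assignment
#' over observed nodes and slots, and the cached log-likelihood terms.
#'
#' @param trajectory a `removal_trajectory` whose victims are the latent
#'   slots in removal order.
#' @param assignment an `mfng_assignment` covering observed nodes and slots.
#' @param model_ll,attack_ll,complete_ll cached log-likelihood components.
#' @return An object of class `posterior_sample`.
#' @export
posterior_sample <- function(trajectory, assignment, model_ll = NA_real_,
                             attack_ll = NA_real_, complete_ll = NA_real_) {
  structure(list(trajectory = trajectory, assignment = assignment,
                 model_ll = model_ll, attack_ll = attack_ll,
                 complete_ll = complete_ll),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", length(x$trajectory$events), "latent slots,",
      "complete log-likelihood", format(x$complete_ll), "\n")
  invisible(x)
}

#' Complete-data log-likelihood
#'
#' The joint log-likelihood of the reconstructed original network and the
#' removal trajectory: the MFNG model term over all node pairs of the
#' candidate original graph plus `gamma` times the attack term. Returns
#' `-Inf` when any removal event has zero probability under the attack model
#' (such trajectories carry no posterior mass for any `gamma`).
#'
#' @param measure an `mfng_measure`.
#' @param observed the residual (observed) `igraph` graph.
#' @param sample a `posterior_sample` (or a list with `trajectory` and
#'   `assignment`).
#' @param model an `intervention_model`.
#' @return A log-likelihood value.
#' @export
complete_log_likelihood <- function(measure, observed, sample, model) {
  st <- build_state(measure, observed, sample$assignment,
                    length(sample$trajectory$events), model,
                    trajectory = sample$trajectory)
  state_complete_ll(st)
}

# ---- trajectory sampling (recursive rejection) ---------------------------

# Draw one restoration proposal for a slot: independent Bernoulli links to
# the present nodes. Returns the 0/1 link vector over `partners`.
propose_slot_links <- function(pvec) as.integer(stats::runif(length(pvec)) < pvec)

#' Rejection-sample a removal trajectory
#'
#' Samples the latent removal path conditional on the assignment: slots are
#' restored in reverse removal order; each restoration proposes links to the
#' currently present nodes independently with their MFNG link probabilities
#' (redrawn until the restored node has degree at least one), and is then
#' tested against the attack transition probability of the restored node in
#' the proposed residual graph, raised to `gamma`. A failed test restarts
#' the whole restoration pass, so the path acceptance probability is exactly
#' the product of the per-step attack probabilities and accepted paths are
#' exact draws from the trajectory posterior given the assignment. (A
#' per-slot retry would instead bias the draw: the attack acceptance rate of
#' a slot depends on the links of the slots restored before it.)
#'
#' @param measure an `mfng_measure`.
#' @param assignment an `mfng_assignment` covering observed nodes and the
#'   latent slots.
#' @param observed the residual `igraph` graph.
#' @param model an `intervention_model`.
#' @param steps number of latent slots `T`.
#' @param max_proposals budget of full restoration passes; exceeding it
#'   raises an error suggesting a larger budget or a review of `gamma`.
#' @return A `removal_trajectory` over the latent slots.
#' @export
sample_trajectory <- function(measure, assignment, observed, model, steps,
                              max_proposals = 1000) {
  st <- build_state(measure, observed, assignment, steps, model)
  if (steps == 0) return(removal_trajectory(list(), residual = observed))
  base_deg <- rowSums(st$A)
  const_acc <- st$model$gamma == 0 || st$model$alpha == 0
  for (pass in seq_len(max_proposals)) {
    deg <- base_deg
    links_list <- vector("list", steps)
    ok <- TRUE
    for (s in rev(seq_len(steps))) {
      v <- st$n_obs + s
      partners <- slot_partners(st, s)
      pvec <- st$Pmat[v, partners]
      d <- 0
      for (trial in 1:200) {   # degree >= 1 (constant normaliser per slot)
        links <- propose_slot_links(pvec)
        d <- sum(links)
        if (d > 0) break
      }
      if (d == 0) { ok <- FALSE; break }
      if (!const_acc) {
        # acceptance varies with the proposal: test here, restart the whole
        # pass on failure
        degp <- deg
        degp[partners] <- degp[partners] + links
        degp[v] <- d
        pres <- c(seq_len(st$n_obs), st$n_obs + s:st$T)
        w <- attack_weights(degp[pres], st$model$alpha)
        acc <- (w[match(v, pres)] / sum(w))^st$model$gamma
        if (stats::runif(1) >= acc) { ok <- FALSE; break }
      }
      links_list[[s]] <- links
      deg[partners] <- deg[partners] + links
      deg[v] <- d
    }
    if (ok) {
      for (s in seq_len(steps)) {
        v <- st$n_obs + s
        partners <- slot_partners(st, s)
        st$A[v, partners] <- links_list[[s]]
        st$A[partners, v] <- links_list[[s]]
      }
      return(state_trajectory(st, observed))
    }
  }
  stop("trajectory rejection sampler exhausted its proposal budget (",
       max_proposals, " restoration passes); increase 'max_proposals', ",
       "rely on refine_trajectory(), or review gamma")
}

#' Metropolis rewiring of a removal trajectory
#'
#' For each removal event, `n_steps` rewiring moves: an incident edge
#' `(i, j)` of the restored node is picked uniformly (probability `1/d(i)`),
#' a replacement endpoint `j'` is proposed among the currently non-adjacent
#' present nodes (plus `j` itself, the identity move) with probability
#' proportional to the link probability `p(i, j')`, and the move is accepted
#' with the Metropolis ratio of the trajectory posterior. Node degrees are
#' preserved, the graph stays simple, and the chain leaves the conditional
#' trajectory distribution invariant. Events whose node has degree zero are
#' skipped.
#'
#' @param trajectory a `removal_trajectory` over the latent slots.
#' @inheritParams sample_trajectory
#' @param n_steps number of moves per event.
#' @return The refined `removal_trajectory`.
#' @export
refine_trajectory <- function(trajectory, measure, assignment, observed,
                              model, n_steps) {
  steps <- length(trajectory$events)
  st <- build_state(measure, observed, assignment, steps, model, trajectory)
  att_ll <- state_attack_ll(st)
  for (s in seq_len(steps)) {
    v <- st$n_obs + s
    partners <- slot_partners(st, s)
    for (move in seq_len(n_steps)) {
      nbrs <- partners[st$A[v, partners] == 1L]
      if (length(nbrs) == 0) break
      j <- if (length(nbrs) == 1) nbrs else sample(nbrs, 1)
      elig <- c(partners[st$A[v, partners] == 0L], j)
      wts <- st$Pmat[v, elig]
      jp <- if (length(elig) == 1) elig else sample(elig, 1, prob = wts)
      if (jp == j) next
      Anew <- st$A
      Anew[v, j] <- Anew[j, v] <- 0L
      Anew[v, jp] <- Anew[jp, v] <- 1L
      stnew <- st; stnew$A <- Anew
      att_new <- state_attack_ll(stnew)
      datt <- att_new - att_ll
      if (is.nan(datt)) datt <- 0  # move between two zero-mass states
      dmodel <- log(st$Pmat[v, jp]) - log1p(-st$Pmat[v, jp]) -
                log(st$Pmat[v, j]) + log1p(-st$Pmat[v, j])
      att_part <- if (st$model$gamma == 0) 0 else st$model$gamma * datt
      lr <- dmodel + att_part +
            log(st$Pmat[v, j]) - log(st$Pmat[v, jp])
      if (log(stats::runif(1)) < lr) {
        st$A <- Anew
        att_ll <- att_new
      }
    }
  }
  state_trajectory(st, observed)
}

#' Metropolis link-toggle moves on a removal trajectory
#'
#' The rewiring chain of [refine_trajectory()] preserves the degree of every
#' restored node, and at strong attack exponents the rejection sampler's
#' path acceptance is vanishingly small, so degrees would otherwise stay
#' frozen at their initial values. This complementary chain proposes, for
#' each removal event, toggling a single link between the restored node and
#' a uniformly chosen present node, and accepts with the Metropolis ratio of
#' the full trajectory posterior (model term plus `gamma` times the attack
#' term, whose victim degree and normalisers both change). Removing the last
#' link of a node is always rejected. Together with rewiring this makes the
#' trajectory chain irreducible over all latent link sets.
#'
#' @inheritParams refine_trajectory
#' @return The updated `removal_trajectory`.
#' @export
toggle_trajectory <- function(trajectory, measure, assignment, observed,
                              model, n_steps) {
  steps <- length(trajectory$events)
  st <- build_state(measure, observed, assignment, steps, model, trajectory)
  att_ll <- state_attack_ll(st)
  for (s in seq_len(steps)) {
    v <- st$n_obs + s
    partners <- slot_partners(st, s)
    for (move in seq_len(n_steps)) {
      u <- if (length(partners) == 1) partners else sample(partners, 1)
      adding <- st$A[v, u] == 0L
      if (!adding && sum(st$A[v, partners]) <= 1L) next  # keep degree >= 1
      Anew <- st$A
      Anew[v, u] <- Anew[u, v] <- if (adding) 1L else 0L
      stnew <- st; stnew$A <- Anew
      att_new <- state_attack_ll(stnew)
      datt <- att_new - att_ll
      if (is.nan(datt)) datt <- 0
      p <- st$Pmat[v, u]
      dmodel <- if (adding) log(p) - log1p(-p) else log1p(-p) - log(p)
      att_part <- if (st$model$gamma == 0) 0 else st$model$gamma * datt
      if (log(stats::runif(1)) < dmodel + att_part) {
        st$A <- Anew
        att_ll <- att_new
      }
    }
  }
  state_trajectory(st, observed)
}

#' Metropolis swap sampling of the category assignment
#'
#' `n_steps` iterations of: pick two distinct nodes/slots uniformly, swap
#' their category sequences, and accept with the Metropolis ratio of the
#' complete-data likelihood (the attack term does not depend on the
#' assignment, so only link probabilities involving the swapped pair enter).
#' The chain is reversible and preserves the multiset of category sequences.
#'
#' @param assignment an `mfng_assignment` covering observed nodes and slots.
#' @param trajectory a `removal_trajectory` over the latent slots.
#' @inheritParams sample_trajectory
#' @param n_steps number of proposed swaps.
#' @return The updated `mfng_assignment`.
#' @export
sample_assignment <- function(assignment, trajectory, measure, observed,
                              model, n_steps) {
  steps <- length(trajectory$events)
  st <- build_state(measure, observed, assignment, steps, model, trajectory)
  for (it in seq_len(n_steps)) {
    ij <- sample.int(st$N, 2)
    i <- ij[1]; j <- ij[2]
    if (identical(st$assign[, i], st$assign[, j])) next
    dl <- swap_delta(st, i, j)
    if (log(stats::runif(1)) < dl) {
      tmp <- st$assign[, i]; st$assign[, i] <- st$assign[, j]; st$assign[, j] <- tmp
      st$Pmat <- swap_pmat(st$Pmat, i, j)
    }
  }
  mfng_assignment(st$assign, st$measure$m)
}

# Model log-likelihood change caused by swapping the sequences of nodes i, j.
swap_delta <- function(st, i, j) {
  v <- setdiff(seq_len(st$N), c(i, j))
  pi <- st$Pmat[i, v]; pj <- st$Pmat[j, v]
  ai <- st$A[i, v]; aj <- st$A[j, v]
  sum((ai - aj) * (log(pj) - log(pi)) +
      ((1 - ai) - (1 - aj)) * (log1p(-pj) - log1p(-pi)))
}

swap_pmat <- function(Pmat, i, j) {
  Pmat[c(i, j), ] <- Pmat[c(j, i), ]
  Pmat[, c(i, j)] <- Pmat[, c(j, i)]
  Pmat
}

# ---- Gibbs driver --------------------------------------------------------

#' Configuration of the Monte-Carlo EM run
#'
#' @param K number of retained posterior samples per E-step.
#' @param B number of burn-in Gibbs sweeps discarded before collecting.
#' @param S number of gradient-ascent steps per M-step.
#' @param sigma gradient-ascent learning rate (halved when a step would
#'   decrease the Q-function).
#' @param refine_steps rewiring moves per removal event per sweep.
#' @param toggle_steps link-toggle moves per removal event per sweep (the
#'   degree-changing complement of the rewiring chain).
#' @param swap_steps assignment swap proposals per sweep.
#' @param proposal_budget per-slot proposal budget of the rejection sampler
#'   inside a sweep; when exhausted the sweep keeps the current trajectory
#'   and relies on the rewiring chain (set to 0 to disable fresh draws).
#' @param tol relative Q-change below which EM stops.
#' @param max_iter EM iteration cap.
#' @param engine `"cpp"` (compiled Gibbs kernel) or `"R"` (reference
#'   implementation; identical algorithm, much slower).
#' @return An object of class `em_config`.
#' @export
em_config <- function(K = 2000, B = 500, S = 10, sigma = 0.1,
                      refine_steps = 2, toggle_steps = 2, swap_steps = 30,
                      proposal_budget = 50, tol = 1e-3, max_iter = 50,
                      engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(K >= 1, B >= 0, S >= 1, sigma > 0, refine_steps >= 0,
            toggle_steps >= 0, swap_steps >= 0, proposal_budget >= 0,
            tol > 0, max_iter >= 1)
  structure(list(K = as.integer(K), B = as.integer(B), S = as.integer(S),
                 sigma = sigma, refine_steps = as.integer(refine_steps),
                 toggle_steps = as.integer(toggle_steps),
                 swap_steps = as.integer(swap_steps),
                 proposal_budget = as.integer(proposal_budget),
                 tol = tol, max_iter = as.integer(max_iter), engine = engine),
            class = "em_config")
}

# Default assignment initialisation: enumerate the m^k sequences in random
# order when the candidate original network has exactly m^k nodes, otherwise
# draw i.i.d. sequences from L.
init_assignment <- function(measure, observed, steps) {
  nodes <- c(graph_names(observed), latent_slot_names(steps))
  n <- length(nodes)
  if (n == measure$m^measure$k) {
    full <- enumerate_categories(measure)
    perm <- sample.int(n)
    mfng_assignment(full[, perm, drop = FALSE], measure$m, nodes)
  } else {
    sample_categories(measure, n, nodes)
  }
}

# Model-only initial trajectory: restore each slot with links drawn from the
# model conditioned on degree >= 1 (forcing a single weighted link when the
# Bernoulli draw keeps coming back empty).
init_trajectory <- function(measure, assignment, observed, model, steps) {
  st <- build_state(measure, observed, assignment, steps, model)
  for (s in rev(seq_len(steps))) {
    v <- st$n_obs + s
    partners <- slot_partners(st, s)
    pvec <- st$Pmat[v, partners]
    links <- integer(length(partners))
    for (trial in 1:50) {
      links <- propose_slot_links(pvec)
      if (sum(links) > 0) break
    }
    if (sum(links) == 0)
      links[sample.int(length(partners), 1, prob = pvec)] <- 1L
    st$A[v, partners] <- links
    st$A[partners, v] <- links
  }
  state_trajectory(st, observed)
}

#' Draw posterior samples of the latent structure
#'
#' Runs the Gibbs sampler that alternates trajectory updates (a fresh
#' rejection draw when the proposal budget allows, always followed by
#' Metropolis rewiring) with assignment swap updates, for `B + K` sweeps,
#' discarding the first `B`.
#'
#' @inheritParams sample_trajectory
#' @param config an [em_config()].
#' @param assignment optional initial assignment (defaults to
#'   [init_assignment()]); the swap chain preserves its multiset of
#'   sequences.
#' @param trajectory optional initial trajectory.
#' @param materialize when `FALSE`, skip building the per-sample R objects
#'   and return only the pooled summaries (sufficient for the M-step and
#'   for [reconstruct_posterior()]).
#' @return A list of class `posterior_pool` with elements `samples` (list of
#'   [posterior_sample()], or `NULL` when `materialize = FALSE`),
#'   `link_scores` (mean slot-incident link indicator, a `T x (n_obs + T)`
#'   matrix), `profiles` (pooled sufficient statistics for the M-step, when
#'   available), `best` (highest-likelihood sample seen) and `final` (last
#'   sampler state, for warm starts).
#' @export
draw_posterior_samples <- function(measure, observed, model, steps, config,
                                   assignment = NULL, trajectory = NULL,
                                   materialize = TRUE) {
  if (is.null(assignment)) assignment <- init_assignment(measure, observed, steps)
  if (is.null(trajectory)) {
    trajectory <- tryCatch(
      sample_trajectory(measure, assignment, observed, model, steps,
                        max_proposals = max(config$proposal_budget, 50)),
      error = function(e) init_trajectory(measure, assignment, observed,
                                          model, steps))
  }
  if (config$engine == "cpp") {
    gibbs_pool_cpp(measure, observed, model, steps, config, assignment,
                   trajectory, materialize = materialize)
  } else {
    gibbs_pool_r(measure, observed, model, steps, config, assignment,
                 trajectory)
  }
}

# Reference R implementation of the Gibbs loop.
gibbs_pool_r <- function(measure, observed, model, steps, config,
                         assignment, trajectory) {
  samples <- vector("list", config$K)
  n_rec <- 0L
  link_sum <- NULL
  for (sweep in seq_len(config$B + config$K)) {
    if (config$proposal_budget > 0 && steps > 0) {
      fresh <- tryCatch(
        sample_trajectory(measure, assignment, observed, model, steps,
                          max_proposals = config$proposal_budget),
        error = function(e) NULL)
      if (!is.null(fresh)) trajectory <- fresh
    }
    if (config$toggle_steps > 0 && steps > 0)
      trajectory <- toggle_trajectory(trajectory, measure, assignment,
                                      observed, model, config$toggle_steps)
    if (config$refine_steps > 0 && steps > 0)
      trajectory <- refine_trajectory(trajectory, measure, assignment,
                                      observed, model, config$refine_steps)
    if (config$swap_steps > 0)
      assignment <- sample_assignment(assignment, trajectory, measure,
                                      observed, model, config$swap_steps)
    if (sweep > config$B) {
      st <- build_state(measure, observed, assignment, steps, model,
                        trajectory)
      mll <- state_model_ll(st)
      all_ <- state_attack_ll(st)
      n_rec <- n_rec + 1L
      samples[[n_rec]] <- posterior_sample(
        trajectory, mfng_assignment(st$assign, measure$m),
        model_ll = mll, attack_ll = all_,
        complete_ll = if (is.finite(all_)) mll + model$gamma * all_ else -Inf)
      sl <- slot_link_matrix(trajectory, observed, steps)
      link_sum <- if (is.null(link_sum)) sl else link_sum + sl
    }
  }
  lls <- data.frame(
    model = vapply(samples, `[[`, numeric(1), "model_ll"),
    attack = vapply(samples, `[[`, numeric(1), "attack_ll"),
    complete = vapply(samples, `[[`, numeric(1), "complete_ll"))
  structure(list(samples = samples,
                 link_scores = if (config$K > 0) link_sum / config$K,
                 profiles = NULL,
                 lls = lls,
                 best = samples[[which.max(lls$complete)]],
                 final = list(assignment = assignment,
                              trajectory = trajectory),
                 K = config$K),
            class = "posterior_pool")
}

#' @export
print.posterior_pool <- function(x, ...) {
  cat("Posterior pool:", length(x$samples), "samples\n")
  invisible(x)
}

# T x N 0/1 matrix of slot-incident links encoded by a trajectory.
slot_link_matrix <- function(trajectory, observed, steps) {
  nodes <- c(graph_names(observed), latent_slot_names(steps))
  M <- matrix(0L, steps, length(nodes),
              dimnames = list(latent_slot_names(steps), nodes))
  for (s in seq_along(trajectory$events)) {
    ev <- trajectory$events[[s]]
    M[s, ev$neighbors] <- 1L
    # links from earlier slots to this slot live in the earlier events
  }
  # symmetrise slot-slot entries so each row carries the slot's full G0 row
  if (steps > 1) {
    for (s in seq_len(steps)) {
      later <- which(M[s, latent_slot_names(steps)] == 1L)
      for (sp in later) M[sp, latent_slot_names(steps)[s]] <- 1L
    }
  }
  M
}

#' Monte-Carlo Q-function
#'
#' Average complete-data log-likelihood of the sample pool evaluated under a
#' candidate measure (trajectories and assignments held fixed).
#'
#' @param candidate an `mfng_measure`.
#' @param samples a `posterior_pool` or list of `posterior_sample`s.
#' @param observed the residual graph.
#' @param model an `intervention_model`.
#' @return The Q value (mean complete log-likelihood).
#' @export
q_function <- function(candidate, samples, observed, model) {
  samples <- pool_samples(samples)
  if (length(samples) == 0) stop("empty sample list")
  mean(vapply(samples, function(s)
    complete_log_likelihood(candidate, observed, s, model), numeric(1)))
}

pool_samples <- function(samples) {
  if (inherits(samples, "posterior_pool")) samples$samples else samples
}
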