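# ---- pooled sufficient statistics for the M-step -------------------------
#
# The model log-likelihood of a candidate original graph depends on a node
# pair only through the multiset of category pairs its two sequences show
# across the k levels. Pairs are therefore binned by that profile: with
# U = m(m+1)/2 unordered category pairs, a profile is a composition of k
# over U cells, encoded in radix k+1. Pooling the per-profile edge and
# non-edge counts over all posterior samples reduces each gradient step of
# the M-step from O(K n^2 k) to O(#profiles), with no approximation.

upair_index <- function(m) {
  U <- matrix(0L, m, m)
  u <- 0L
  for (a in seq_len(m)) for (b in a:m) {
    u <- u + 1L
    U[a, b] <- u; U[b, a] <- u
  }
  U
}

profile_codes <- function(measure) {
  m <- measure$m; k <- measure$k
  U <- m * (m + 1L) / 2L
  base <- k + 1L
  nbins <- base^(U - 1L)
  coef <- c(base^(seq_len(U - 1L) - 1L), 0)
  list(m = m, k = k, U = U, base = base, coef = coef, nbins = nbins,
       upair = upair_index(m))
}

# Decode bin ids (0-based) into a U x length(ids) matrix of per-pair level
# counts.
decode_profiles <- function(ids, codes) {
  n <- length(ids)
  out <- matrix(0L, codes$U, n)
  rest <- ids
  for (u in seq_len(codes$U - 1L)) {
    out[u, ] <- rest %% codes$base
    rest <- rest %/% codes$base
  }
  out[codes$U, ] <- codes$k - colSums(out[seq_len(codes$U - 1L), , drop = FALSE])
  out
}

# Map the upper triangle of a candidate adjacency into profile bins and
# tabulate edge/non-edge counts. `sequences` is the k x N assignment matrix
# aligned with A.
profile_counts <- function(A, sequences, codes) {
  N <- ncol(sequences)
  ids <- matrix(0, N, N)
  for (l in seq_len(codes$k)) {
    cl <- sequences[l, ]
    ids <- ids + codes$coef[codes$upair[cl, cl, drop = FALSE]]
  }
  up <- upper.tri(A)
  e <- tabulate(ids[up & A == 1] + 1L, nbins = codes$nbins)
  ne <- tabulate(ids[up & A == 0] + 1L, nbins = codes$nbins)
  list(edge = e, nonedge = ne)
}

# Pool the profile counts of a sample list (R fallback; the compiled Gibbs
# kernel returns the same pooled counts directly).
pooled_profiles <- function(samples, observed, measure) {
  codes <- profile_codes(measure)
  if (codes$nbins > 5e6) return(NULL)
  samples <- pool_samples(samples)
  steps <- length(samples[[1]]$trajectory$events)
  obs_nodes <- graph_names(observed)
  nodes <- c(obs_nodes, latent_slot_names(steps))
  n_obs <- length(obs_nodes)
  N <- length(nodes)
  Aobs <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  if (n_obs > 0)
    Aobs[seq_len(n_obs), seq_len(n_obs)] <- graph_adjacency(observed, obs_nodes)
  e <- numeric(codes$nbins); ne <- numeric(codes$nbins)
  att <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    A <- Aobs
    sl <- slot_link_matrix(s$trajectory, observed, steps)
    A[n_obs + seq_len(steps), ] <- sl
    A[, n_obs + seq_len(steps)] <- t(sl)
    seqs <- s$assignment[, nodes, drop = FALSE]
    pc <- profile_counts(A, seqs, codes)
    e <- e + pc$edge; ne <- ne + pc$nonedge
    att[i] <- s$attack_ll
  }
  list(codes = codes, edge = e, nonedge = ne, attack_ll = att,
       K = length(samples))
}

# Q (model part, summed over samples) and its gradient in the free entries
# of P, from pooled profile counts.
profile_q <- function(P, prof) {
  codes <- prof$codes
  use <- which(prof$edge + prof$nonedge > 0)
  if (length(use) == 0) return(list(q = 0, grad = matrix(0, codes$m, codes$m)))
  n_u <- decode_profiles(use - 1L, codes)
  theta <- P[upper.tri(P, diag = TRUE)][order(upair_order(codes$m))]
  # theta indexed by unordered-pair id u (same order as upair_index)
  logtheta <- log(theta)
  logp <- as.numeric(crossprod(n_u, logtheta))
  p <- exp(logp)
  e <- prof$edge[use]; ne <- prof$nonedge[use]
  q <- sum(e * logp + ne * log1p(-p))
  wgrad <- e - ne * p / (1 - p)          # per-bin weight
  gtheta <- as.numeric(n_u %*% wgrad) / theta
  G <- matrix(0, codes$m, codes$m)
  u <- 0L
  for (a in seq_len(codes$m)) for (b in a:codes$m) {
    u <- u + 1L
    G[a, b] <- G[b, a] <- gtheta[u]
  }
  list(q = q, grad = G)
}

# Order mapping so that P[upper.tri(diag=TRUE)] (column-major) can be
# re-indexed by unordered pair id.
upair_order <- function(m) {
  U <- upair_index(m)
  U[upper.tri(U, diag = TRUE)]
}

#' Gradient-ascent M-step
#'
#' Updates the generating measure's `P` by `S` batch gradient steps on the
#' Monte-Carlo Q-function: each step adds `sigma / K` times the summed
#' per-sample gradient, symmetrises and clamps the result. The attack term
#' carries no gradient (it does not depend on `P`). If a step would decrease
#' the Q-function the learning rate is halved and the step retried, so the
#' Q-function never decreases across the M-step.
#'
#' @param measure the current `mfng_measure`.
#' @param samples a `posterior_pool` or list of `posterior_sample`s.
#' @param observed the residual graph.
#' @param model an `intervention_model`.
#' @param config an [em_config()].
#' @return The updated `mfng_measure`, with attribute `"q"` holding the
#'   final Q value (mean complete log-likelihood of the pool under the
#'   updated measure).
#' @export
m_step <- function(measure, samples, observed, model, config) {
  prof <- if (inherits(samples, "posterior_pool") && !is.null(samples$profiles))
    samples$profiles
  else
    pooled_profiles(samples, observed, measure)
  if (is.null(prof))
    return(m_step_direct(measure, samples, observed, model, config))
  K <- prof$K
  att_mean <- mean(prof$attack_ll)
  att_const <- if (model$gamma == 0) 0 else model$gamma * att_mean
  P <- measure$P
  cur <- profile_q(P, prof)
  for (step in seq_len(config$S)) {
    sigma_eff <- config$sigma
    improved <- FALSE
    for (h in 1:30) {
      Pnew <- P + (sigma_eff / K) * cur$grad
      Pnew <- clamp_probability((Pnew + t(Pnew)) / 2, measure$clamp)
      new <- profile_q(Pnew, prof)
      if (new$q >= cur$q) {
        P <- Pnew; cur <- new; improved <- TRUE
        break
      }
      sigma_eff <- sigma_eff / 2
    }
    if (!improved) break
  }
  out <- mfng_measure(measure$m, measure$k, P, measure$L, measure$clamp)
  attr(out, "q") <- cur$q / K + att_const
  out
}

# Direct (per-sample) M-step, used when the profile space is too large to
# pool (large m with deep recursion). Same update, computed from per-sample
# adjacencies.
m_step_direct <- function(measure, samples, observed, model, config) {
  samples <- pool_samples(samples)
  K <- length(samples)
  steps <- length(samples[[1]]$trajectory$events)
  obs_nodes <- graph_names(observed)
  nodes <- c(obs_nodes, latent_slot_names(steps))
  n_obs <- length(obs_nodes)
  N <- length(nodes)
  Aobs <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  if (n_obs > 0)
    Aobs[seq_len(n_obs), seq_len(n_obs)] <- graph_adjacency(observed, obs_nodes)
  As <- lapply(samples, function(s) {
    A <- Aobs
    sl <- slot_link_matrix(s$trajectory, observed, steps)
    A[n_obs + seq_len(steps), ] <- sl
    A[, n_obs + seq_len(steps)] <- t(sl)
    A
  })
  seqs <- lapply(samples, function(s) s$assignment[, nodes, drop = FALSE])
  att_mean <- mean(vapply(samples, `[[`, numeric(1), "attack_ll"))
  att_const <- if (model$gamma == 0) 0 else model$gamma * att_mean
  model_q <- function(meas) {
    sum(vapply(seq_len(K), function(i) {
      Pm <- link_probability_matrix(meas, mfng_assignment(seqs[[i]], meas$m))
      up <- upper.tri(As[[i]])
      sum(As[[i]][up] * log(Pm[up]) + (1 - As[[i]][up]) * log1p(-Pm[up]))
    }, numeric(1)))
  }
  cur_meas <- measure
  cur_q <- model_q(cur_meas)
  for (step in seq_len(config$S)) {
    G <- Reduce(`+`, lapply(seq_len(K), function(i)
      gradient_from_adjacency(cur_meas, As[[i]], seqs[[i]])))
    sigma_eff <- config$sigma
    improved <- FALSE
    for (h in 1:30) {
      Pnew <- cur_meas$P + (sigma_eff / K) * G
      cand <- mfng_measure(measure$m, measure$k,
                           (Pnew + t(Pnew)) / 2, measure$L, measure$clamp)
      qnew <- model_q(cand)
      if (qnew >= cur_q) {
        cur_meas <- cand; cur_q <- qnew; improved <- TRUE
        break
      }
      sigma_eff <- sigma_eff / 2
    }
    if (!improved) break
  }
  attr(cur_meas, "q") <- cur_q / K + att_const
  cur_meas
}

#' Posterior link scores for the missing structure
#'
#' For every candidate pair involving at least one latent slot (slot-slot
#' and slot-observed pairs), the score is the fraction of posterior samples
#' in which that link is present, with slots aligned by removal-time index.
#'
#' @param samples a `posterior_pool` or list of `posterior_sample`s.
#' @param observed the residual graph.
#' @param steps number of latent slots.
#' @return A data frame with columns `from` (a slot), `to` (a slot or an
#'   observed node) and `score` in `[0, 1]`.
#' @export
reconstruct_posterior <- function(samples, observed, steps) {
  if (inherits(samples, "posterior_pool") && !is.null(samples$link_scores)) {
    M <- samples$link_scores
  } else {
    samples <- pool_samples(samples)
    if (length(samples) == 0) stop("empty sample list")
    M <- Reduce(`+`, lapply(samples, function(s)
      slot_link_matrix(s$trajectory, observed, steps))) / length(samples)
  }
  nodes <- colnames(M)
  slots <- latent_slot_names(steps)
  n_obs <- length(nodes) - steps
  rows <- list()
  for (s in seq_len(steps)) {
    partners <- c(seq_len(n_obs),
                  if (s < steps) n_obs + (s + 1L):steps else integer(0))
    rows[[s]] <- data.frame(from = slots[s], to = nodes[partners],
                            score = as.numeric(M[s, partners]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the Monte-Carlo EM reconstruction
#'
#' Alternates the E-step ([draw_posterior_samples()]) and the M-step
#' ([m_step()]) until the Q-function proxy changes by less than `tol`
#' (relative) or `max_iter` iterations are reached. Successive E-steps warm
#' start from the last sampler state and re-apply the burn-in.
#'
#' @param observed the residual `igraph` graph.
#' @param steps number of missing nodes `T` (a modelling input; estimating
#'   it is out of scope).
#' @param model an `intervention_model` (use `gamma = 0` for the
#'   attack-blind baseline, `gamma = 1` for the full causal likelihood).
#' @param config an [em_config()].
#' @param m,k MFNG dimensions used when `measure0` is not given; `k`
#'   defaults to `log_m(n)` when the candidate original size is a power of
#'   `m`.
#' @param measure0 optional starting measure; defaults to a symmetric
#'   Uniform(0.2, 0.8) draw (one fresh draw per start).
#' @param assignment optional initial assignment.
#' @param n_starts number of independent EM runs from random
#'   initialisations. The MFNG likelihood is multi-modal and categories are
#'   identifiable only up to relabelling, so with several starts the final
#'   measures are aligned by category permutation onto the consensus run
#'   (the one closest to the others in permutation-aligned Frobenius
#'   distance) and averaged; link scores are averaged as well. The
#'   ensemble shrinks the spurious structure a single run can commit to on
#'   weakly identified instances. (The Monte-Carlo Q-proxy cannot arbitrate
#'   between starts: it is an expected *complete* likelihood under each
#'   run's own posterior, and overfitted basins report inflated values.)
#' @return An object of class `em_state`: a list with `measure` (final
#'   estimate), `trace` (data frame of Q values per iteration), `pool` (last
#'   sample pool), `scores` (edge score table from
#'   [reconstruct_posterior()]), `converged`, `iterations`, `start_qs`
#'   (final Q of every start), `config`, `model`. With `n_starts > 1` the
#'   measure and scores are the aligned ensemble averages; trace and pool
#'   come from the consensus run.
#' @export
run_em <- function(observed, steps, model, config = em_config(),
                   m = 2, k = NULL, measure0 = NULL, assignment = NULL,
                   n_starts = 1) {
  stopifnot(n_starts >= 1)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    m0 <- if (i == 1) measure0 else NULL
    fits[[i]] <- run_em_once(observed, steps, model, config, m = m, k = k,
                             measure0 = m0, assignment = assignment)
  }
  qs <- vapply(fits, function(f) utils::tail(f$trace$q, 1), numeric(1))
  best <- fits[[1]]
  if (n_starts > 1) {
    D <- matrix(0, n_starts, n_starts)
    for (i in seq_len(n_starts - 1)) for (j in (i + 1):n_starts) {
      D[i, j] <- D[j, i] <- frobenius_error(fits[[i]]$measure,
                                            fits[[j]]$measure)
    }
    pick <- which.min(rowSums(D))
    best <- fits[[pick]]
    ref <- best$measure
    Pavg <- Reduce(`+`, lapply(fits, function(f)
      align_measure_P(f$measure, ref))) / n_starts
    best$measure <- mfng_measure(ref$m, ref$k, Pavg, ref$L, ref$clamp)
    best$scores$score <- rowMeans(
      vapply(fits, function(f) f$scores$score,
             numeric(nrow(best$scores))))
  }
  best$start_qs <- qs
  best
}

# P of `measure`, category-permuted to best match `ref` in Frobenius norm.
align_measure_P <- function(measure, ref) {
  best <- NULL
  best_d <- Inf
  for (p in permutations_of(ref$m)) {
    Pp <- measure$P[p, p, drop = FALSE]
    d <- sum((Pp - ref$P)^2)
    if (d < best_d) {
      best_d <- d
      best <- Pp
    }
  }
  best
}

run_em_once <- function(observed, steps, model, config,
                        m = 2, k = NULL, measure0 = NULL, assignment = NULL) {
  stopifnot(steps >= 1)
  if (is.null(measure0)) {
    if (is.null(k)) {
      n_total <- igraph::vcount(observed) + steps
      k <- round(log(n_total) / log(m))
      if (m^k != n_total)
        stop("candidate size is not a power of m; supply 'k' or 'measure0'")
    }
    measure0 <- random_mfng_measure(m, k, range = c(0.2, 0.8))
  }
  cur <- measure0
  if (is.null(assignment))
    assignment <- init_assignment(cur, observed, steps)
  trajectory <- NULL
  qs <- numeric(0)
  pool <- NULL
  converged <- FALSE
  P_hist <- list()
  for (j in seq_len(config$max_iter)) {
    pool <- draw_posterior_samples(cur, observed, model, steps, config,
                                   assignment = assignment,
                                   trajectory = trajectory,
                                   materialize = FALSE)
    assignment <- pool$final$assignment
    trajectory <- pool$final$trajectory
    cur <- m_step(cur, pool, observed, model, config)
    qj <- attr(cur, "q")
    if (!is.finite(qj))
      stop("non-finite Q-function at EM iteration ", j,
           "; the sampler likely produced zero-mass trajectories")
    qs <- c(qs, qj)
    P_hist[[j]] <- cur$P
    if (j >= 2 &&
        abs(qs[j] - qs[j - 1]) / max(1, abs(qs[j - 1])) < config$tol) {
      converged <- TRUE
      break
    }
  }
  # tail-average the trailing iterates (aligned to the last one): each
  # E-step resamples the latent structure, so the iterates oscillate around
  # the mode with Monte-Carlo noise that averaging removes
  L <- min(4L, length(P_hist))
  if (L > 1) {
    tail_Ps <- P_hist[(length(P_hist) - L + 1):length(P_hist)]
    ref <- cur
    Pavg <- Reduce(`+`, lapply(tail_Ps, function(P)
      align_measure_P(mfng_measure(cur$m, cur$k, P, cur$L, cur$clamp),
                      ref))) / L
    q_last <- attr(cur, "q")
    cur <- mfng_measure(cur$m, cur$k, Pavg, cur$L, cur$clamp)
    attr(cur, "q") <- q_last
  }
  structure(list(measure = cur,
                 trace = data.frame(iteration = seq_along(qs), q = qs),
                 pool = pool,
                 scores = reconstruct_posterior(pool, observed, steps),
                 converged = converged, iterations = length(qs),
                 config = config, model = model),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat("Monte-Carlo EM state:", x$iterations, "iterations,",
      if (x$converged) "converged" else "iteration cap reached", "\n")
  cat("Final Q:", format(utils::tail(x$trace$q, 1)), "\n")
  print(x$measure)
  invisible(x)
}

# ---- exact posterior enumeration (test oracle) ---------------------------

#' Canonical key of a latent-structure state
#'
#' Serialises the latent link pattern (slots in removal order, partners in
#' canonical order) and the category assignment of every node into a string,
#' so that sampler output and the exact enumeration oracle can be compared
#' state by state.
#'
#' @param sample a `posterior_sample` (or list with `trajectory` and
#'   `assignment`).
#' @param observed the residual graph.
#' @param steps number of latent slots.
#' @return A character scalar.
#' @export
posterior_state_key <- function(sample, observed, steps) {
  sl <- slot_link_matrix(sample$trajectory, observed, steps)
  nodes <- colnames(sl)
  n_obs <- length(nodes) - steps
  bits <- unlist(lapply(seq_len(steps), function(s) {
    partners <- c(seq_len(n_obs),
                  if (s < steps) n_obs + (s + 1L):steps else integer(0))
    sl[s, partners]
  }))
  asg <- sample$assignment[, nodes, drop = FALSE]
  paste(paste(bits, collapse = ""),
        paste(apply(asg, 2, paste, collapse = ""), collapse = "."),
        sep = "|")
}

# Distinct permutations of the columns of a sequence matrix (multiset
# permutations, generated recursively).
multiset_permutations <- function(codes) {
  tab <- table(codes)
  syms <- names(tab)
  out <- list()
  recur <- function(prefix, counts) {
    if (sum(counts) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(syms)) {
      if (counts[i] > 0) {
        counts[i] <- counts[i] - 1
        recur(c(prefix, syms[i]), counts)
        counts[i] <- counts[i] + 1
      }
    }
  }
  recur(character(0), as.integer(tab))
  out
}

#' Exact posterior over trajectories and assignments
#'
#' Exhaustively enumerates every latent link pattern (and, if `assignment`
#' is supplied, every distinct arrangement of its multiset of category
#' sequences — the states reachable by the swap chain; otherwise every
#' category assignment), computes the complete-data likelihood of each
#' state and normalises. Intended as a test oracle on tiny instances.
#'
#' @inheritParams sample_trajectory
#' @param assignment optional `mfng_assignment` whose multiset of sequences
#'   constrains the enumeration.
#' @param max_states refuse enumeration beyond this many states.
#' @return A data frame with columns `state` (canonical key as in
#'   [posterior_state_key()]), `log_weight` and `prob` (normalised; sums
#'   to 1).
#' @export
enumerate_posterior_exact <- function(measure, observed, model, steps,
                                      assignment = NULL, max_states = 1e6) {
  obs_nodes <- graph_names(observed)
  slots <- latent_slot_names(steps)
  nodes <- c(obs_nodes, slots)
  N <- length(nodes)
  n_obs <- length(obs_nodes)
  # assignment arrangements
  if (!is.null(assignment)) {
    asg <- assignment[, nodes, drop = FALSE]
    codes <- apply(asg, 2, paste, collapse = ",")
    arrangements <- multiset_permutations(codes)
    seq_of_code <- asg[, !duplicated(codes), drop = FALSE]
    colnames(seq_of_code) <- codes[!duplicated(codes)]
    arr_mats <- lapply(arrangements, function(arr) {
      M <- seq_of_code[, arr, drop = FALSE]
      colnames(M) <- nodes
      M
    })
  } else {
    grid <- expand.grid(rep(list(seq_len(measure$m^measure$k)), N))
    all_seq <- enumerate_categories(measure)
    arr_mats <- lapply(seq_len(nrow(grid)), function(r) {
      M <- all_seq[, as.integer(grid[r, ]), drop = FALSE]
      colnames(M) <- nodes
      M
    })
  }
  bits_per_slot <- n_obs + steps - seq_len(steps)
  n_patterns <- prod(2^bits_per_slot)
  n_states <- length(arr_mats) * n_patterns
  if (steps == 0) {
    akey <- if (!is.null(assignment))
      paste(apply(assignment[, nodes, drop = FALSE], 2, paste,
                  collapse = ""), collapse = ".")
    else ""
    return(data.frame(state = paste("", akey, sep = "|"),
                      log_weight = 0, prob = 1, stringsAsFactors = FALSE))
  }
  if (n_states > max_states)
    stop("state space too large for exact enumeration (", n_states, " states)")
  keys <- character(n_states)
  lws <- numeric(n_states)
  idx <- 0L
  for (arr in arr_mats) {
    asg_obj <- mfng_assignment(arr, measure$m)
    st0 <- build_state(measure, observed, asg_obj, steps, model)
    for (pat in 0:(n_patterns - 1L)) {
      st <- st0
      rest <- pat
      bits_all <- integer(0)
      for (s in seq_len(steps)) {
        nb <- bits_per_slot[s]
        partners <- slot_partners(st, s)
        links <- integer(nb)
        for (b in seq_len(nb)) {
          links[b] <- rest %% 2L
          rest <- rest %/% 2L
        }
        st$A[n_obs + s, partners] <- links
        st$A[partners, n_obs + s] <- links
        bits_all <- c(bits_all, links)
      }
      idx <- idx + 1L
      lws[idx] <- state_complete_ll(st)
      keys[idx] <- paste(paste(bits_all, collapse = ""),
                         paste(apply(arr, 2, paste, collapse = ""),
                               collapse = "."), sep = "|")
    }
  }
  finite <- is.finite(lws)
  mx <- max(lws[finite])
  w <- ifelse(finite, exp(lws - mx), 0)
  data.frame(state = keys, log_weight = lws, prob = w / sum(w),
             stringsAsFactors = FALSE)
}
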