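# Wrapper around the compiled Gibbs kernel. Mirrors gibbs_pool_r().

trajectory_from_slot_links <- function(sl, nodes, n_obs, steps, observed) {
  events <- lapply(seq_len(steps), function(s) {
    partners <- c(seq_len(n_obs),
                  if (s < steps) n_obs + (s + 1L):steps else integer(0))
    nbrs <- partners[sl[s, partners] == 1L]
    list(victim = nodes[n_obs + s], neighbors = nodes[nbrs])
  })
  removal_trajectory(events, residual = observed)
}

gibbs_pool_cpp <- function(measure, observed, model, steps, config,
                           assignment, trajectory, materialize = TRUE) {
  st <- build_state(measure, observed, assignment, steps, model,
                    trajectory = trajectory)
  codes <- profile_codes(measure)
  pool_profiles <- codes$nbins <= 5e6
  res <- gibbs_kernel(
    st$A, st$assign, measure$P, st$n_obs, st$T,
    model$alpha, model$gamma, config$K, config$B,
    config$refine_steps, config$toggle_steps, config$swap_steps,
    config$proposal_budget,
    if (pool_profiles) codes$nbins else 0L,
    codes$upair, codes$coef, isTRUE(materialize))
  nodes <- st$nodes
  n_obs <- st$n_obs
  samples <- NULL
  if (isTRUE(materialize)) {
    samples <- lapply(seq_len(config$K), function(i) {
      sl <- res$slot_links[[i]]
      am <- res$assigns[[i]]
      colnames(am) <- nodes
      posterior_sample(
        trajectory_from_slot_links(sl, nodes, n_obs, steps, observed),
        mfng_assignment(am, measure$m),
        model_ll = res$model_ll[i], attack_ll = res$attack_ll[i],
        complete_ll = res$complete_ll[i])
    })
  }
  link_scores <- res$link_sum / config$K
  dimnames(link_scores) <- list(latent_slot_names(max(steps, 1))[seq_len(nrow(link_scores))],
                                nodes)
  fa <- res$final_assign
  colnames(fa) <- nodes
  ba <- res$best_assign
  colnames(ba) <- nodes
  best <- posterior_sample(
    trajectory_from_slot_links(res$best_slots, nodes, n_obs, steps, observed),
    mfng_assignment(ba, measure$m),
    complete_ll = res$best_ll)
  structure(list(
    samples = samples,
    link_scores = link_scores,
    profiles = if (pool_profiles)
      list(codes = codes, edge = res$edge_counts,
           nonedge = res$nonedge_counts, attack_ll = res$attack_ll,
           K = config$K),
    lls = data.frame(model = res$model_ll, attack = res$attack_ll,
                     complete = res$complete_ll),
    best = best,
    final = list(
      assignment = mfng_assignment(fa, measure$m),
      trajectory = trajectory_from_slot_links(
        res$final_A[n_obs + seq_len(steps), , drop = FALSE],
        nodes, n_obs, steps, observed)),
    fresh_success = res$fresh_success,
    K = config$K), class = "posterior_pool")
}
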