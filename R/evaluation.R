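#' Metric report
#'
#' Small container for a reported metric: its name, value, dispersion over
#' replicates (present only when more than one replicate was averaged), the
#' replicate count and a configuration echo.
#'
#' @param metric metric name.
#' @param value numeric value (usually a mean over replicates).
#' @param dispersion standard deviation over replicates, or `NA` for a
#'   single replicate.
#' @param replicates number of replicates averaged.
#' @param config named list echoing the configuration that produced the
#'   value.
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(metric, value, dispersion = NA_real_,
                          replicates = 1L, config = list()) {
  if (replicates > 1 && is.na(dispersion))
    stop("dispersion must be given when replicates > 1")
  if (replicates <= 1) dispersion <- NA_real_
  structure(list(metric = metric, value = value, dispersion = dispersion,
                 replicates = as.integer(replicates), config = config),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(x$metric, ": ", format(x$value), sep = "")
  if (!is.na(x$dispersion))
    cat(" +/- ", format(x$dispersion), " (n = ", x$replicates, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(metric = x$metric, value = x$value, dispersion = x$dispersion,
             replicates = x$replicates, stringsAsFactors = FALSE)
}

#' Permutation-aligned Frobenius error between generating measures
#'
#' MFNG categories are identifiable only up to a simultaneous relabelling of
#' rows and columns of `P`, so the Frobenius norm of the difference is
#' minimised over all category permutations before being reported.
#'
#' @param estimated,truth `mfng_measure`s with the same `m`.
#' @return The minimal Frobenius norm (a nonnegative number).
#' @export
frobenius_error <- function(estimated, truth) {
  stopifnot(inherits(estimated, "mfng_measure"), inherits(truth, "mfng_measure"))
  if (estimated$m != truth$m) stop("measures have different m")
  m <- truth$m
  if (m > 7) stop("permutation alignment supports m <= 7")
  perms <- permutations_of(m)
  best <- Inf
  for (p in perms) {
    d <- estimated$P[p, p, drop = FALSE] - truth$P
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

permutations_of <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    rest <- permutations_of(m - 1L)
    for (r in rest) {
      v <- seq_len(m)[-i]
      out[[length(out) + 1]] <- c(i, v[r])
    }
  }
  out
}

#' Signed divergence between true and recovered link probabilities
#'
#' Sum over category-sequence pairs of `w * p_true * log(p_true / p_hat)`,
#' where `w` is the product-measure weight of the pair under `L`. Unlike a
#' strict KL divergence this per-pair form carries a sign: it is positive
#' when the recovered measure systematically underestimates link
#' probabilities and negative when it overestimates them.
#'
#' @param truth,estimated `mfng_measure`s with the same `m` and `k`.
#' @return A signed real number (0 when the measures agree).
#' @export
signed_kl_divergence <- function(truth, estimated) {
  stopifnot(truth$m == estimated$m, truth$k == estimated$k)
  if (truth$m^truth$k > 4096)
    stop("sequence space too large (m^k > 4096)")
  seqs <- enumerate_categories(truth)
  n <- ncol(seqs)
  Pt <- matrix(1, n, n); Pe <- matrix(1, n, n)
  wseq <- rep(1, n)
  for (l in seq_len(truth$k)) {
    cl <- seqs[l, ]
    Pt <- Pt * truth$P[cl, cl, drop = FALSE]
    Pe <- Pe * estimated$P[cl, cl, drop = FALSE]
    wseq <- wseq * truth$L[cl]
  }
  W <- outer(wseq, wseq)
  sum(W * Pt * (log(Pt) - log(Pe)))
}

#' Kolmogorov-Smirnov distance between degree distributions
#'
#' Generates `n_samples` networks from the measure and reports the mean and
#' standard deviation of the sup distance between the empirical degree CDF
#' of each generated network and that of the reference network.
#'
#' @param reference the reference `igraph` graph.
#' @param measure an `mfng_measure`.
#' @param n_samples number of generated networks.
#' @param assignment optional assignment used for generation; defaults to
#'   the enumeration assignment when the reference size equals `m^k`,
#'   otherwise fresh sequences are drawn from `L` for every sample.
#' @return A `metric_report` named `"e_KS"`.
#' @export
ks_distance <- function(reference, measure, n_samples, assignment = NULL) {
  stopifnot(n_samples >= 1)
  n <- igraph::vcount(reference)
  dref <- as.numeric(igraph::degree(reference))
  fixed <- assignment
  if (is.null(fixed) && n == measure$m^measure$k)
    fixed <- enumerate_categories(measure)
  ds <- vapply(seq_len(n_samples), function(i) {
    asg <- if (is.null(fixed)) sample_categories(measure, n) else fixed
    g <- sample_network(measure, asg)
    degree_cdf_distance(dref, as.numeric(igraph::degree(g)))
  }, numeric(1))
  metric_report("e_KS", mean(ds),
                dispersion = if (n_samples > 1) stats::sd(ds) else NA_real_,
                replicates = n_samples,
                config = list(n_samples = n_samples))
}

degree_cdf_distance <- function(d1, d2) {
  grid <- 0:max(d1, d2)
  F1 <- stats::ecdf(d1)(grid)
  F2 <- stats::ecdf(d2)(grid)
  max(abs(F1 - F2))
}

#' Link-prediction areas under the ROC and precision-recall curves
#'
#' Scores every candidate latent-incident pair against the ground truth:
#' positives are the original-network edges that are absent from the
#' residual network. Latent slots are aligned to true removed nodes by
#' removal-time index via `latent_map` (this alignment lives only in the
#' evaluation harness, never in the inference path). ROC-AUC uses the
#' rank-sum form with tie correction; PR-AUC is the step-interpolated
#' average precision, which equals the positive prevalence for constant
#' scores.
#'
#' @param scores edge score table from [reconstruct_posterior()].
#' @param truth the original `igraph` graph.
#' @param latent_map named character vector mapping each latent slot name to
#'   the identifier of the node truly removed at that step.
#' @return A list with elements `roc_auc` and `pr_auc`.
#' @export
link_auc <- function(scores, truth, latent_map) {
  map_id <- function(x) ifelse(x %in% names(latent_map), latent_map[x], x)
  from <- map_id(scores$from)
  to <- map_id(scores$to)
  tn <- graph_names(truth)
  if (!all(c(from, to) %in% tn))
    stop("latent_map does not place every candidate pair in the truth graph")
  el <- igraph::as_edgelist(truth, names = TRUE)
  ekeys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  labels <- paste(pmin(from, to), pmax(from, to), sep = "\r") %in% ekeys
  np <- sum(labels)
  if (np == 0) stop("no positive pairs: AUC undefined")
  nn <- sum(!labels)
  if (nn == 0) stop("no negative pairs: AUC undefined")
  r <- rank(scores$score)
  roc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  # average precision with tied scores handled as threshold groups
  ord <- order(scores$score, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores$score[ord]
  grp <- cumsum(!duplicated(sc))
  tp_g <- tapply(lab, grp, sum)
  n_g <- tapply(lab, grp, length)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  pr <- sum(tp_g * prec) / np
  list(roc_auc = as.numeric(roc), pr_auc = as.numeric(pr))
}

#' Log-likelihood of a fitted measure on a reference graph
#'
#' Evaluates [model_log_likelihood()] of the measure on the full reference
#' network under the supplied assignment (typically the best sampled
#' assignment, with latent slots renamed to the true node identifiers).
#'
#' @param measure an `mfng_measure`.
#' @param reference the reference `igraph` graph.
#' @param assignment an `mfng_assignment` covering the reference vertices.
#' @return The log-likelihood.
#' @export
model_fit_loglik <- function(measure, reference, assignment) {
  model_log_likelihood(measure, reference, assignment)
}

#' Mean coverage as a function of injected share
#'
#' For each share, repeats `n_trials` independent injections
#' ([select_injected_nodes()]) and reports the mean and standard deviation
#' of [coverage()].
#'
#' @param graph an undirected `igraph` graph.
#' @param shares numeric vector of injection shares in `[0, 1]`.
#' @param alpha injection weight exponent.
#' @param n_trials independent injections per share.
#' @return A data frame with columns `share`, `coverage`, `sd`, `n`.
#' @export
coverage_curve <- function(graph, shares, alpha, n_trials) {
  stopifnot(all(shares >= 0 & shares <= 1), n_trials >= 1)
  rows <- lapply(shares, function(sh) {
    cv <- vapply(seq_len(n_trials), function(i)
      coverage(graph, select_injected_nodes(graph, sh, alpha)), numeric(1))
    data.frame(share = sh, coverage = mean(cv),
               sd = if (n_trials > 1) stats::sd(cv) else NA_real_,
               n = n_trials)
  })
  do.call(rbind, rows)
}

#' Estimated affected users under a fitted model
#'
#' Draws `n_instances` networks from the measure, injects
#' `ceiling(share * n_total)` nodes with weight `degree^alpha` in each, and
#' reports the mean and standard deviation of [affected_users()].
#'
#' @param measure an `mfng_measure`.
#' @param n_total number of nodes per generated network.
#' @param share injected share.
#' @param alpha injection weight exponent.
#' @param n_instances number of generated networks.
#' @param assignment optional fixed assignment for generation (defaults as
#'   in [ks_distance()]).
#' @return A `metric_report` named `"affected_users"`.
#' @export
affected_users_estimate <- function(measure, n_total, share, alpha,
                                    n_instances, assignment = NULL) {
  stopifnot(n_instances >= 1)
  fixed <- assignment
  if (is.null(fixed) && n_total == measure$m^measure$k)
    fixed <- enumerate_categories(measure)
  xs <- vapply(seq_len(n_instances), function(i) {
    asg <- if (is.null(fixed)) sample_categories(measure, n_total) else fixed
    g <- sample_network(measure, asg)
    inj <- select_injected_nodes(g, share, alpha)
    as.numeric(affected_users(g, inj))
  }, numeric(1))
  metric_report("affected_users", mean(xs),
                dispersion = if (n_instances > 1) stats::sd(xs) else NA_real_,
                replicates = n_instances,
                config = list(n_total = n_total, share = share,
                              alpha = alpha, n_instances = n_instances))
}
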