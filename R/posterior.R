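#' Posterior edge-probability matrix
#'
#' Averages the closed-form conditional edge probabilities Q_ij(theta) over
#' the posterior parameter draws (Rao-Blackwellized estimate of
#' `P(B_ij = 1 | M)`): lower variance than, and the same expectation as,
#' counting sampled binary networks.
#'
#' @param draws a `parameter_draws` object from [sample_parameters()].
#' @param data the [visitation_matrix()] the draws were fitted to.
#' @return an `edge_probability_matrix` with attribute `n_theta` equal to
#'   the number of draws averaged.
#' @export
posterior_edge_matrix <- function(draws, data) {
  n <- n_draws(draws)
  stopifnot(n >= 1)
  Q <- matrix(0, nrow(data), ncol(data))
  M <- unclass(data)
  for (k in seq_len(n)) {
    Q <- Q + cpp_edge_prob(M, draws$C[k], draws$r[k], draws$rho[k],
                           draws$sigma[k, ], draws$tau[k, ])
  }
  Q <- Q / n
  dimnames(Q) <- dimnames(data)
  structure(Q, n_theta = n,
            class = c("edge_probability_matrix", "matrix", "array"))
}

#' Sample a binary network from edge probabilities
#'
#' Independent Bernoulli draws per species pair; this is exact conditional
#' sampling of the incidence matrix given parameters, since the conditional
#' posterior of B factorizes over entries.
#'
#' @param edge_probs an `edge_probability_matrix` (or any matrix in \[0,1\]).
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used when sampling many networks inside an outer loop).
#' @return an [incidence_matrix()].
#' @export
sample_incidence <- function(edge_probs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- unclass(edge_probs)
  B <- matrix(as.double(stats::runif(length(Q)) < Q), nrow(Q), ncol(Q))
  dimnames(B) <- dimnames(Q)
  incidence_matrix(B)
}

#' Posterior average of a network/parameter function
#'
#' Monte Carlo estimate of `<f(B, theta)>` over the joint posterior: for
#' each parameter draw theta_k, `n_networks_per_draw` incidence matrices are
#' sampled from their conditional distribution and `f` is evaluated on each
#' pair. Returns the grand mean, the Monte Carlo standard error computed
#' across per-draw means, and the per-draw means themselves (useful for
#' plotting posterior metric distributions).
#'
#' @param f function of `(network, params)` returning a numeric scalar.
#' @param draws a `parameter_draws` object.
#' @param data the fitted [visitation_matrix()].
#' @param n_networks_per_draw number of network samples per parameter draw.
#' @param seed integer seed for the network sampling.
#' @return a `posterior_estimate` list: `estimate`, `se`, `samples`.
#' @export
posterior_average <- function(f, draws, data, n_networks_per_draw = 1L,
                              seed = 1L) {
  stopifnot(n_networks_per_draw >= 1)
  n <- n_draws(draws)
  set.seed(seed)
  M <- unclass(data)
  per_draw <- numeric(n)
  for (k in seq_len(n)) {
    Q <- cpp_edge_prob(M, draws$C[k], draws$r[k], draws$rho[k],
                       draws$sigma[k, ], draws$tau[k, ])
    dimnames(Q) <- dimnames(data)
    params <- get_draw(draws, k)
    vals <- vapply(seq_len(n_networks_per_draw), function(l) {
      B <- sample_incidence(Q)
      val <- tryCatch(f(B, params), error = function(e)
        stop(sprintf("posterior_average: f failed at draw %d: %s",
                     k, conditionMessage(e)), call. = FALSE))
      as.numeric(val)
    }, numeric(1))
    per_draw[k] <- mean(vals)
  }
  est <- mean(per_draw)
  se <- if (n > 1) stats::sd(per_draw) / sqrt(n) else 0
  structure(list(estimate = est, se = se, samples = per_draw),
            class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("posterior estimate: %.6g (MC se %.3g, %d samples)\n",
              x$estimate, x$se, length(x$samples)))
  invisible(x)
}

#' Posterior distribution of a network metric
#'
#' Convenience wrapper around [posterior_average()] that packages the
#' per-draw metric values with their summary (mean, sd, central 95%
#' interval).
#'
#' @inheritParams posterior_average
#' @return a `metric_distribution` list: `samples`, `mean`, `sd`, `ci95`.
#' @export
metric_distribution <- function(f, draws, data, n_networks_per_draw = 1L,
                                seed = 1L) {
  est <- posterior_average(f, draws, data, n_networks_per_draw, seed)
  structure(list(samples = est$samples, mean = est$estimate,
                 sd = stats::sd(est$samples),
                 ci95 = unname(stats::quantile(est$samples, c(0.025, 0.975)))),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("metric distribution: mean %.4g, sd %.4g, 95%% CI [%.4g, %.4g] (%d samples)\n",
              x$mean, x$sd, x$ci95[1], x$ci95[2], length(x$samples)))
  invisible(x)
}

#' Mean entropy of edge probabilities
#'
#' Average binary entropy `-[Q log Q + (1-Q) log(1-Q)]` over species pairs;
#' a global measure of network uncertainty (0 when every edge is certain).
#'
#' @param edge_probs an `edge_probability_matrix`.
#' @return non-negative scalar (nats).
#' @export
edge_entropy <- function(edge_probs) {
  q <- as.vector(unclass(edge_probs))
  h <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log1p(-p))
  mean(h(q))
}
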