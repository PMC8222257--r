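#' Expected visitation matrix
#'
#' The Poisson mean for every plant-pollinator pair:
#' `mu_ij = C * sigma_i * tau_j * (1 + r * B_ij)`. Preferred interactions
#' (edges of `network`) multiply the baseline visit rate by `1 + r`.
#'
#' @param params a [model_parameters()] object.
#' @param network an [incidence_matrix()] with dimensions matching `params`.
#' @return matrix of non-negative Poisson means.
#' @export
compute_mean_matrix <- function(params, network) {
  stopifnot(inherits(params, "model_parameters"))
  if (nrow(network) != length(params$sigma) ||
      ncol(network) != length(params$tau))
    stop("dimension mismatch between parameters and incidence matrix")
  mu <- params$C * outer(params$sigma, params$tau) * (1 + params$r * unclass(network))
  dimnames(mu) <- dimnames(network)
  mu
}

#' Poisson log-likelihood of a visitation matrix
#'
#' Exact log of the data likelihood: independent Poisson counts with means
#' from [compute_mean_matrix()], including the `log(M_ij!)` normalization so
#' that `exp()` of the result is a true probability. A structurally
#' impossible observation (`mu_ij = 0` with `M_ij > 0`) gives `-Inf`.
#'
#' @param data a [visitation_matrix()].
#' @param network an [incidence_matrix()].
#' @param params a [model_parameters()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, network, params) {
  .match_dims(data, network, "incidence matrix")
  mu <- compute_mean_matrix(params, network)
  sum(stats::dpois(as.vector(unclass(data)), as.vector(mu), log = TRUE))
}

#' Joint log-posterior of a network and parameters
#'
#' Up to an additive constant shared by all `(B, theta)`:
#' log-likelihood plus the Bernoulli(rho) prior on every edge and the
#' exponential(lambda_r) prior on r. Uniform priors on C, rho and the
#' abundance simplexes contribute only constants. Degenerate priors are
#' honoured exactly: `rho = 0` with an edge present (or `rho = 1` with one
#' absent) gives `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param prior a [prior_config()].
#' @return scalar log-posterior (unnormalized).
#' @export
log_posterior_joint <- function(data, network, params, prior = prior_config()) {
  .match_dims(data, network, "incidence matrix")
  B <- unclass(network)
  n_edge <- sum(B)
  n_gap <- length(B) - n_edge
  edge_lp <- 0
  edge_lp <- edge_lp + (if (n_edge > 0) n_edge * log(params$rho) else 0)
  edge_lp <- edge_lp + (if (n_gap > 0) n_gap * log1p(-params$rho) else 0)
  if (!is.null(prior$c_upper) && params$C > prior$c_upper) return(-Inf)
  log_likelihood(data, network, params) + edge_lp +
    stats::dexp(params$r, prior$lambda_r, log = TRUE)
}

#' Marginal log-posterior of the parameters
#'
#' The latent incidence matrix is summed out analytically, leaving
#' `log P(theta | M)` up to a theta-independent constant:
#' `-C - lambda_r * r + sum_ij M_ij log(C sigma_i tau_j) + sum_ij Y_ij`,
#' where each `Y_ij` is evaluated by a two-branch log-sum-exp that stays
#' finite for very large counts, r, or C. The `log(M_ij!)` constants are
#' dropped (they cancel in sampling); [log_likelihood()] retains them.
#'
#' @param params a [model_parameters()].
#' @param data a [visitation_matrix()].
#' @param prior a [prior_config()].
#' @return scalar log-density, up to a constant.
#' @export
log_marginal_posterior <- function(params, data, prior = prior_config()) {
  stopifnot(inherits(params, "model_parameters"))
  if (nrow(data) != length(params$sigma) || ncol(data) != length(params$tau))
    stop("dimension mismatch between parameters and data")
  if (!is.null(prior$c_upper) && params$C > prior$c_upper) return(-Inf)
  cpp_log_marginal(unclass(data), params$C, params$r, params$rho,
                   params$sigma, params$tau, prior$lambda_r)
}

#' Per-edge posterior probabilities at fixed parameters
#'
#' The conditional probability that each preferred interaction exists given
#' the data and one parameter set:
#' `Q_ij = rho (1+r)^M_ij e^{-C r sigma_i tau_j} / (1 - rho + rho (1+r)^M_ij
#' e^{-C r sigma_i tau_j})`, computed on the logit scale for stability. When
#' the preference factor is zero the data carry no edge information and every
#' entry equals `rho`.
#'
#' @param params a [model_parameters()].
#' @param data a [visitation_matrix()].
#' @return an `edge_probability_matrix`: a numeric matrix in \[0, 1\] with the
#'   data's dimnames and an `n_theta` attribute of 1.
#' @export
edge_probability <- function(params, data) {
  stopifnot(inherits(params, "model_parameters"))
  if (nrow(data) != length(params$sigma) || ncol(data) != length(params$tau))
    stop("dimension mismatch between parameters and data")
  Q <- cpp_edge_prob(unclass(data), params$C, params$r, params$rho,
                     params$sigma, params$tau)
  dimnames(Q) <- dimnames(data)
  structure(Q, n_theta = 1L,
            class = c("edge_probability_matrix", "matrix", "array"))
}

# target density on the unconstrained scale (internal; used by the sampler
# and by gradient-correctness tests)
.target_grad <- function(M, z, prior) {
  cpp_target_grad(M, z, prior$lambda_r,
                  if (is.null(prior$c_upper)) -1 else prior$c_upper)
}

# unconstrained <-> constrained transforms (gamma/softmax chart for the
# simplexes; see the methods vignette)
.z_to_params <- function(z, n_p, n_a) {
  s <- z[4:(3 + n_p)]
  t <- z[(4 + n_p):(3 + n_p + n_a)]
  sg <- exp(s - max(s)); sg <- sg / sum(sg)
  tu <- exp(t - max(t)); tu <- tu / sum(tu)
  model_parameters(C = exp(z[1]), r = exp(z[2]), rho = stats::plogis(z[3]),
                   sigma = sg, tau = tu)
}

.params_to_z <- function(params) {
  c(log(params$C), log(params$r), stats::qlogis(params$rho),
    log(params$sigma), log(params$tau))
}
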