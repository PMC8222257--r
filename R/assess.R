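#' Posterior-predictive summary
#'
#' Computes the posterior-predictive mean matrix
#' `lambda_ij = (1/n) sum_k [Q_ij(theta_k) mu_ij(B=1) + (1-Q_ij(theta_k)) mu_ij(B=0)]`
#' (equivalently `C sigma_i tau_j (1 + r Q_ij)` averaged over draws), the
#' residue `M - lambda`, the chi-squared discrepancy and its reference
#' degrees of freedom. The per-entry predictive standard deviation is
#' `sqrt(lambda)` (the predictive count is Poisson given B and theta, so its
#' mean and variance coincide; the mixture over draws adds the cross-draw
#' spread, reported separately as `lambda_sd`).
#'
#' @param draws a `parameter_draws` object.
#' @param data the fitted [visitation_matrix()].
#' @return a `predictive_summary` list: `predictive_mean`, `predictive_sd`,
#'   `lambda_sd`, `residue`, `x2`, `dof`, `x2_over_dof`.
#' @export
predictive_mean <- function(draws, data) {
  n <- n_draws(draws)
  stopifnot(n >= 1)
  M <- unclass(data)
  lam <- matrix(0, nrow(M), ncol(M))
  lam2 <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(n)) {
    Q <- cpp_edge_prob(M, draws$C[k], draws$r[k], draws$rho[k],
                       draws$sigma[k, ], draws$tau[k, ])
    mu0 <- draws$C[k] * outer(draws$sigma[k, ], draws$tau[k, ])
    lk <- mu0 * (1 + draws$r[k] * Q)
    lam <- lam + lk
    lam2 <- lam2 + lk^2
  }
  lam <- lam / n
  lambda_sd <- sqrt(pmax(lam2 / n - lam^2, 0))
  dimnames(lam) <- dimnames(data)
  res <- unclass(data) - lam
  out <- structure(list(predictive_mean = lam,
                        predictive_sd = sqrt(lam),
                        lambda_sd = lambda_sd,
                        residue = res,
                        x2 = NA_real_, dof = nrow(M) * ncol(M),
                        x2_over_dof = NA_real_),
                   class = "predictive_summary")
  out$x2 <- discrepancy(data, out)
  out$x2_over_dof <- out$x2 / out$dof
  out
}

#' Chi-squared discrepancy between data and predictive mean
#'
#' `X^2 = sum_ij (M_ij - lambda_ij)^2 / lambda_ij`. Under a correct model
#' X^2 is approximately chi-squared with `n_p * n_a` degrees of freedom, so
#' values well below `dof` indicate a good fit. Entries with
#' `lambda_ij = 0` contribute 0 when `M_ij = 0` and make the discrepancy
#' infinite (with a warning) otherwise.
#'
#' @param data a [visitation_matrix()].
#' @param summary a `predictive_summary`, or any matrix of predictive means.
#' @return non-negative scalar.
#' @export
discrepancy <- function(data, summary) {
  lam <- if (inherits(summary, "predictive_summary"))
    summary$predictive_mean else unclass(summary)
  .match_dims(data, lam, "predictive mean")
  M <- unclass(data)
  bad <- lam == 0 & M > 0
  if (any(bad)) {
    warning("predictive mean is zero where counts are positive: infinite discrepancy")
    return(Inf)
  }
  ok <- lam > 0
  sum((M[ok] - lam[ok])^2 / lam[ok])
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat(sprintf("predictive_summary: X^2 = %.4g on %d dof (X^2/dof = %.3g)\n",
              x$x2, x$dof, x$x2_over_dof))
  invisible(x)
}

#' Simulate a replicate data set from one posterior draw
#'
#' Draws a network from its conditional distribution given the parameters
#' and the data, then Poisson counts from the model means: a sample from the
#' posterior-predictive distribution used in model checking.
#'
#' @param params a [model_parameters()] draw.
#' @param data the observed [visitation_matrix()].
#' @param seed optional seed; `NULL` continues the RNG stream.
#' @return a [visitation_matrix()] replicate.
#' @export
predictive_replicate <- function(params, data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- edge_probability(params, data)
  B <- sample_incidence(Q)
  generate_visitation(params, B)
}
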