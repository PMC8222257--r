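#' Sampler configuration
#'
#' Defaults follow the reference analysis protocol: four independent runs,
#' 5000 warmup iterations each, then 500 retained draws per run (2000 draws
#' pooled). Step size is tuned by dual averaging to a target acceptance
#' statistic and a diagonal mass matrix is estimated during warmup.
#'
#' @param chains number of independent chains (>= 1).
#' @param warmup warmup (equilibration) iterations per chain, discarded.
#' @param draws retained draws per chain.
#' @param target_accept dual-averaging target acceptance statistic in (0, 1).
#' @param int_time nominal integration time of a trajectory; the number of
#'   leapfrog steps is `int_time / step_size`, capped at `max_leapfrog` and
#'   jittered uniformly to avoid periodicity.
#' @param max_leapfrog cap on leapfrog steps per trajectory.
#' @param init_attempts re-initialization budget when the starting point has
#'   non-finite posterior density.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(chains = 4L, warmup = 5000L, draws = 500L,
                           target_accept = 0.8, int_time = 1.2,
                           max_leapfrog = 64L, init_attempts = 100L) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1,
            target_accept > 0, target_accept < 1,
            int_time > 0, max_leapfrog >= 1, init_attempts >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), target_accept = target_accept,
                 int_time = int_time, max_leapfrog = as.integer(max_leapfrog),
                 init_attempts = as.integer(init_attempts)),
            class = "sampler_config")
}

#' Sample model parameters from the marginal posterior
#'
#' Runs Hamiltonian Monte Carlo on the unconstrained transform of
#' theta = (C, r, rho, sigma, tau), targeting the marginal posterior in
#' which the latent incidence matrix has been summed out (see
#' [log_marginal_posterior()]). All change-of-variables terms are included,
#' so retained draws are distributed according to the constrained-scale
#' posterior. Identical seed, configuration and data give identical draws.
#'
#' @param data a [visitation_matrix()].
#' @param prior a [prior_config()].
#' @param config a [sampler_config()].
#' @param seed integer RNG seed.
#' @return a `parameter_draws` object: per-draw C, r, rho, abundance
#'   matrices, chain ids, and marginal log-posterior values.
#' @export
sample_parameters <- function(data, prior = prior_config(),
                              config = sampler_config(), seed = 1L) {
  stopifnot(inherits(config, "sampler_config"))
  M <- unclass(data)
  if (any(rowSums(M) == 0) || any(colSums(M) == 0))
    warning("data contain species with zero observed visits; their abundance parameters are weakly identified")
  set.seed(seed)
  chains <- lapply(seq_len(config$chains), function(ch)
    .run_chain(M, prior, config))
  n_p <- nrow(M); n_a <- ncol(M)
  per <- config$draws
  out <- list(
    C = unlist(lapply(chains, `[[`, "C")),
    r = unlist(lapply(chains, `[[`, "r")),
    rho = unlist(lapply(chains, `[[`, "rho")),
    sigma = do.call(rbind, lapply(chains, `[[`, "sigma")),
    tau = do.call(rbind, lapply(chains, `[[`, "tau")),
    lp = unlist(lapply(chains, `[[`, "lp")),
    chain = rep(seq_len(config$chains), each = per),
    accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
    step_size = vapply(chains, `[[`, numeric(1), "step_size"),
    config = config, prior = prior, seed = seed,
    plant_labels = rownames(data), pollinator_labels = colnames(data))
  colnames(out$sigma) <- rownames(data)
  colnames(out$tau) <- colnames(data)
  structure(out, class = "parameter_draws")
}

#' Number of retained draws
#' @param draws a `parameter_draws` object.
#' @export
n_draws <- function(draws) length(draws$C)

#' Extract one posterior draw as a parameter object
#' @param draws a `parameter_draws` object.
#' @param k draw index.
#' @return a [model_parameters()].
#' @export
get_draw <- function(draws, k) {
  stopifnot(k >= 1, k <= n_draws(draws))
  model_parameters(C = draws$C[k], r = draws$r[k], rho = draws$rho[k],
                   sigma = draws$sigma[k, ], tau = draws$tau[k, ])
}

#' @export
print.parameter_draws <- function(x, ...) {
  cat(sprintf("parameter_draws: %d draws (%d chains x %d), %d plants x %d pollinators\n",
              n_draws(x), x$config$chains, x$config$draws,
              ncol(x$sigma), ncol(x$tau)))
  cat(sprintf("  posterior means: <C> = %.3g, <r> = %.3g, <rho> = %.3g\n",
              mean(x$C), mean(x$r), mean(x$rho)))
  invisible(x)
}

#' Flatten draws to a draw archive data frame
#'
#' One row per retained draw: chain, iteration, C, r, rho, the abundance
#' vectors (`sigma_<label>`, `tau_<label>`) and the marginal log-posterior.
#'
#' @param x a `parameter_draws` object.
#' @param ... unused.
#' @export
as.data.frame.parameter_draws <- function(x, ...) {
  sg <- x$sigma; colnames(sg) <- paste0("sigma_", colnames(sg))
  tu <- x$tau; colnames(tu) <- paste0("tau_", colnames(tu))
  data.frame(chain = x$chain,
             iteration = stats::ave(x$chain, x$chain, FUN = seq_along),
             C = x$C, r = x$r, rho = x$rho, sg, tu,
             log_posterior = x$lp, check.names = FALSE)
}

#' Convergence diagnostics for posterior draws
#'
#' Reports split-chain potential-scale-reduction statistics (Rhat) for the
#' scalar parameters C, r and rho, per-chain mean marginal log-posterior,
#' and a trapped-chain flag: a chain is considered trapped at a local
#' optimum when its mean log-posterior falls below the best chain's mean by
#' more than `trapped_sd_mult` within-chain standard deviations of the best
#' chain. A flagged run should be repeated with a fresh seed.
#'
#' @param draws a `parameter_draws` object.
#' @param trapped_sd_mult multiple of the best chain's log-posterior spread
#'   used as the trapped threshold (default 5).
#' @return a `convergence_report` list with elements `rhat`, `chain_lp_mean`,
#'   `trapped`, `flagged_chains`.
#' @export
check_convergence <- function(draws, trapped_sd_mult = 5) {
  ch <- draws$chain
  n_chain <- length(unique(ch))
  lp_mean <- tapply(draws$lp, ch, mean)
  lp_sd <- tapply(draws$lp, ch, stats::sd)
  if (n_chain < 2) {
    warning("single chain: between-chain diagnostics unavailable")
    rep <- list(rhat = c(C = NA_real_, r = NA_real_, rho = NA_real_),
                chain_lp_mean = lp_mean, trapped = FALSE,
                flagged_chains = integer(0))
    return(structure(rep, class = "convergence_report"))
  }
  rhat <- c(C = .split_rhat(draws$C, ch),
            r = .split_rhat(draws$r, ch),
            rho = .split_rhat(draws$rho, ch))
  best <- which.max(lp_mean)
  spread <- lp_sd[best]
  if (!is.finite(spread) || spread == 0) spread <- .Machine$double.eps
  flagged <- which(lp_mean < lp_mean[best] - trapped_sd_mult * spread)
  rep <- list(rhat = rhat, chain_lp_mean = lp_mean,
              trapped = length(flagged) > 0,
              flagged_chains = as.integer(names(lp_mean)[flagged]))
  structure(rep, class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence_report\n  split Rhat:",
      paste(sprintf("%s = %.3f", names(x$rhat), x$rhat), collapse = ", "),
      "\n  chain mean log-posterior:",
      paste(sprintf("%.2f", x$chain_lp_mean), collapse = ", "), "\n")
  if (x$trapped)
    cat("  TRAPPED chains:", paste(x$flagged_chains, collapse = ", "),
        "- repeat the calculation\n")
  else cat("  no trapped chains\n")
  invisible(x)
}

# ---- internals ---------------------------------------------------------

# split-chain Rhat (each chain halved, then standard between/within ratio)
.split_rhat <- function(x, chain) {
  pieces <- list()
  for (c_id in unique(chain)) {
    xi <- x[chain == c_id]
    h <- floor(length(xi) / 2)
    if (h < 2) return(NA_real_)
    pieces <- c(pieces, list(xi[1:h], xi[(h + 1):(2 * h)]))
  }
  m <- length(pieces); n <- length(pieces[[1]])
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# dispersed but data-informed random start: abundances near the observed
# margins, preference factor log-uniform over two decades, and C solved
# from the model's own first moment, E[total] = C (1 + r rho)
.random_init <- function(M, prior) {
  n_p <- nrow(M); n_a <- ncol(M)
  R <- rowSums(M) + 0.5; K <- colSums(M) + 0.5
  r0 <- exp(stats::runif(1, 0, log(200)))
  rho0 <- stats::runif(1, 0.1, 0.6)
  C0 <- max(sum(M), 1) / (1 + r0 * rho0) * exp(stats::rnorm(1, 0, 0.3))
  c(log(C0), log(r0), stats::qlogis(rho0),
    log(R / sum(R)) + stats::rnorm(n_p, 0, 0.3),
    log(K / sum(K)) + stats::rnorm(n_a, 0, 0.3))
}

# The marginal posterior is multimodal: secondary optima explain large
# counts through inflated C and r instead of edges. Each chain therefore
# starts from the best of a few short gradient ascents from dispersed
# starts, which lands most chains in the dominant basin while leaving
# enough diversity for the trapped-chain diagnostic to catch failures.
.map_init <- function(M, prior, n_starts = 5L, maxit = 400L) {
  fn <- function(z) {
    v <- .target_grad(M, z, prior)
    if (!is.finite(v$lp)) 1e10 else -v$lp
  }
  gr <- function(z) {
    v <- .target_grad(M, z, prior)
    if (!is.finite(v$lp)) numeric(length(z)) else -v$grad
  }
  best <- NULL; best_val <- Inf
  for (k in seq_len(n_starts)) {
    z0 <- .random_init(M, prior)
    o <- tryCatch(
      stats::optim(z0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = maxit)),
      error = function(e) list(par = z0, value = fn(z0)))
    if (o$value < best_val) { best <- o$par; best_val <- o$value }
  }
  if (!is.finite(best_val) || best_val >= 1e10) return(NULL)
  polished <- .polish_flips(M, prior, list(par = best, value = best_val),
                            fn, gr)
  # jitter off the optimum so chains do not all start at the same point
  polished$par + stats::rnorm(length(polished$par), 0, 0.05)
}

# The model has an exact reflection degeneracy: a species with no edges and
# abundance x is likelihood-equivalent to one with edges to every partner
# and abundance x/(1+r); only the Bernoulli(rho) prior separates the two.
# Gradient ascent can settle on the wrong side for zero-degree species, so
# the optimum is polished with discrete complement flips (scale the
# abundance by 1+r, re-optimize briefly, keep improvements).
.polish_flips <- function(M, prior, o, fn, gr, max_sweeps = 3L) {
  n_p <- nrow(M); n_a <- ncol(M)
  for (sweep in seq_len(max_sweeps)) {
    p <- .z_to_params(o$par, n_p, n_a)
    Q <- cpp_edge_prob(M, p$C, p$r, p$rho, p$sigma, p$tau)
    improved <- FALSE
    # majority-on rows/columns are candidates: the flipped optimum may keep
    # a few cells on, so an exact all-ones test misses partial complements
    flips <- c(lapply(which(colMeans(Q) > 0.5), function(j) 3L + n_p + j),
               lapply(which(rowMeans(Q) > 0.5), function(i) 3L + i))
    for (idx in flips) {
      z2 <- o$par
      z2[idx] <- z2[idx] + log1p(p$r)
      o2 <- tryCatch(
        stats::optim(z2, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = 100L)),
        error = function(e) NULL)
      if (!is.null(o2) && o2$value < o$value - 1e-8) {
        o <- o2; improved <- TRUE
      }
    }
    if (!improved) break
  }
  o
}

.leapfrog <- function(M, prior, z, p, eps, L, invmass) {
  tg <- .target_grad(M, z, prior)
  if (!is.finite(tg$lp)) return(list(lp = -Inf))
  g <- tg$grad
  for (l in seq_len(L)) {
    p <- p + 0.5 * eps * g
    z <- z + eps * invmass * p
    tg <- .target_grad(M, z, prior)
    if (!is.finite(tg$lp)) return(list(lp = -Inf))
    g <- tg$grad
    p <- p + 0.5 * eps * g
  }
  list(z = z, p = p, lp = tg$lp)
}

.initial_eps <- function(M, prior, z, invmass) {
  d <- length(z)
  eps <- 0.1
  p0 <- stats::rnorm(d) / sqrt(invmass)
  lp0 <- .target_grad(M, z, prior)$lp
  h0 <- lp0 - 0.5 * sum(p0^2 * invmass)
  step_ratio <- function(eps) {
    out <- .leapfrog(M, prior, z, p0, eps, 1L, invmass)
    if (!is.finite(out$lp)) return(-Inf)
    (out$lp - 0.5 * sum(out$p^2 * invmass)) - h0
  }
  dir <- if (step_ratio(eps) > log(0.5)) 1 else -1
  for (k in 1:30) {
    eps_new <- eps * 2^dir
    if (dir > 0 && step_ratio(eps_new) <= log(0.5)) break
    if (dir < 0 && step_ratio(eps_new) > log(0.5)) { eps <- eps_new; break }
    eps <- eps_new
  }
  eps
}

.run_chain <- function(M, prior, config) {
  n_p <- nrow(M); n_a <- ncol(M)
  d <- 3L + n_p + n_a

  z <- NULL
  for (a in seq_len(config$init_attempts)) {
    cand <- .map_init(M, prior)
    if (!is.null(cand) && is.finite(.target_grad(M, cand, prior)$lp)) {
      z <- cand; break
    }
  }
  if (is.null(z))
    stop("could not find an initialization with finite posterior density")

  invmass <- rep(1, d)
  eps <- .initial_eps(M, prior, z, invmass)

  # dual averaging state (Hoffman & Gelman defaults)
  da_reset <- function(eps) list(mu = log(10 * eps), log_eps_bar = log(eps),
                                 hbar = 0, count = 0)
  da <- da_reset(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  warmup <- config$warmup
  win_lo <- floor(0.25 * warmup); win_hi <- floor(0.75 * warmup)
  acc_z <- matrix(0, nrow = max(win_hi - win_lo, 1), ncol = d)
  acc_n <- 0L

  n_keep <- config$draws
  keep <- matrix(NA_real_, n_keep, d)
  lp_keep <- numeric(n_keep)
  n_accept <- 0L

  lp_cur <- .target_grad(M, z, prior)$lp
  total <- warmup + n_keep
  for (iter in seq_len(total)) {
    p0 <- stats::rnorm(d) / sqrt(invmass)
    h0 <- lp_cur - 0.5 * sum(p0^2 * invmass)
    L_nom <- as.integer(max(1, min(config$max_leapfrog,
                                   ceiling(config$int_time / max(eps, 1e-8)))))
    L <- sample.int(L_nom, 1L)
    prop <- .leapfrog(M, prior, z, p0, eps, L, invmass)
    if (is.finite(prop$lp)) {
      h1 <- prop$lp - 0.5 * sum(prop$p^2 * invmass)
      alpha <- min(1, exp(h1 - h0))
      if (!is.finite(alpha)) alpha <- 0  # divergent trajectory: reject
    } else alpha <- 0
    if (stats::runif(1) < alpha) {
      z <- prop$z; lp_cur <- prop$lp
      if (iter > warmup) n_accept <- n_accept + 1L
    }

    if (iter <= warmup) {
      # dual averaging of the step size toward the target acceptance
      da$count <- da$count + 1
      w <- 1 / (da$count + t0)
      da$hbar <- (1 - w) * da$hbar + w * (config$target_accept - alpha)
      log_eps <- da$mu - sqrt(da$count) / gamma * da$hbar
      eta <- da$count^(-kappa)
      da$log_eps_bar <- eta * log_eps + (1 - eta) * da$log_eps_bar
      eps <- exp(log_eps)

      if (iter > win_lo && iter <= win_hi) {
        acc_n <- acc_n + 1L
        acc_z[acc_n, ] <- z
      }
      if (iter == win_hi && acc_n > 10L) {
        # regularized diagonal mass estimate (inverse mass = posterior var)
        v <- apply(acc_z[seq_len(acc_n), , drop = FALSE], 2, stats::var)
        invmass <- v * acc_n / (acc_n + 5) + 1e-3 * 5 / (acc_n + 5)
        eps <- exp(da$log_eps_bar)
        da <- da_reset(eps)
      }
      if (iter == warmup && warmup > 0) eps <- exp(da$log_eps_bar)
    } else {
      keep[iter - warmup, ] <- z
      lp_keep[iter - warmup] <- lp_cur
    }
  }

  pars <- apply(keep, 1, .z_to_params, n_p = n_p, n_a = n_a)
  lp_marg <- vapply(seq_len(n_keep), function(k)
    cpp_log_marginal(M, pars[[k]]$C, pars[[k]]$r, pars[[k]]$rho,
                     pars[[k]]$sigma, pars[[k]]$tau, prior$lambda_r),
    numeric(1))
  list(C = vapply(pars, `[[`, numeric(1), "C"),
       r = vapply(pars, `[[`, numeric(1), "r"),
       rho = vapply(pars, `[[`, numeric(1), "rho"),
       sigma = do.call(rbind, lapply(pars, `[[`, "sigma")),
       tau = do.call(rbind, lapply(pars, `[[`, "tau")),
       lp = lp_marg,
       accept_rate = n_accept / n_keep,
       step_size = eps)
}
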