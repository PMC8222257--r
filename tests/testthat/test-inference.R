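test_that("edge_probability matches its closed form and degenerate limits", {
  M <- visitation_matrix(matrix(c(5, 0, 2, 1, 0, 3), 2, 3))
  # r = 0: every entry equals rho
  p <- model_parameters(10, 0, 0.37, c(0.4, 0.6), rep(1 / 3, 3))
  expect_equal(unname(unclass(edge_probability(p, M))), matrix(0.37, 2, 3),
               ignore_attr = TRUE)
  # degenerate rho
  p0 <- model_parameters(10, 4, 0, c(0.4, 0.6), rep(1 / 3, 3))
  p1 <- model_parameters(10, 4, 1, c(0.4, 0.6), rep(1 / 3, 3))
  expect_equal(unname(unclass(edge_probability(p0, M))), matrix(0, 2, 3),
               ignore_attr = TRUE)
  expect_equal(unname(unclass(edge_probability(p1, M))), matrix(1, 2, 3),
               ignore_attr = TRUE)
})

test_that("edge_probability equals enumeration-based marginals on 2x3", {
  set.seed(8)
  M <- visitation_matrix(matrix(c(4, 0, 1, 2, 0, 6), 2, 3))
  for (k in 1:5) {
    p <- generate_parameters(2, 3, C = runif(1, 3, 60),
                             r = runif(1, 0.5, 40), rho = runif(1, 0.1, 0.9))
    expect_equal(unname(unclass(edge_probability(p, M))),
                 enum_edge_prob(M, p), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("sample_incidence is Bernoulli per entry and reproducible", {
  Q1 <- matrix(1, 3, 3); Q0 <- matrix(0, 3, 3)
  expect_equal(unname(unclass(sample_incidence(Q1, seed = 1))), Q1)
  expect_equal(unname(unclass(sample_incidence(Q0, seed = 1))), Q0)
  expect_identical(sample_incidence(matrix(0.5, 4, 4), seed = 3),
                   sample_incidence(matrix(0.5, 4, 4), seed = 3))
  # binomial concentration at n = 1e4
  q <- 0.37
  set.seed(2)
  hits <- mean(vapply(1:10000, function(i)
    unclass(sample_incidence(matrix(q, 1, 1)))[1, 1], numeric(1)))
  expect_lt(abs(hits - q), 3 * sqrt(q * (1 - q) / 1e4))
})

test_that("posterior_edge_matrix averages per-draw probabilities", {
  set.seed(5)
  M <- visitation_matrix(matrix(c(3, 0, 1, 7, 0, 2), 2, 3))
  p1 <- generate_parameters(2, 3, C = 20, r = 10, rho = 0.3)
  p2 <- generate_parameters(2, 3, C = 35, r = 4, rho = 0.6)
  d1 <- fabricate_draws(list(p1))
  expect_equal(unclass(posterior_edge_matrix(d1, M)),
               unclass(edge_probability(p1, M)),
               ignore_attr = TRUE)
  dd <- fabricate_draws(list(p1, p1, p1))
  expect_equal(unclass(posterior_edge_matrix(dd, M)),
               unclass(edge_probability(p1, M)), ignore_attr = TRUE)
  dmix <- fabricate_draws(list(p1, p2))
  manual <- (unclass(edge_probability(p1, M)) +
               unclass(edge_probability(p2, M))) / 2
  expect_equal(unclass(posterior_edge_matrix(dmix, M)), manual,
               ignore_attr = TRUE)
  expect_identical(attr(posterior_edge_matrix(dmix, M), "n_theta"), 2L)
})

test_that("posterior_average has exact behaviour for degenerate f", {
  set.seed(7)
  M <- visitation_matrix(matrix(c(3, 0, 1, 7), 2, 2))
  ps <- lapply(1:6, function(k)
    generate_parameters(2, 2, C = runif(1, 5, 40), r = runif(1, 0, 20),
                        rho = runif(1, 0.2, 0.8)))
  dd <- fabricate_draws(ps, chains = 2L)
  one <- posterior_average(function(B, th) 1, dd, M, seed = 1)
  expect_equal(one$estimate, 1)
  expect_equal(one$se, 0)
  rho_est <- posterior_average(function(B, th) th$rho, dd, M, seed = 1)
  expect_equal(rho_est$estimate, mean(vapply(ps, `[[`, numeric(1), "rho")))
  # error propagation carries the draw index
  expect_error(
    posterior_average(function(B, th) stop("boom"), dd, M, seed = 1),
    "draw 1")
})

test_that("posterior_average of B_ij agrees with the closed-form average", {
  set.seed(12)
  M <- visitation_matrix(matrix(c(6, 0, 2, 1), 2, 2))
  ps <- lapply(1:40, function(k)
    generate_parameters(2, 2, C = runif(1, 5, 40), r = runif(1, 0, 20),
                        rho = runif(1, 0.2, 0.8)))
  dd <- fabricate_draws(ps, chains = 2L)
  Q <- posterior_edge_matrix(dd, M)
  est <- posterior_average(function(B, th) unclass(B)[1, 1], dd, M,
                           n_networks_per_draw = 4L, seed = 2)
  se <- max(est$se, 1e-3)
  expect_lt(abs(est$estimate - unclass(Q)[1, 1]), 3 * se + 0.05)
})

test_that("sampler output satisfies structural invariants and determinism", {
  set.seed(31)
  sc <- synthetic_scenario(n_p = 4, n_a = 5, C = 120, r = 20, rho = 0.3,
                           seed = 31)
  M <- generate_visitation(sc$true_params, sc$true_network)
  cfg <- tiny_config(chains = 2, warmup = 300, draws = 80)
  d1 <- quiet_sample(M, prior_config(), cfg, seed = 5)
  d2 <- quiet_sample(M, prior_config(), cfg, seed = 5)
  expect_identical(d1$C, d2$C)
  expect_identical(d1$sigma, d2$sigma)
  expect_identical(n_draws(d1), 160L)
  expect_lt(max(abs(rowSums(d1$sigma) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(d1$tau) - 1)), 1e-12)
  expect_true(all(d1$C > 0) && all(d1$r >= 0) &&
                all(d1$rho >= 0 & d1$rho <= 1))
  # draw archive layout
  df <- as.data.frame(d1)
  expect_identical(nrow(df), 160L)
  expect_true(all(c("chain", "iteration", "C", "r", "rho", "log_posterior")
                  %in% colnames(df)))
  # zero-count species trigger the weak-identification warning
  M0 <- visitation_matrix(rbind(unclass(M), 0))
  expect_warning(sample_parameters(M0, config = tiny_config(1, 50, 10), seed = 1),
                 "zero observed visits")
})

test_that("chain order does not affect pooled posterior summaries", {
  set.seed(32)
  sc <- synthetic_scenario(n_p = 4, n_a = 5, C = 120, r = 20, rho = 0.3,
                           seed = 32)
  M <- generate_visitation(sc$true_params, sc$true_network)
  d <- quiet_sample(M, config = tiny_config(2, 300, 80), seed = 6)
  perm <- order(d$chain, decreasing = TRUE)
  d_rev <- d
  for (f in c("C", "r", "rho", "lp", "chain")) d_rev[[f]] <- d[[f]][perm]
  d_rev$sigma <- d$sigma[perm, ]; d_rev$tau <- d$tau[perm, ]
  expect_lt(max(abs(unclass(posterior_edge_matrix(d, M)) -
                      unclass(posterior_edge_matrix(d_rev, M)))), 1e-10)
})

test_that("check_convergence flags trapped chains and only those", {
  ps <- lapply(1:40, function(k)
    generate_parameters(2, 2, C = 10, r = 2, rho = 0.4, seed = k))
  dd <- fabricate_draws(ps, chains = 2L)
  dd$lp <- rnorm(40, 0, 1)
  rep_ok <- check_convergence(dd)
  expect_false(rep_ok$trapped)
  # artificial -1000 shift of chain 2
  dd_bad <- dd
  dd_bad$lp[dd_bad$chain == 2] <- dd_bad$lp[dd_bad$chain == 2] - 1000
  rep_bad <- check_convergence(dd_bad)
  expect_true(rep_bad$trapped)
  expect_identical(rep_bad$flagged_chains, 2L)
  # identical chains: no flag, Rhat near 1
  dd_id <- dd
  dd_id$C[dd_id$chain == 2] <- dd_id$C[dd_id$chain == 1]
  dd_id$lp[dd_id$chain == 2] <- dd_id$lp[dd_id$chain == 1]
  expect_false(check_convergence(dd_id)$trapped)
  # single chain: warning and NA Rhat
  d1 <- fabricate_draws(ps[1:10], chains = 1L)
  expect_warning(r1 <- check_convergence(d1), "single chain")
  expect_true(all(is.na(r1$rhat)))
})

test_that("false-alarm rate of the trapped flag is small for healthy chains", {
  # chains drawn from the same distribution should rarely be flagged
  set.seed(99)
  flags <- vapply(1:100, function(k) {
    dd <- fabricate_draws(lapply(1:40, function(i)
      model_parameters(10, 2, 0.4, c(0.5, 0.5), c(0.5, 0.5))), chains = 2L)
    dd$lp <- rnorm(40)
    check_convergence(dd)$trapped
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})

test_that("more sampling effort does not increase edge uncertainty", {
  # averaged over seeds: a single data realization can buck the trend when
  # extra visits happen to land ambiguously
  ent <- sapply(1:6, function(s) {
    sc <- synthetic_scenario(n_p = 5, n_a = 6, C = 50, r = 30, rho = 0.3,
                             seed = 40 + s)
    vapply(c(50, 500), function(C) {
      p <- sc$true_params; p$C <- C
      M <- generate_visitation(p, sc$true_network, seed = 50 + s)
      d <- quiet_sample(M, config = tiny_config(2, 400, 100), seed = 60 + s)
      edge_entropy(posterior_edge_matrix(d, M))
    }, numeric(1))
  })
  expect_lte(mean(ent[2, ]), mean(ent[1, ]) + 0.01)
})

test_that("aggregating replicate matrices sharpens edge probabilities", {
  set.seed(36)
  sc <- synthetic_scenario(n_p = 6, n_a = 8, C = 60, r = 30, rho = 0.3,
                           seed = 36)
  mats <- lapply(1:3, function(k)
    generate_visitation(sc$true_params, sc$true_network))
  mid_frac <- function(M) {
    d <- quiet_sample(M, config = tiny_config(2, 400, 100), seed = 37)
    q <- as.vector(unclass(posterior_edge_matrix(d, M)))
    mean(q > 0.05 & q < 0.95)
  }
  individual <- mean(vapply(mats, mid_frac, numeric(1)))
  aggregated <- mid_frac(aggregate_visitation(mats))
  expect_lte(aggregated, individual)
})
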