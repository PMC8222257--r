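# Independent oracles and small fixtures used across the suite.
# These deliberately avoid the package's own computational paths.

# exhaustive log marginal: log sum over all 2^(np*na) incidence matrices of
# exp(log_posterior_joint); feasible up to 9 cells
enum_log_marginal <- function(data, params, prior = prior_config()) {
  n <- nrow(data) * ncol(data)
  stopifnot(n <= 9)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  lps <- apply(grid, 1, function(bits) {
    B <- incidence_matrix(matrix(as.double(bits), nrow(data), ncol(data)),
                          rownames(data), colnames(data))
    log_posterior_joint(data, B, params, prior)
  })
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# exhaustive per-edge marginal P(B_ij = 1 | M, theta)
enum_edge_prob <- function(data, params, prior = prior_config()) {
  n <- nrow(data) * ncol(data)
  stopifnot(n <= 9)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  lps <- apply(grid, 1, function(bits) {
    B <- incidence_matrix(matrix(as.double(bits), nrow(data), ncol(data)),
                          rownames(data), colnames(data))
    log_posterior_joint(data, B, params, prior)
  })
  w <- exp(lps - max(lps)); w <- w / sum(w)
  matrix(colSums(grid * w), nrow(data), ncol(data))
}

# brute-force NODF written from the metric's definition with explicit
# neighbour sets, independent of the package's matrix-product version
nodf_brute <- function(B) {
  B <- unclass(B)
  score_unordered <- function(neigh) {
    n <- length(neigh)
    tot <- 0
    for (u in seq_len(n - 1)) for (v in (u + 1):n) {
      ku <- length(neigh[[u]]); kv <- length(neigh[[v]])
      hi <- max(ku, kv); lo <- min(ku, kv)
      if (hi > lo && lo > 0) {
        tot <- tot + 100 * length(intersect(neigh[[u]], neigh[[v]])) / lo
      }
    }
    tot
  }
  rows <- lapply(seq_len(nrow(B)), function(i) which(B[i, ] == 1))
  cols <- lapply(seq_len(ncol(B)), function(j) which(B[, j] == 1))
  denom <- nrow(B) * (nrow(B) - 1) / 2 + ncol(B) * (ncol(B) - 1) / 2
  (score_unordered(rows) + score_unordered(cols)) / denom
}

# hand-assembled draws container for tests that need a known posterior
fabricate_draws <- function(params_list, chains = 1L) {
  n <- length(params_list)
  stopifnot(n %% chains == 0)
  sg <- do.call(rbind, lapply(params_list, `[[`, "sigma"))
  tu <- do.call(rbind, lapply(params_list, `[[`, "tau"))
  structure(list(
    C = vapply(params_list, `[[`, numeric(1), "C"),
    r = vapply(params_list, `[[`, numeric(1), "r"),
    rho = vapply(params_list, `[[`, numeric(1), "rho"),
    sigma = sg, tau = tu,
    lp = numeric(n),
    chain = rep(seq_len(chains), each = n / chains),
    accept_rate = rep(1, chains), step_size = rep(0.1, chains),
    config = sampler_config(chains = chains, warmup = 0,
                            draws = n / chains),
    prior = prior_config(), seed = 0L,
    plant_labels = paste0("plant_", seq_len(ncol(sg))),
    pollinator_labels = paste0("pol_", seq_len(ncol(tu)))),
    class = "parameter_draws")
}

quiet_sample <- function(...) suppressWarnings(sample_parameters(...))

# short sampler settings for unit tests (not the acceptance protocol)
tiny_config <- function(chains = 2L, warmup = 400L, draws = 150L)
  sampler_config(chains = chains, warmup = warmup, draws = draws)
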