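#' Threshold a visitation matrix into a binary network
#'
#' The naive baseline the Bayesian reconstruction is compared against:
#' declare an interaction whenever at least `t` visits were observed
#' (`t = 1` is the common "any visit" rule, `t = 5` a conservative one).
#'
#' @param data a [visitation_matrix()].
#' @param t positive integer visit threshold.
#' @return an [incidence_matrix()].
#' @export
threshold_network <- function(data, t = 1L) {
  stopifnot(t >= 1)
  incidence_matrix((unclass(data) >= t) * 1,
                   rownames(data), colnames(data))
}

#' Connectance of a binary network
#'
#' Fraction of all possible plant-pollinator pairs that are connected; the
#' network-level analogue of the model parameter rho.
#'
#' @param network an [incidence_matrix()].
#' @return real in \[0, 1\].
#' @export
connectance <- function(network) {
  mean(unclass(network))
}

#' Nestedness based on Overlap and Decreasing Fill (NODF)
#'
#' For every ordered pair of rows with strictly decreasing positive degrees
#' (`k_u > k_v > 0`) the pair contributes `100 * |N(u) intersect N(v)| / k_v`;
#' pairs with equal degrees or an empty smaller row contribute 0 (the
#' "decreasing fill" requirement), and likewise over column pairs. NODF is
#' the sum of contributions divided by `n_p (n_p - 1) / 2 + n_a (n_a - 1) / 2`,
#' giving a score from 0 (no nesting) to 100 (perfect nesting).
#'
#' @param network an [incidence_matrix()] with at least 2 rows and 2 columns.
#' @return real in \[0, 100\].
#' @export
nodf <- function(network) {
  B <- unclass(network)
  if (nrow(B) < 2 || ncol(B) < 2)
    stop("NODF requires at least 2 rows and 2 columns")
  pair_sum <- function(A) {
    k <- rowSums(A)
    ov <- A %*% t(A)             # shared partners for every row pair
    tot <- 0
    n <- nrow(A)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        hi <- max(k[u], k[v]); lo <- min(k[u], k[v])
        if (hi > lo && lo > 0) tot <- tot + 100 * ov[u, v] / lo
      }
    }
    tot
  }
  n_p <- nrow(B); n_a <- ncol(B)
  denom <- n_p * (n_p - 1) / 2 + n_a * (n_a - 1) / 2
  (pair_sum(B) + pair_sum(t(B))) / denom
}

#' Degree distribution of one side of a bipartite network
#'
#' @param network an [incidence_matrix()].
#' @param side `"plants"` (row degrees) or `"pollinators"` (column degrees).
#' @return named numeric vector `p_k` over k = 0..max degree, summing to 1.
#' @export
degree_distribution <- function(network, side = c("plants", "pollinators")) {
  side <- match.arg(side)
  B <- unclass(network)
  deg <- if (side == "plants") rowSums(B) else colSums(B)
  p <- tabulate(deg + 1, nbins = max(deg) + 1) / length(deg)
  names(p) <- 0:max(deg)
  p
}

#' Posterior-expected mean degree
#'
#' Expected number of partners per species on one side, computed directly
#' from the edge-probability matrix: `sum_ij Q_ij / n_side`. By linearity
#' this equals the posterior mean of the per-network mean degree. The
#' maximum-likelihood Poisson fit to an inferred degree distribution is
#' exactly this mean.
#'
#' @param edge_probs an `edge_probability_matrix`.
#' @param side `"plants"` or `"pollinators"`.
#' @return non-negative real.
#' @export
mean_degree <- function(edge_probs, side = c("plants", "pollinators")) {
  side <- match.arg(side)
  Q <- unclass(edge_probs)
  sum(Q) / if (side == "plants") nrow(Q) else ncol(Q)
}

#' Aggregate visitation matrices across sites or periods
#'
#' Pools observations measuring approximately the same system: the species
#' set of the result is the union of the input labels (matched as exact
#' strings) and counts are summed, species absent from an input contributing
#' zero. Aggregation sharpens edge posteriors by increasing effective
#' sampling effort.
#'
#' @param matrices list of [visitation_matrix()] objects (length >= 1).
#' @return a [visitation_matrix()] over the union of species.
#' @export
aggregate_visitation <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  for (m in matrices) {
    .check_labels(rownames(m), nrow(m), "plant")
    .check_labels(colnames(m), ncol(m), "pollinator")
  }
  plants <- unique(unlist(lapply(matrices, rownames)))
  pols <- unique(unlist(lapply(matrices, colnames)))
  out <- matrix(0, length(plants), length(pols),
                dimnames = list(plants, pols))
  for (m in matrices) out[rownames(m), colnames(m)] <-
    out[rownames(m), colnames(m)] + unclass(m)
  visitation_matrix(out)
}
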