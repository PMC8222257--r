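#' Visitation count matrix
#'
#' Container for the raw field data: a plant x pollinator matrix of
#' non-negative integer visit counts with unique species labels on both
#' sides. This is the sole input to the reconstruction.
#'
#' @param counts numeric matrix of non-negative integers, plants in rows and
#'   pollinators in columns.
#' @param plant_labels,pollinator_labels character vectors of unique species
#'   names; default to the dimnames of `counts` or `plant_1`, `pol_1`, ...
#' @return an object of class `visitation_matrix`: an integer matrix with
#'   dimnames set.
#' @examples
#' M <- visitation_matrix(matrix(c(3, 0, 1, 7), 2, 2))
#' total_visits(M)
#' @export
visitation_matrix <- function(counts, plant_labels = NULL,
                              pollinator_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("visitation matrix needs at least one plant and one pollinator")
  if (anyNA(counts))
    stop("visitation matrix contains missing cells; absences must be explicit zeros")
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("visitation counts must be non-negative integers")
  if (is.null(plant_labels))
    plant_labels <- rownames(counts) %||% paste0("plant_", seq_len(nrow(counts)))
  if (is.null(pollinator_labels))
    pollinator_labels <- colnames(counts) %||% paste0("pol_", seq_len(ncol(counts)))
  .check_labels(plant_labels, nrow(counts), "plant")
  .check_labels(pollinator_labels, ncol(counts), "pollinator")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(plant_labels, pollinator_labels)
  structure(counts, class = c("visitation_matrix", "matrix", "array"))
}

#' Binary incidence matrix of preferred interactions
#'
#' The latent object of the model: `entries[i, j] = 1` when plant i is
#' preferentially visited by pollinator j.
#'
#' @param entries matrix with values in {0, 1}.
#' @param plant_labels,pollinator_labels species labels, as in
#'   [visitation_matrix()].
#' @return an object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(entries, plant_labels = NULL,
                             pollinator_labels = NULL) {
  entries <- as.matrix(entries)
  if (!all(entries %in% c(0, 1)))
    stop("incidence matrix entries must be exactly 0 or 1")
  if (is.null(plant_labels))
    plant_labels <- rownames(entries) %||% paste0("plant_", seq_len(nrow(entries)))
  if (is.null(pollinator_labels))
    pollinator_labels <- colnames(entries) %||% paste0("pol_", seq_len(ncol(entries)))
  .check_labels(plant_labels, nrow(entries), "plant")
  .check_labels(pollinator_labels, ncol(entries), "pollinator")
  storage.mode(entries) <- "double"
  dimnames(entries) <- list(plant_labels, pollinator_labels)
  structure(entries, class = c("incidence_matrix", "matrix", "array"))
}

#' Model parameters theta = (C, r, rho, sigma, tau)
#'
#' @param C positive sampling-effort scale: the global multiplier on expected
#'   counts set by observation time and area.
#' @param r non-negative preference factor; an edge multiplies the expected
#'   number of visits by `1 + r`.
#' @param rho prior edge probability (the connectance parameter), in \[0, 1\].
#' @param sigma,tau relative abundances of plants and pollinators; each must
#'   be a non-negative vector summing to one (they are renormalized when the
#'   sum is within 1e-8 of one, and rejected otherwise).
#' @return an object of class `model_parameters` (a list).
#' @export
model_parameters <- function(C, r, rho, sigma, tau) {
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (C < 0) stop("C must be positive")
  if (r < 0) stop("r must be non-negative")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  sigma <- .check_simplex(sigma, "sigma")
  tau <- .check_simplex(tau, "tau")
  structure(list(C = C, r = r, rho = rho, sigma = sigma, tau = tau),
            class = "model_parameters")
}

#' Prior configuration
#'
#' @param lambda_r rate of the exponential prior on the preference factor r;
#'   default 0.01, a weakly informative prior with mean 100.
#' @param c_upper optional finite upper bound for the otherwise improper
#'   uniform prior on C. `NULL` (the default) leaves the prior unbounded;
#'   the e^{-C} factor of the marginal posterior keeps it proper.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(lambda_r = 0.01, c_upper = NULL) {
  stopifnot(is.numeric(lambda_r), length(lambda_r) == 1L, lambda_r > 0)
  if (!is.null(c_upper))
    stopifnot(is.numeric(c_upper), length(c_upper) == 1L, c_upper > 0)
  structure(list(lambda_r = lambda_r, c_upper = c_upper),
            class = "prior_config")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("model_parameters: C = %.4g, r = %.4g, rho = %.4g, %d plants, %d pollinators\n",
              x$C, x$r, x$rho, length(x$sigma), length(x$tau)))
  invisible(x)
}

#' @export
print.visitation_matrix <- function(x, ...) {
  cat(sprintf("visitation_matrix: %d plants x %d pollinators, %d visits\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Total number of observed visits
#' @param data a [visitation_matrix()].
#' @return integer sum of all counts.
#' @export
total_visits <- function(data) sum(data)

#' Mean number of unique observations per species pair
#'
#' Total visit count divided by the number of plant-pollinator pairs; a
#' simple gauge of sampling intensity (e.g. about 1.2 for a well-sampled
#' single-site month, below 0.4 for undersampled surveys).
#'
#' @param data a [visitation_matrix()], or a single total count when `n_p`
#'   and `n_a` are given.
#' @param n_p,n_a dimensions, only used when `data` is a scalar total.
#' @return real number of observations per pair.
#' @export
observations_per_pair <- function(data, n_p = NULL, n_a = NULL) {
  if (is.null(n_p)) {
    sum(data) / (nrow(data) * ncol(data))
  } else {
    as.numeric(data) / (n_p * n_a)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_labels <- function(labels, n, side) {
  if (length(labels) != n)
    stop(sprintf("%s labels (%d) do not match matrix dimension (%d)",
                 side, length(labels), n))
  if (anyDuplicated(labels))
    stop(sprintf("duplicate %s labels", side))
  invisible(labels)
}

.check_simplex <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s must be a non-negative numeric vector", name))
  s <- sum(x)
  if (abs(s - 1) > 1e-8)
    stop(sprintf("%s must sum to 1 (got %.6f)", name, s))
  x / s
}

.match_dims <- function(data, other, what = "matrix") {
  if (!all(dim(data) == dim(other)))
    stop(sprintf("dimension mismatch between data (%dx%d) and %s (%dx%d)",
                 nrow(data), ncol(data), what, nrow(other), ncol(other)))
  invisible(TRUE)
}
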