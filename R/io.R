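#' Read a visitation matrix from disk
#'
#' Two dialects are supported. `labeled_csv`: first row holds pollinator
#' labels, first column plant labels, cells are integer counts; this is also
#' the format [write_visitation_matrix()] produces. `weblife`: the Web of
#' Life interaction-matrix layout (same row/column orientation, possibly
#' numeric cells stored as decimals), mapped onto the same type. Row and
#' column order are preserved as read. Missing cells are rejected: an
#' unobserved pair must be an explicit zero.
#'
#' @param path file to read.
#' @param format `"labeled_csv"` or `"weblife"`.
#' @param sep field separator (`","` by default; use `"\t"` for TSV).
#' @return a [visitation_matrix()].
#' @export
load_visitation_matrix <- function(path, format = c("labeled_csv", "weblife"),
                                   sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  # header is parsed by hand: read.table would silently deduplicate
  # repeated species labels, which must instead be a structural error
  df <- utils::read.table(path, header = FALSE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", colClasses = "character")
  if (nrow(df) < 2 || ncol(df) < 2)
    stop("expected a header row of pollinator labels and at least one plant row")
  pol_labels <- as.character(df[1, -1])
  plant_labels <- as.character(df[-1, 1])
  mat <- as.matrix(df[-1, -1, drop = FALSE])
  colnames(mat) <- pol_labels
  if (format == "weblife") {
    # Web of Life exports sometimes carry summary columns; drop any column
    # whose label starts with "Num" (e.g. "Number of hosts sampled").
    keep <- !grepl("^num", colnames(mat), ignore.case = TRUE)
    mat <- mat[, keep, drop = FALSE]
  }
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at plant '%s', pollinator '%s'",
                 plant_labels[bad[1]], colnames(mat)[bad[2]]))
  }
  if (any(mat < 0) || any(mat != round(mat))) {
    bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer or negative count at plant '%s', pollinator '%s'",
                 plant_labels[bad[1]], colnames(mat)[bad[2]]))
  }
  visitation_matrix(mat, plant_labels, colnames(mat))
}

#' Write a visitation matrix as labeled CSV
#'
#' @param data a [visitation_matrix()] (or an incidence or edge-probability
#'   matrix; any labelled matrix round-trips).
#' @param path destination file.
#' @param sep field separator.
#' @export
write_visitation_matrix <- function(data, path, sep = ",") {
  df <- data.frame(species = rownames(data), unclass(data),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run configuration for a full fit
#'
#' @param input path to a visitation matrix file.
#' @param format input dialect, see [load_visitation_matrix()].
#' @param prior a [prior_config()].
#' @param sampler a [sampler_config()].
#' @param seed integer seed recorded in all outputs.
#' @param metrics character vector of metric names to compute over the
#'   posterior; any of `"connectance"`, `"nodf"`, `"mean_degree_plants"`,
#'   `"mean_degree_pollinators"`.
#' @param output_dir directory for the artifact bundle.
#' @param rerun_budget number of re-runs allowed when convergence is flagged.
#' @return a `run_config` list.
#' @export
run_config <- function(input, format = "labeled_csv",
                       prior = prior_config(), sampler = sampler_config(),
                       seed = 1L, metrics = c("connectance", "nodf"),
                       output_dir = "pollinet_fit", rerun_budget = 2L) {
  known <- c("connectance", "nodf", "mean_degree_plants",
             "mean_degree_pollinators")
  if (!all(metrics %in% known))
    stop("unknown metric(s): ", paste(setdiff(metrics, known), collapse = ", "))
  structure(list(input = input, format = format, prior = prior,
                 sampler = sampler, seed = as.integer(seed),
                 metrics = metrics, output_dir = output_dir,
                 rerun_budget = as.integer(rerun_budget)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Flat key-value layout mirroring [run_config()] fields, with prior and
#' sampler settings given under `prior` and `sampler` objects, e.g.
#' `{"input": "counts.csv", "seed": 3, "sampler": {"chains": 2}}`.
#' Unspecified settings keep their defaults.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
run_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$input)) stop("config file must name an 'input' matrix")
  pr <- do.call(prior_config, j$prior %||% list())
  sm <- do.call(sampler_config, j$sampler %||% list())
  run_config(input = j$input,
             format = j$format %||% "labeled_csv",
             prior = pr, sampler = sm,
             seed = j$seed %||% 1L,
             metrics = j$metrics %||% c("connectance", "nodf"),
             output_dir = j$output_dir %||% "pollinet_fit",
             rerun_budget = j$rerun_budget %||% 2L)
}

#' Fit a network reconstruction end to end and write an artifact bundle
#'
#' Pipeline: load data, sample the posterior, check convergence (re-running
#' with a shifted seed up to `rerun_budget` times if a chain is trapped),
#' compute edge probabilities, the posterior-predictive summary and the
#' requested posterior metric distributions, and write everything under the
#' configured output directory: `draws.csv`, `edge_probabilities.csv`,
#' `predictive_mean.csv`, `residue.csv`, `assessment.json`,
#' `metrics.json`, per-metric trace CSVs, and `manifest.json` (full
#' configuration, seeds used, package version).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory objects (`data`, `draws`,
#'   `edge_probs`, `assessment`, `metrics`, `convergence`).
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- load_visitation_matrix(config$input, config$format)
  if (config$sampler$chains < 2)
    warning("fewer than 2 chains: trapped-chain detection is unavailable")

  seed <- config$seed
  seeds_used <- integer(0)
  for (attempt in seq_len(config$rerun_budget + 1L)) {
    seeds_used <- c(seeds_used, seed)
    draws <- sample_parameters(data, config$prior, config$sampler, seed)
    conv <- check_convergence(draws)
    if (!conv$trapped) break
    message(sprintf("run_fit: trapped chain(s) %s detected, re-running (attempt %d)",
                    paste(conv$flagged_chains, collapse = ","), attempt + 1L))
    seed <- seed + 1000L
  }
  if (conv$trapped)
    stop("run_fit: convergence still flagged after exhausting the re-run budget")

  edge_probs <- posterior_edge_matrix(draws, data)
  assessment <- predictive_mean(draws, data)

  metric_funs <- list(
    connectance = function(B, th) connectance(B),
    nodf = function(B, th) nodf(B),
    mean_degree_plants = function(B, th) sum(B) / nrow(B),
    mean_degree_pollinators = function(B, th) sum(B) / ncol(B))
  metrics <- lapply(config$metrics, function(name)
    metric_distribution(metric_funs[[name]], draws, data,
                        seed = config$seed + 7L))
  names(metrics) <- config$metrics

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(as.data.frame(draws), out("draws.csv"), row.names = FALSE)
  write_visitation_matrix(edge_probs, out("edge_probabilities.csv"))
  write_visitation_matrix(assessment$predictive_mean, out("predictive_mean.csv"))
  write_visitation_matrix(assessment$residue, out("residue.csv"))
  jsonlite::write_json(list(x2 = assessment$x2, dof = assessment$dof,
                            x2_over_dof = assessment$x2_over_dof),
                       out("assessment.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(metrics, function(m) list(mean = m$mean, sd = m$sd,
                                     ci95 = m$ci95)),
    out("metrics.json"), auto_unbox = TRUE, digits = NA)
  for (name in names(metrics))
    utils::write.csv(data.frame(value = metrics[[name]]$samples),
                     out(paste0("metric_", name, ".csv")), row.names = FALSE)
  manifest <- list(
    input = config$input, format = config$format,
    prior = unclass(config$prior), sampler = unclass(config$sampler),
    seed = config$seed, seeds_used = seeds_used,
    metrics = config$metrics,
    posterior_means = list(C = mean(draws$C), r = mean(draws$r),
                           rho = mean(draws$rho)),
    convergence = list(rhat = as.list(conv$rhat),
                       chain_lp_mean = as.numeric(conv$chain_lp_mean),
                       trapped = conv$trapped),
    package_version = as.character(utils::packageVersion("pollinet")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(data = data, draws = draws, edge_probs = edge_probs,
                 assessment = assessment, metrics = metrics,
                 convergence = conv))
}
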