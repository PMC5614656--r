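#' Monte-Carlo simulation configuration
#'
#' Parameters of the frequency simulation: genes with `M` isoforms get
#' `M` expression draws from the Weibull model `W(a, b)`, converted to
#' descending frequencies. The scale `b` cancels in frequencies and is
#' kept at 1 for all frequency work. All downstream randomness flows from
#' `seed` through deterministic sub-seeds, so every result is
#' reproducible bit-for-bit.
#'
#' @param a Shape parameter in (0, 1] for this regime (default the
#'   canonical 0.39).
#' @param b Scale parameter (default 1).
#' @param reps Simulated genes per isoform count `M` (default 10000;
#'   quantile and tail estimates use larger dedicated defaults).
#' @param M_range Isoform counts simulated (default `1:30`).
#' @param k_max Deepest rank kept in median matrices (default 9).
#' @param seed Master seed (default 1).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(a = 0.39, b = 1, reps = 10000, M_range = 1:30,
                       k_max = 9, seed = 1) {
  if (!is_scalar_number(a) || a <= 0 || a > 1)
    stopf("`a` must be in (0, 1] for the frequency simulation")
  if (!is_scalar_number(b) || b <= 0) stopf("`b` must be > 0")
  if (!is_scalar_number(reps) || reps < 1) stopf("`reps` must be >= 1")
  if (any(M_range < 1)) stopf("`M_range` must be positive")
  structure(list(a = a, b = b, reps = as.integer(reps),
                 M_range = as.integer(M_range), k_max = as.integer(k_max),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: W(a = %g, b = %g), %d reps/M, M in %d..%d, k_max %d, seed %d\n",
              x$a, x$b, x$reps, min(x$M_range), max(x$M_range), x$k_max, x$seed))
  invisible(x)
}

# reps x M matrix of descending frequency vectors for genes with M
# isoforms under W(a, 1). Consumes the current RNG stream.
simulate_group_frequencies <- function(M, a, reps) {
  x <- matrix(stats::qweibull(stats::runif(reps * M), shape = a, scale = 1),
              nrow = reps, ncol = M)
  f <- x / rowSums(x)
  sort_rows_desc(f)
}

#' Simulate per-M isoform frequency distributions
#'
#' For each `M` in `config$M_range`, draws `config$reps` genes: `M`
#' expression values from `W(a, 1)`, converted to frequencies and sorted
#' descending. Each `M` uses a sub-seed derived from `(seed, M)`.
#'
#' @param config A [sim_config()].
#' @return Named list mapping `M` (as character) to a `reps x M` matrix
#'   of descending frequency vectors, suitable for
#'   [median_frequency_matrix()].
#' @export
simulate_frequency_groups <- function(config = sim_config()) {
  groups <- lapply(config$M_range, function(M) {
    with_seed(derive_seed(config$seed, M),
              simulate_group_frequencies(M, config$a, config$reps))
  })
  names(groups) <- as.character(config$M_range)
  groups
}

#' Simulated median-frequency matrix
#'
#' [median_frequency_matrix()] applied to [simulate_frequency_groups()]:
#' the Monte-Carlo estimate of `mf(k, M)` under the Weibull model at
#' `config$a`.
#'
#' @inheritParams simulate_frequency_groups
#' @param M_max Number of matrix columns (default `max(config$M_range)`).
#' @return A `frequency_matrix`.
#' @export
simulated_median_matrix <- function(config = sim_config(),
                                    M_max = max(config$M_range)) {
  mat <- empty_frequency_matrix(config$k_max, M_max)
  for (M in config$M_range) {
    if (M > M_max) next
    f <- with_seed(derive_seed(config$seed, M),
                   simulate_group_frequencies(M, config$a, config$reps))
    for (k in seq_len(min(config$k_max, M))) {
      mat[k, M] <- stats::median(f[, k])
    }
  }
  mat
}

#' Grid-search estimation of the Weibull shape parameter
#'
#' For each candidate shape on the grid, simulates a median-frequency
#' matrix and measures its Euclidean distance to the observed matrix;
#' the estimate is the distance-minimizing shape. Each grid point uses a
#' deterministic sub-seed derived from `(config$seed, a)`, so the profile
#' is reproducible. Ties in the minimum break toward the smaller shape.
#'
#' @param observed A `frequency_matrix` of empirical median frequencies.
#' @param grid Candidate shapes in (0, 1), default `seq(0.01, 0.99, 0.01)`.
#' @param config A [sim_config()]; its `a` is ignored (the grid supplies
#'   the shapes).
#' @return An object of class `"shape_fit"`: list with `a_hat`,
#'   `min_distance`, and `profile` (data.frame of `a` and `distance`).
#' @export
estimate_shape <- function(observed, grid = seq(0.01, 0.99, by = 0.01),
                           config = sim_config()) {
  if (length(grid) == 0L) stopf("`grid` must be nonempty")
  if (any(grid <= 0 | grid >= 1)) stopf("`grid` values must lie in (0, 1)")
  grid <- sort(grid)
  cfg <- config
  distances <- vapply(grid, function(a) {
    cfg$a <- a
    cfg$seed <- derive_seed(config$seed, a)
    sim <- simulated_median_matrix(cfg, M_max = ncol(observed))
    matrix_distance(observed, sim)
  }, numeric(1))
  i <- which.min(distances)  # first minimum = smallest a on a sorted grid
  structure(list(a_hat = grid[i], min_distance = distances[i],
                 profile = data.frame(a = grid, distance = distances)),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("shape_fit: a_hat = %g (distance %.4g over %d grid points)\n",
              x$a_hat, x$min_distance, nrow(x$profile)))
  invisible(x)
}

#' Significance threshold for isoform dominance
#'
#' The `(1 - alpha)` quantile of the pooled distribution of all isoform
#' frequencies (every rank) over simulated genes with `M` isoforms. An
#' isoform whose observed frequency exceeds this threshold is
#' "significantly dominant": a randomly selected isoform of an `M`-isoform
#' gene exceeds it with probability less than `alpha` under the model.
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param M Isoform count, `>= 2` (for `M = 1` the frequency is always 1).
#' @param alpha Significance level in (0, 0.5), default 0.05.
#' @param config A [sim_config()]; the default uses 1e5 reps because
#'   tail quantiles need tighter Monte-Carlo error than medians.
#' @return The frequency threshold.
#' @examples
#' \donttest{dominance_threshold(10)}  # about 0.53 at the canonical shape
#' @export
dominance_threshold <- function(M, alpha = 0.05, config = sim_config(reps = 1e5)) {
  if (!is_scalar_number(M) || M < 2)
    stopf("`M` must be >= 2 (a single-isoform gene always has frequency 1)")
  if (alpha <= 0 || alpha >= 0.5) stopf("`alpha` must be in (0, 0.5)")
  x <- with_seed(derive_seed(config$seed, M), {
    v <- matrix(stats::qweibull(stats::runif(config$reps * M),
                                shape = config$a, scale = 1),
                nrow = config$reps, ncol = M)
    as.vector(v / rowSums(v))
  })
  stats::quantile(x, 1 - alpha, names = FALSE, type = 7)
}

#' Table of dominance thresholds over isoform counts
#'
#' @param M_values Isoform counts, each `>= 2`.
#' @inheritParams dominance_threshold
#' @return Data.frame with columns `M`, `alpha`, `threshold`.
#' @export
dominance_threshold_table <- function(M_values = c(2, 5, 10, 20, 30),
                                      alpha = 0.05,
                                      config = sim_config(reps = 1e5)) {
  data.frame(M = M_values, alpha = alpha,
             threshold = vapply(M_values, dominance_threshold,
                                numeric(1), alpha = alpha, config = config))
}

#' Tail probability of a ranked isoform frequency
#'
#' Monte-Carlo estimate of `P(f(k, M) >= t)`: the probability that the
#' `k`-th most dominant isoform of an `M`-isoform gene carries at least a
#' fraction `t` of the gene's expression.
#'
#' @param k Rank, `1 <= k <= M`.
#' @param M Isoform count.
#' @param t Frequency threshold in (0, 1).
#' @param config A [sim_config()] (default 1e5 reps).
#' @return List with `p` (estimate), `se` (binomial standard error) and
#'   `reps`.
#' @export
probability_rank_exceeds <- function(k, M, t, config = sim_config(reps = 1e5)) {
  if (!is_scalar_number(k) || k < 1 || k > M) stopf("`k` must satisfy 1 <= k <= M")
  if (!is_scalar_number(t) || t <= 0 || t >= 1) stopf("`t` must be in (0, 1)")
  f <- with_seed(derive_seed(config$seed, M),
                 simulate_group_frequencies(M, config$a, config$reps))
  p <- mean(f[, k] >= t)
  list(p = p, se = sqrt(p * (1 - p) / config$reps), reps = config$reps)
}

#' Genome-weighted tail percentage
#'
#' Weights the per-M tail probabilities `P(f(k, M) >= t)` by the number
#' of genes in each isoform-count group (for example, counts derived from
#' an Ensembl annotation) and returns the weighted percentage of genes
#' whose rank-`k` isoform reaches frequency `t`.
#'
#' @param weights Named nonnegative vector: names are isoform counts `M`,
#'   values are gene counts.
#' @inheritParams probability_rank_exceeds
#' @return Percentage in `[0, 100]`.
#' @export
genome_weighted_percent <- function(weights, k, t, config = sim_config(reps = 1e5)) {
  if (is.null(names(weights))) stopf("`weights` must be named by isoform count M")
  if (any(weights < 0) || sum(weights) == 0)
    stopf("`weights` must be nonnegative and not all zero")
  Ms <- as.integer(names(weights))
  keep <- weights > 0 & Ms >= k
  ps <- vapply(Ms[keep], function(M) {
    probability_rank_exceeds(k, M, t, config)$p
  }, numeric(1))
  100 * sum(weights[keep] * ps) / sum(weights)
}

#' Expected number of expressed isoforms under the model
#'
#' Median over simulated `M`-isoform genes of the number of isoforms with
#' frequency at least `cutoff`. With the default cutoff 0.001 this is the
#' model's prediction for how many of a gene's annotated isoforms are
#' detectable, which grows with `M`.
#'
#' @param M Isoform count(s); vectorized.
#' @param cutoff Frequency cutoff in (0, 1), default 0.001.
#' @param config A [sim_config()].
#' @return Named numeric vector of medians, one per `M`.
#' @export
expected_expressed_isoforms <- function(M, cutoff = 0.001, config = sim_config()) {
  if (cutoff <= 0 || cutoff >= 1) stopf("`cutoff` must be in (0, 1)")
  out <- vapply(M, function(Mi) {
    f <- with_seed(derive_seed(config$seed, Mi),
                   simulate_group_frequencies(Mi, config$a, config$reps))
    stats::median(rowSums(f >= cutoff))
  }, numeric(1))
  stats::setNames(out, as.character(M))
}
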