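#' Generalized harmonic number of the median-frequency formula
#'
#' Computes \eqn{H_M = \sum_{m=1}^{M} \frac{1}{m} e^{-(1 + m/M)^2}}, the
#' normalizing constant of the closed-form approximation for median
#' isoform frequencies.
#'
#' @param M Isoform count, integer `>= 1` (vectorized).
#' @return `H_M`, same length as `M`.
#' @examples
#' harmonic_number(1)  # exp(-4)
#' @export
harmonic_number <- function(M) {
  if (length(M) == 0L || any(!is.finite(M)) || any(M < 1))
    stopf("`M` must be >= 1")
  vapply(M, function(Mi) {
    m <- seq_len(Mi)
    sum(exp(-(1 + m / Mi)^2) / m)
  }, numeric(1))
}

#' Frequency index of the k-th dominant isoform
#'
#' The unnormalized weight \eqn{(1/k) e^{-(1 + k/M)^2}} assigned to rank
#' `k` in a gene with `M` isoforms. Normalizing the indices over
#' `k = 1..M` yields [median_frequency_formula()].
#'
#' @param k Isoform rank(s), `1 <= k <= M`.
#' @param M Isoform count.
#' @return The index, vectorized over `k`.
#' @export
frequency_index <- function(k, M) {
  if (!is_scalar_number(M) || M < 1) stopf("`M` must be >= 1")
  if (any(k < 1) || any(k > M)) stopf("`k` must satisfy 1 <= k <= M")
  exp(-(1 + k / M)^2) / k
}

#' Closed-form approximation of the median isoform frequency
#'
#' The approximation
#' \deqn{mf(k, M) = \frac{e^{-(1 + k/M)^2}}{k \, H_M}}
#' for the median frequency of the `k`-th most dominant isoform of a gene
#' with `M` annotated isoforms. The values sum to 1 over `k = 1..M` by
#' construction. The formula closely tracks the Monte-Carlo medians of
#' the Weibull model at the canonical shape, but it is an empirical
#' approximation: no derivation from the Weibull model exists (sums of
#' Weibull variables have no closed-form distribution).
#'
#' @inheritParams frequency_index
#' @return Median frequency estimate(s), vectorized over `k`.
#' @examples
#' median_frequency_formula(1, 10)  # about 0.53
#' @export
median_frequency_formula <- function(k, M) {
  frequency_index(k, M) / harmonic_number(M)
}

#' Median-frequency matrix from the closed-form approximation
#'
#' Fills the standard rank-by-isoform-count matrix (rows `k = 1..k_max`,
#' columns `M = 1..M_max`, cells with `k > M` masked as `NA`) with
#' [median_frequency_formula()] values.
#'
#' @param k_max Maximum rank (default 9).
#' @param M_max Maximum isoform count (default 30).
#' @return A `frequency_matrix`: numeric matrix with dimnames `k` and `M`.
#' @export
formula_matrix <- function(k_max = 9, M_max = 30) {
  if (k_max > M_max) stopf("`k_max` must be <= `M_max`")
  mat <- empty_frequency_matrix(k_max, M_max)
  for (M in seq_len(M_max)) {
    ks <- seq_len(min(k_max, M))
    mat[ks, M] <- median_frequency_formula(ks, M)
  }
  mat
}
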