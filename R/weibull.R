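#' Weibull parameter pair for the splicing model
#'
#' Bundles the shape parameter `a` and scale parameter `b` of the type III
#' (Weibull) extreme-value distribution used to model transcript isoform
#' expression levels. In this model the shape is a property of the splicing
#' mechanism itself and is shared by all genes, while the scale tracks the
#' expression level of each gene.
#'
#' The density is the scale-in-denominator form
#' \deqn{W(x; a, b) = \frac{a}{b}\left(\frac{x}{b}\right)^{a-1}
#'       e^{-(x/b)^a},}
#' identical to [stats::dweibull()] with `shape = a`, `scale = b`. This
#' parameterization is fixed throughout the package to avoid the usual
#' rate-versus-scale ambiguity.
#'
#' @param a Shape parameter, dimensionless, `> 0`.
#' @param b Scale parameter, in expression units (FPKM/TPM), `> 0`.
#' @return An object of class `"weibull_params"`: a list with elements
#'   `a` and `b`.
#' @examples
#' p <- weibull_params(0.39, 1)
#' weibull_mean(p)  # b * Gamma(1 + 1/a)
#' @export
weibull_params <- function(a, b = 1) {
  if (!is_scalar_number(a) || a <= 0) stopf("shape `a` must be a single number > 0")
  if (!is_scalar_number(b) || b <= 0) stopf("scale `b` must be a single number > 0")
  structure(list(a = a, b = b), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull parameters: shape a = %g, scale b = %g (mean %.4g)\n",
              x$a, x$b, weibull_mean(x)))
  invisible(x)
}

as_weibull_params <- function(params) {
  if (inherits(params, "weibull_params")) return(params)
  if (is.numeric(params) && length(params) %in% 1:2) {
    return(weibull_params(params[[1]], if (length(params) == 2L) params[[2]] else 1))
  }
  stopf("`params` must be a weibull_params object or a numeric (a, b)")
}

#' Weibull density of isoform expression
#'
#' Evaluates the model density at nonnegative expression values.
#'
#' @param x Numeric vector of expression values, all `>= 0`.
#' @param params A [weibull_params()] object (or numeric `c(a, b)`).
#' @return Densities, same length as `x`.
#' @examples
#' weibull_pdf(2, weibull_params(1, 1))  # exp(-2), the exponential case
#' @export
weibull_pdf <- function(x, params) {
  params <- as_weibull_params(params)
  if (any(!is.finite(x)) || any(x < 0)) stopf("`x` must be finite and >= 0")
  stats::dweibull(x, shape = params$a, scale = params$b)
}

#' Sample isoform expression values from the Weibull model
#'
#' Draws by the inverse-CDF transform `x = b * (-log(1 - u))^(1/a)` with
#' `u` uniform on (0, 1); reproducible for a fixed `seed`, which is applied
#' locally and never disturbs the caller's RNG state.
#'
#' @param n Number of draws, `>= 1`.
#' @param params A [weibull_params()] object (or numeric `c(a, b)`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of `n` nonnegative values.
#' @export
weibull_sample <- function(n, params, seed = NULL) {
  params <- as_weibull_params(params)
  if (!is_scalar_number(n) || n < 1) stopf("`n` must be >= 1")
  with_seed(seed, stats::qweibull(stats::runif(n), shape = params$a, scale = params$b))
}

#' Population mean of the Weibull model
#'
#' The mean identity `mu = b * Gamma(1 + 1/a)` links the two parameters to
#' the average isoform expression level.
#'
#' @inheritParams weibull_pdf
#' @return The population mean.
#' @export
weibull_mean <- function(params) {
  params <- as_weibull_params(params)
  params$b * gamma(1 + 1 / params$a)
}

#' Approximate gene expression from isoform count and Weibull parameters
#'
#' For a gene with `M` isoforms whose expression levels are Weibull draws,
#' the total gene expression is approximately `E = b * M * Gamma(1 + 1/a)`
#' (the sample mean of the `M` isoform levels approaches the population
#' mean as `M` grows). [scale_from_gene()] inverts the relation for `b`.
#'
#' @inheritParams weibull_pdf
#' @param M Annotated isoform count, `>= 1`.
#' @return Expected gene expression `E`.
#' @export
gene_expression <- function(params, M) {
  params <- as_weibull_params(params)
  if (!is_scalar_number(M) || M < 1) stopf("`M` must be >= 1")
  params$b * M * gamma(1 + 1 / params$a)
}

#' @rdname gene_expression
#' @param E Observed gene expression (sum over isoforms), `> 0`.
#' @param a Shape parameter.
#' @return `scale_from_gene()`: the implied scale `b = E / (M * Gamma(1 + 1/a))`.
#' @export
scale_from_gene <- function(E, M, a) {
  if (!is_scalar_number(E) || E <= 0) stopf("`E` must be > 0")
  if (!is_scalar_number(M) || M < 1) stopf("`M` must be >= 1")
  E / (M * gamma(1 + 1 / a))
}

#' Canonical shape parameter of the splicing model
#'
#' Solves the fixed-point equation `1 + 1/a = Gamma(1 + 1/a)` on (0, 1) by
#' bisection. Its root, approximately 0.39, is the shape at which the
#' Euclidean-distance grid search against observed median isoform
#' frequencies also bottoms out, making it the model's canonical shape.
#'
#' @param tolerance Bracket width at which bisection stops (default 1e-10).
#' @param interval Search bracket, default `c(0.05, 0.95)`; the objective
#'   `Gamma(1 + 1/a) - (1 + 1/a)` changes sign exactly once on it.
#' @return The root `a*`.
#' @examples
#' round(canonical_shape(), 2)  # 0.39
#' @export
canonical_shape <- function(tolerance = 1e-10, interval = c(0.05, 0.95)) {
  if (!is_scalar_number(tolerance) || tolerance <= 0) stopf("`tolerance` must be > 0")
  f <- function(a) gamma(1 + 1 / a) - (1 + 1 / a)
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) stopf("objective does not change sign on the bracket")
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    # stop on both bracket width and residual so the returned root
    # satisfies the fixed point to `tolerance`
    if (fm == 0 || (hi - lo <= tolerance && abs(fm) <= tolerance) ||
        mid == lo || mid == hi) {
      return(mid)
    }
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
}

#' Scale isoform expression vectors
#'
#' Rescales one gene's isoform expression vector for pooling across genes
#' and conditions. The `"naive"` method divides by the sample mean; because
#' the Weibull mean is `b * Gamma(1 + 1/a)`, not `b`, the correct scale
#' estimate is the sample mean divided by `Gamma(1 + 1/a)`, which the
#' `"gamma-corrected"` method uses. Naive-scaled values are bounded above
#' by the vector length `n`, a diagnostic of the scaling bias for small
#' isoform counts.
#'
#' @param x Nonnegative expression vector with positive mean.
#' @param a Shape parameter (used by the gamma-corrected method).
#' @param method `"gamma-corrected"` or `"naive"`.
#' @return Scaled vector, same length as `x`.
#' @export
scale_expressions <- function(x, a = canonical_shape(),
                              method = c("gamma-corrected", "naive")) {
  method <- match.arg(method)
  if (length(x) == 0L) stopf("`x` must be nonempty")
  if (any(x < 0)) stopf("`x` must be >= 0")
  m <- mean(x)
  if (m <= 0) stopf("all-zero vector: scale undefined")
  scale <- if (method == "naive") m else m / gamma(1 + 1 / a)
  x / scale
}

#' Weibull plot coordinates
#'
#' For positive data, plots `log(x)` against `log(-log(1 - F))` using
#' median-rank plotting positions `F_i = (i - 0.3) / (n + 0.4)` on the
#' sorted values. For true Weibull data the points fall on a line whose
#' slope is the shape parameter, which [weibull_plot_fit()] estimates by
#' least squares.
#'
#' @param values Positive numeric vector, `length >= 2`.
#' @return A data.frame with columns `log_x` and `log_neglog_sf`.
#' @export
weibull_plot_coords <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  if (any(values <= 0)) stopf("values must be > 0")
  v <- sort(values)
  n <- length(v)
  F_hat <- (seq_len(n) - 0.3) / (n + 0.4)
  data.frame(log_x = log(v), log_neglog_sf = log(-log(1 - F_hat)))
}

#' @rdname weibull_plot_coords
#' @return `weibull_plot_fit()`: a list with the fitted `slope` (shape
#'   estimate), `intercept`, and the coordinate data.frame.
#' @export
weibull_plot_fit <- function(values) {
  coords <- weibull_plot_coords(values)
  if (diff(range(coords$log_x)) == 0)
    stopf("degenerate Weibull plot: all values identical")
  fit <- stats::lm(log_neglog_sf ~ log_x, data = coords)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       coords = coords)
}

#' Curve-fit estimation of the Weibull shape from scaled expression values
#'
#' Histograms the pooled (scaled) isoform expression values and fits the
#' Weibull density to the bin-midpoint density estimates by least squares.
#' This mirrors the simple curve-fitting route to the shape parameter; it
#' is known to be biased when applied to naive-scaled values from genes
#' with few isoforms, because the per-gene scale estimate is itself noisy
#' and bounded (see [scale_expressions()]). Grid-search estimation on the
#' median-frequency matrix ([estimate_shape()]) is the preferred route.
#'
#' @param scaled_values Pooled nonnegative values (conventionally from
#'   genes with at least `min_M` isoforms).
#' @param n_bins Number of equal-width histogram bins on
#'   `[0, 99th percentile]`, `>= 10` (default 50).
#' @param min_M Documentation-carrying minimum isoform count used to select
#'   the genes pooled into `scaled_values` (default 5); not enforced here.
#' @return A list with `a_hat`, `b_hat`, the histogram `breaks`, observed
#'   bin `density`, and fitted density `fitted`.
#' @export
fit_shape_curvefit <- function(scaled_values, n_bins = 50, min_M = 5) {
  if (n_bins < 10) stopf("`n_bins` must be >= 10")
  if (length(scaled_values) < 10 * n_bins)
    stopf("insufficient data: need at least %d values, got %d",
          10 * n_bins, length(scaled_values))
  if (any(scaled_values < 0)) stopf("values must be >= 0")
  upper <- stats::quantile(scaled_values, 0.99, names = FALSE)
  if (upper <= 0) stopf("degenerate values: 99th percentile is 0")
  x <- scaled_values[scaled_values <= upper]
  breaks <- seq(0, upper, length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  width <- diff(breaks)
  prop <- h$counts / sum(h$counts)
  # Compare bin probability masses, not midpoint densities: with a < 1
  # the density diverges at 0 and a midpoint evaluation cannot represent
  # the first bin.
  obj <- function(par) {
    mass <- diff(stats::pweibull(breaks, shape = par[1], scale = par[2]))
    sum((mass - prop)^2)
  }
  fit <- stats::optim(c(0.5, 1), obj, method = "L-BFGS-B",
                      lower = c(1e-3, 1e-3), upper = c(10, 100))
  list(a_hat = fit$par[1], b_hat = fit$par[2], breaks = breaks,
       density = prop / width,
       fitted = diff(stats::pweibull(breaks, fit$par[1], fit$par[2])) / width)
}
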