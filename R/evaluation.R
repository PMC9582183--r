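#' Kullback-Leibler divergence between densities on a grid
#'
#' Trapezoid quadrature of `integral p ln(p/g)` with the convention
#' `0 ln 0 = 0`. Errors if `p` carries mass where `g` vanishes (absolute
#' continuity violated).
#'
#' @param p,g Density values on `grid` (non-negative).
#' @param grid Strictly increasing evaluation points.
#' @return KL divergence in nats.
#' @examples
#' x <- seq(0.01, 10, length.out = 500)
#' kl_divergence(dgamma(x, 2), dgamma(x, 2), x)  # 0
#' @export
kl_divergence <- function(p, g, grid) {
  if (length(p) != length(grid) || length(g) != length(grid)) {
    abort("`p`, `g` and `grid` must have the same length",
          class = "metaif_domain_error")
  }
  if (any(p < 0) || any(g < 0)) {
    abort("densities must be non-negative", class = "metaif_domain_error")
  }
  if (any(p > 0 & g == 0)) {
    abort("p has mass where the reference vanishes (support violation)",
          class = "metaif_support_violation")
  }
  integrand <- ifelse(p > 0, p * log(p / g), 0)
  pracma::trapz(grid, integrand)
}

#' Goodness-of-fit metrics
#'
#' `rmse()` is the root mean squared difference; `chi_square()` the
#' residual sum of squares over `l - n_params` degrees of freedom (so
#' `chi_square = rmse^2 * l / (l - n_params)`); `r_squared()` the usual
#' `1 - SS_res / SS_tot` (can be negative for predictors worse than the
#' mean).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A scalar.
#' @export
rmse <- function(observed, predicted) {
  check_paired(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname rmse
#' @param n_params Number of fitted parameters (must be < length).
#' @export
chi_square <- function(observed, predicted, n_params) {
  check_paired(observed, predicted)
  l <- length(observed)
  if (l <= n_params) {
    abort("need more observations than parameters",
          class = "metaif_dof_error")
  }
  sum((observed - predicted)^2) / (l - n_params)
}

#' @rdname rmse
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("R^2 is undefined for a constant observed vector",
          class = "metaif_domain_error")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

check_paired <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    abort("`observed` and `predicted` must be equal-length, non-empty",
          class = "metaif_domain_error")
  }
  invisible(TRUE)
}

#' Kernel-density reference on a grid
#'
#' Gaussian kernel density estimate with Silverman's bandwidth, evaluated
#' on a regular grid and renormalized after clipping to x > 0. The default
#' grid spans the sample range padded by three bandwidths; explicit
#' `from`/`to` override it.
#'
#' @param samples Observations (n >= 2, nonzero variance).
#' @param grid_size Number of grid points (default 512).
#' @param from,to Optional grid limits.
#' @return A [grid_density()] with an extra column `density` (mass divided
#'   by the grid spacing).
#' @export
kde_reference <- function(samples, grid_size = 512, from = NULL, to = NULL) {
  if (length(samples) < 2 || sd(samples) == 0) {
    abort("kernel reference needs >= 2 distinct observations",
          class = "metaif_degenerate_data")
  }
  bw <- stats::bw.nrd0(samples)
  lo <- from %||% (min(samples) - 3 * bw)
  hi <- to %||% (max(samples) + 3 * bw)
  lo <- max(lo, 1e-12)  # concentrations live on x > 0
  d <- density(samples, bw = bw, from = lo, to = hi, n = grid_size)
  dx <- d$x[2] - d$x[1]
  dens <- pmax(d$y, 1e-300)  # floor keeps KL against this reference defined
  mass <- dens * dx
  out <- grid_density(d$x, mass)
  out$density <- out$mass / dx
  attr(out, "bw") <- bw
  out
}

#' Empirical cumulative distribution function
#'
#' Thin wrapper over [stats::ecdf()]: a right-continuous step function,
#' 0 below the minimum and 1 at and above the maximum.
#'
#' @param samples Numeric observations (n >= 1).
#' @return A function of class `ecdf`.
#' @export
aif_ecdf <- function(samples) {
  if (length(samples) < 1 || anyNA(samples)) {
    abort("need at least one observation", class = "metaif_domain_error")
  }
  stats::ecdf(samples)
}

#' Evaluate a fitted AIF density against the empirical reference
#'
#' Builds the kernel-density reference of the samples and reports, in one
#' row: the KL divergence of the fitted density from the reference, the
#' differential entropy of the fitted density, and RMSE / chi-square / R^2
#' comparing the fitted pdf to the kernel pdf on the kernel grid (two
#' fitted parameters for the chi-square denominator).
#'
#' @param samples Positive observations.
#' @param fit An [aif_family()], `maxent_fit`, or `met_reg_fit`.
#' @param grid_size Reference grid resolution.
#' @return A one-row tibble of class `aif_evaluation` with columns
#'   `kl_divergence`, `entropy`, `rmse`, `chi_square`, `r_squared`.
#' @examples
#' x <- rgamma(300, 2, scale = 0.5)
#' evaluate_aif_fit(x, fit_weibull_mle(x))
#' @export
evaluate_aif_fit <- function(samples, fit, grid_size = 512) {
  if (inherits(fit, "met_reg_fit")) fit <- fit$family
  ref <- kde_reference(samples, grid_size = grid_size)
  fitted_pdf <- density_eval(fit, ref$x)
  kl <- kl_divergence(fitted_pdf, ref$density, ref$x)
  out <- tibble(
    kl_divergence = kl,
    entropy = differential_entropy(fit),
    rmse = rmse(ref$density, fitted_pdf),
    chi_square = chi_square(ref$density, fitted_pdf, n_params = 2),
    r_squared = r_squared(ref$density, fitted_pdf)
  )
  class(out) <- c("aif_evaluation", class(out))
  out
}

#' Plot a fitted AIF density over the empirical reference
#'
#' @param samples Positive observations.
#' @param fit A fitted density (see [evaluate_aif_fit()]).
#' @return A ggplot.
#' @export
plot_aif_fit <- function(samples, fit) {
  if (inherits(fit, "met_reg_fit")) fit <- fit$family
  ref <- kde_reference(samples)
  df <- tidyr::pivot_longer(
    tibble(x = ref$x, empirical = ref$density,
           fitted = density_eval(fit, ref$x)),
    -"x", names_to = "which", values_to = "density"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "concentration (mmol/L)", y = "density",
                  linetype = NULL)
}
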