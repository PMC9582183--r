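#' Least-squares estimation of the exchange rate constants
#'
#' Solves the Murase linear system `C_T = A K` in the least-squares sense
#' through a QR factorization of the design matrix. The low-level
#' `estimate_*()` functions are unit-agnostic (K comes out in the inverse
#' of the time unit of `A`); the [fit_pk()] surface works on curves and
#' reports `ka`, `kb` in 1/min.
#'
#' @param A Design matrix from [build_design_matrix()].
#' @param y Measured tissue concentrations (length `nrow(A)`).
#' @return A list with `k` (the estimate), `cov` (covariance
#'   `(A'A)^-1 sigma2_hat`), `rss`, `sigma2`.
#' @export
estimate_ls <- function(A, y) {
  if (nrow(A) != length(y)) {
    abort("`y` must match the design matrix rows", class = "metaif_domain_error")
  }
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    abort("design matrix is rank deficient; use estimate_ridge()",
          class = "metaif_rank_error")
  }
  k <- qr.coef(qrA, y)
  resid <- y - as.numeric(A %*% k)
  rss <- sum(resid^2)
  n <- length(y)
  sigma2 <- if (n > ncol(A)) rss / (n - ncol(A)) else NA_real_
  xtx_inv <- chol2inv(chol(crossprod(A)))
  if (any(k < 0)) {
    warn("least-squares estimate has a negative rate constant")
  }
  list(k = unname(k), cov = xtx_inv * sigma2, rss = rss, sigma2 = sigma2)
}

#' Ridge (Tikhonov) estimation of the rate constants
#'
#' `K = (A'A + w I)^-1 A' y`; reduces to [estimate_ls()] at `w = 0` and
#' shrinks toward zero as `w` grows.
#'
#' @inheritParams estimate_ls
#' @param ridge_weight Non-negative ridge weight.
#' @return A list with `k` and `rss`.
#' @export
estimate_ridge <- function(A, y, ridge_weight) {
  if (ridge_weight < 0) {
    abort("`ridge_weight` must be non-negative", class = "metaif_domain_error")
  }
  xtx <- crossprod(A) + diag(ridge_weight, ncol(A))
  k <- as.numeric(solve(xtx, crossprod(A, y)))
  list(k = k, rss = sum((y - as.numeric(A %*% k))^2))
}

#' Maximum-a-posteriori estimation of the rate constants
#'
#' Maximizes `ln p(K | Y) = -||Y - A K||^2 / sigma2 + ln p(K)` over
#' `K >= 0` (rates are physiological, so non-negativity is enforced) by
#' bounded quasi-Newton from several starts. Priors:
#'
#' * `pk_prior("flat")` — constant on the non-negative orthant, so the MAP
#'   is the non-negative least-squares solution;
#' * `pk_prior("exponential", rate = r)` — independent exponential priors;
#' * `pk_prior("maxent", density = f)` — an arbitrary density (for example
#'   a fitted [aif_family()] or `maxent_fit`), applied independently per
#'   component.
#'
#' @inheritParams estimate_ls
#' @param prior A [pk_prior()].
#' @param sigma2 Noise variance; defaults to [estimate_sigma2()] of a
#'   preliminary least-squares fit.
#' @return A list with `k`, `log_posterior`, `sigma2`.
#' @export
estimate_map <- function(A, y, prior = pk_prior("flat"), sigma2 = NULL) {
  if (is.null(sigma2)) {
    ls <- estimate_ls(A, y)
    sigma2 <- estimate_sigma2(A, y, ls$k)
  }
  if (sigma2 <= 0) {
    abort("`sigma2` must be positive", class = "metaif_domain_error")
  }
  log_prior <- prior_logdensity(prior)
  neg_logpost <- function(k) {
    lp <- log_prior(k)
    if (!is.finite(lp)) return(1e12)
    sum((y - as.numeric(A %*% k))^2) / sigma2 - lp
  }
  ls_start <- tryCatch(pmax(estimate_ls(A, y)$k, 1e-8),
                       error = function(e) NULL)
  starts <- list(ls_start, c(0.01, 0.01), c(0.005, 0.02))
  starts <- purrr::compact(starts)
  best <- NULL
  for (s in starts) {
    ctl <- list(maxit = 500, factr = 1, pgtol = 0, ndeps = rep(1e-7, 2))
    res <- optim(s, neg_logpost, method = "L-BFGS-B",
                 lower = c(0, 0), upper = c(Inf, Inf), control = ctl)
    # restart at the optimum: L-BFGS-B sharpens noticeably on new memory
    res <- optim(res$par, neg_logpost, method = "L-BFGS-B",
                 lower = c(0, 0), upper = c(Inf, Inf), control = ctl)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value) || best$value >= 1e12) {
    abort("prior is not finite anywhere on K >= 0",
          class = "metaif_prior_error")
  }
  list(k = best$par, log_posterior = -best$value, sigma2 = sigma2)
}

#' Prior specifications for MAP estimation
#'
#' @param kind `"flat"`, `"exponential"`, or `"maxent"`.
#' @param rate Rate(s) of the exponential prior (recycled per component).
#' @param density For `"maxent"`: a fitted density (an [aif_family()], a
#'   `maxent_fit`, or a function) evaluated independently at each
#'   component, or a list of two such densities.
#' @return A list of class `pk_prior`.
#' @export
pk_prior <- function(kind = c("flat", "exponential", "maxent"),
                     rate = 1, density = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential" && any(rate <= 0)) {
    abort("exponential prior needs positive rate(s)",
          class = "metaif_domain_error")
  }
  if (kind == "maxent" && is.null(density)) {
    abort("maxent prior needs a fitted `density`",
          class = "metaif_domain_error")
  }
  structure(list(kind = kind, rate = rate, density = density),
            class = "pk_prior")
}

prior_logdensity <- function(prior) {
  switch(prior$kind,
    flat = function(k) 0,
    exponential = {
      rate <- rep_len(prior$rate, 2)
      function(k) sum(-rate * k)
    },
    maxent = {
      dens <- prior$density
      if (!is.list(dens) || inherits(dens, c("aif_family", "maxent_fit"))) {
        dens <- list(dens, dens)
      }
      evals <- purrr::map(dens, function(d) {
        if (is.function(d)) d else function(x) density_eval(d, x)
      })
      function(k) {
        v <- c(evals[[1]](k[1]), evals[[2]](k[2]))
        if (any(v <= 0)) return(-Inf)
        sum(log(v))
      }
    }
  )
}

#' Residual-variance estimate
#'
#' `sigma2_hat = ||y - A K||^2 / (n - 2)` for the two-parameter system.
#'
#' @inheritParams estimate_ls
#' @param k The fitted rate constants.
#' @return Scalar variance estimate.
#' @export
estimate_sigma2 <- function(A, y, k) {
  n <- length(y)
  if (n <= 2) {
    abort("need more than 2 observations to estimate the noise variance",
          class = "metaif_insufficient_data")
  }
  sum((y - as.numeric(A %*% k))^2) / (n - 2)
}

#' Fit the two-compartment rate constants from curves
#'
#' The tidy surface over [estimate_ls()], [estimate_ridge()] and
#' [estimate_map()]: builds the Murase design matrix from the AIF and
#' tissue curves (time in seconds) and reports `ka`, `kb` in 1/min.
#'
#' @param aif,tissue `conc_curve`s on the same grid.
#' @param method `"ls"`, `"ridge"` or `"map"`.
#' @param ridge_weight Ridge weight (method `"ridge"`).
#' @param prior,sigma2 Passed to [estimate_map()] (method `"map"`); the
#'   prior is evaluated on the per-minute scale.
#' @return A list of class `pk_fit` with `ka_per_min`, `kb_per_min`,
#'   `method`, `sigma2`, `residual_ss`, `cov` (per-minute scale, LS only).
#' @examples
#' aif <- generate_aif_curve()
#' tis <- simulate_tissue_curve(aif, 0.6, 1.2)
#' fit_pk(aif, tis)
#' @export
fit_pk <- function(aif, tissue, method = c("ls", "ridge", "map"),
                   ridge_weight = 0, prior = pk_prior("flat"),
                   sigma2 = NULL) {
  method <- match.arg(method)
  A <- build_design_matrix(aif, tissue)
  A_min <- A / 60  # integrals in minutes so K comes out in 1/min
  y <- tissue$conc
  res <- switch(method,
    ls = estimate_ls(A_min, y),
    ridge = estimate_ridge(A_min, y, ridge_weight),
    map = estimate_map(A_min, y, prior = prior, sigma2 = sigma2)
  )
  rss <- res$rss %||% sum((y - as.numeric(A_min %*% res$k))^2)
  structure(list(
    ka_per_min = res$k[1],
    kb_per_min = res$k[2],
    method = method,
    sigma2 = res$sigma2 %||% estimate_sigma2(A_min, y, res$k),
    residual_ss = rss,
    cov = res$cov %||% NULL,
    n = length(y)
  ), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("PK fit (%s): ka = %.4f /min, kb = %.4f /min\n",
              x$method, x$ka_per_min, x$kb_per_min))
  cat(sprintf("  residual SS = %.3e, sigma2 = %.3e (n = %d)\n",
              x$residual_ss, x$sigma2, x$n))
  invisible(x)
}

#' @export
tidy.pk_fit <- function(x, ...) {
  se <- if (!is.null(x$cov)) sqrt(diag(x$cov)) else c(NA_real_, NA_real_)
  tibble(
    term = c("ka_per_min", "kb_per_min"),
    estimate = c(x$ka_per_min, x$kb_per_min),
    std.error = se
  )
}

#' @export
glance.pk_fit <- function(x, ...) {
  tibble(method = x$method, sigma2 = x$sigma2,
         residual_ss = x$residual_ss, n = x$n)
}
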