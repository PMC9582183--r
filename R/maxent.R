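#' @keywords internal
#' Panelled Gauss-Legendre quadrature on (lo, hi].
#'
#' Panels are geometrically spaced so that integrable singularities of
#' ln(x)-type bases near 0 and the exponential tail are both resolved.
#' Returns nodes `x` and weights `w`.
me_quadrature <- function(lo, hi, n_panels = 60, n_nodes = 16) {
  stopifnot(hi > lo, lo > 0)
  edges <- exp(seq(log(lo), log(hi), length.out = n_panels + 1))
  xs <- vector("list", n_panels)
  ws <- vector("list", n_panels)
  for (k in seq_len(n_panels)) {
    gl <- pracma::gaussLegendre(n_nodes, edges[k], edges[k + 1])
    xs[[k]] <- gl$x
    ws[[k]] <- gl$w
  }
  list(x = unlist(xs), w = unlist(ws))
}

default_support <- function(constraints) {
  # scale the upper end from whatever location information the targets carry
  m <- NA_real_
  if (any(constraints$tag == "identity")) {
    m <- constraints$mu[constraints$tag == "identity"][1]
  } else if (any(constraints$tag == "power")) {
    i <- which(constraints$tag == "power")[1]
    m <- constraints$mu[i]^(1 / constraints$exponent[i])
  } else if (any(constraints$tag == "log")) {
    m <- exp(constraints$mu[constraints$tag == "log"][1])
  }
  if (!is.finite(m) || m <= 0) m <- 1
  c(1e-12, 80 * m)
}

#' Maximum-entropy density via damped Newton iteration
#'
#' Solves for the Lagrange multipliers of the maximum-entropy density
#' `p(x) = exp(-sum_i lambda_i phi_i(x))` on a positive support interval,
#' subject to equality moment constraints `E_p[phi_i] = mu_i`. The
#' normalization multiplier `lambda_0` is always recomputed from the
#' log-partition, so the returned density integrates to one; the remaining
#' multipliers are found by minimizing the convex dual
#' `ln Z(lambda) + sum lambda_i mu_i` with damped Newton steps
#' (Hessian = covariance of the basis under the current density) and
#' backtracking line search.
#'
#' @param constraints A [compute_moments()] result (or a tibble with
#'   columns `tag`, `exponent`, `mu`, constant first with `mu = 1`).
#' @param support Length-2 positive interval; default scales with the
#'   targets (roughly `(1e-12, 80 * mean]`).
#' @param tol Maximum allowed moment residual `|E_p[phi_i] - mu_i|`.
#' @param max_iter Newton iteration cap.
#' @return An object of class `maxent_fit`: a list with `lambda` (named,
#'   including `lambda_0`), `basis`, `support`, `moments`, `residual`,
#'   `iterations`, `converged`, `entropy`.
#' @examples
#' mc <- tibble::tibble(tag = c("const", "identity"),
#'                      exponent = NA_real_, mu = c(1, 2))
#' fit <- solve_lambda_newton(mc)
#' fit$lambda  # lambda_identity = 1/mean = 0.5
#' @export
solve_lambda_newton <- function(constraints, support = NULL, tol = 1e-10,
                                max_iter = 200) {
  basis <- constraints_basis(constraints)
  mu <- constraints$mu
  if (abs(mu[1] - 1) > 1e-12) {
    abort("the constant constraint must have target 1",
          class = "metaif_domain_error")
  }
  if (is.null(support)) support <- default_support(constraints)
  quad <- me_quadrature(max(support[1], 1e-12), support[2])
  phi <- basis_matrix(basis, quad$x)      # nodes x (N+1)
  phi_free <- phi[, -1, drop = FALSE]
  mu_free <- mu[-1]
  nfree <- length(mu_free)

  lam <- numeric(nfree)
  state <- me_dual_state(lam, phi_free, quad$w)
  converged <- nfree == 0  # constant-only: uniform density, nothing to solve
  iter <- 0
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    grad <- mu_free - state$moments
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    H <- state$cov
    step <- tryCatch(solve(H + diag(1e-12, nfree), -grad),
                     error = function(e) -grad)
    # backtracking on the dual objective ln Z + lambda' mu
    f0 <- state$logz + sum(lam * mu_free)
    alpha <- 1
    repeat {
      lam_new <- lam + alpha * step
      st_new <- me_dual_state(lam_new, phi_free, quad$w)
      f_new <- st_new$logz + sum(lam_new * mu_free)
      if (is.finite(f_new) && f_new <= f0 + 1e-4 * alpha * sum(step * -grad)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    lam <- lam + alpha * step
    state <- st_new
  }
  residual <- if (nfree == 0) 0 else max(abs(mu_free - state$moments))
  if (!converged && residual > max(tol, 1e-8)) {
    abort(
      paste0("maximum-entropy solve did not converge (moment residual ",
             formatC(residual, digits = 3, format = "e"),
             " after ", iter, " iterations); the constraint set may be ",
             "infeasible on this support"),
      class = "metaif_infeasible"
    )
  }
  lambda0 <- state$logz
  lambda <- c(lambda0, lam)
  names(lambda) <- paste0("lambda_", basis_labels(basis))
  fit <- structure(list(
    lambda = lambda,
    basis = basis,
    support = support,
    moments = constraints,
    residual = residual,
    iterations = iter,
    converged = TRUE,
    quad = quad
  ), class = "maxent_fit")
  fit$entropy <- differential_entropy(fit)
  fit
}

# log-partition, basis moments and covariance under the current multipliers
me_dual_state <- function(lam_free, phi_free, w) {
  s <- -as.numeric(phi_free %*% lam_free)
  smax <- max(s)
  u <- w * exp(s - smax)
  z <- sum(u)
  p <- u / z
  moments <- as.numeric(crossprod(phi_free, p))
  centered <- sweep(phi_free, 2, moments)
  cov <- crossprod(centered, centered * p)
  list(logz = log(z) + smax, p = p, moments = moments, cov = cov)
}

#' Evaluate a maximum-entropy density
#'
#' Returns `exp(-sum lambda_i phi_i(x))` for x inside the support interval
#' and 0 outside.
#'
#' @param fit A `maxent_fit` (from [solve_lambda_newton()] or
#'   [solve_lambda_tlbo()]) or a parametric [aif_family()].
#' @param x Evaluation points.
#' @return Numeric density values.
#' @export
density_eval <- function(fit, x) {
  if (inherits(fit, "aif_family")) return(family_pdf(fit, x))
  out <- numeric(length(x))
  inside <- x >= fit$support[1] & x <= fit$support[2]
  if (any(inside)) {
    phi <- basis_matrix(fit$basis, x[inside])
    out[inside] <- exp(-as.numeric(phi %*% fit$lambda))
  }
  out
}

#' Differential entropy of a fitted density
#'
#' Computes `-integral p ln p dx` in nats. For maximum-entropy fits this
#' equals `sum_i lambda_i E_p[phi_i]`, evaluated by quadrature; for
#' parametric families the closed form is used.
#'
#' @param fit A `maxent_fit` or [aif_family()].
#' @return Entropy in nats.
#' @export
differential_entropy <- function(fit) {
  if (inherits(fit, "aif_family")) return(family_entropy(fit))
  quad <- fit$quad %||% me_quadrature(max(fit$support[1], 1e-12), fit$support[2])
  p <- density_eval(fit, quad$x)
  mass <- sum(quad$w * p)
  if (abs(mass - 1) > 1e-6) {
    abort(paste0("density is not normalized (integral = ",
                 formatC(mass, digits = 8, format = "f"), ")"),
          class = "metaif_normalization_error")
  }
  plogp <- ifelse(p > 0, p * log(p), 0)
  -sum(quad$w * plogp)
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat("Maximum-entropy density fit\n")
  cat("  basis:   ", paste(basis_labels(x$basis), collapse = ", "), "\n")
  cat("  lambda:  ", paste(formatC(x$lambda, digits = 6), collapse = ", "), "\n")
  cat("  support: (", formatC(x$support[1], digits = 3, format = "e"), ", ",
      formatC(x$support[2], digits = 4), "]\n", sep = "")
  cat("  moment residual:", formatC(x$residual, digits = 3, format = "e"),
      " after", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
tidy.maxent_fit <- function(x, ...) {
  tibble(
    term = basis_labels(x$basis),
    lambda = unname(x$lambda),
    mu = x$moments$mu
  )
}

#' @export
glance.maxent_fit <- function(x, ...) {
  tibble(
    entropy = x$entropy,
    residual = x$residual,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
autoplot.maxent_fit <- function(object, n = 400, ...) {
  hi <- object$support[2]
  # trim the plotting window to where the density carries mass
  quad <- object$quad %||% me_quadrature(max(object$support[1], 1e-12), hi)
  p <- density_eval(object, quad$x)
  cum <- cumsum(quad$w * p)
  hi_plot <- quad$x[which(cum > 0.999)[1] %||% length(quad$x)]
  xs <- seq(max(object$support[1], hi_plot / n), hi_plot, length.out = n)
  df <- tibble(x = xs, density = density_eval(object, xs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "concentration (mmol/L)", y = "density")
}
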