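#' Grid densities
#'
#' A discrete probability vector on a strictly increasing support grid,
#' used as the reference measure and the solution space of the
#' soft-constrained (regularized) maximum-entropy solver. `mass` sums to 1.
#'
#' @param x Grid points (strictly increasing).
#' @param mass Non-negative masses; normalized to sum to one.
#' @return A tibble of class `grid_density` with columns `x`, `mass`.
#' @export
grid_density <- function(x, mass) {
  if (length(x) != length(mass) || any(diff(x) <= 0)) {
    abort("grid must be strictly increasing and match `mass`",
          class = "metaif_domain_error")
  }
  if (any(mass < 0) || sum(mass) <= 0) {
    abort("masses must be non-negative with positive total",
          class = "metaif_domain_error")
  }
  out <- tibble(x = as.double(x), mass = mass / sum(mass))
  class(out) <- c("grid_density", class(out))
  out
}

#' Soft-constrained maximum-entropy problem
#'
#' Bundles the ingredients of the regularized formulation
#' `J(p) = || mu - E_p[phi] ||^2 + reg_weight * KL(p, g)` over probability
#' vectors p on the grid of the reference density g. The first constraint
#' row is the constant with target 1 (automatically satisfied on the
#' simplex but kept for fidelity to the moment-system layout).
#'
#' @param constraints A [compute_moments()] result.
#' @param reference A [grid_density()] with strictly positive mass
#'   everywhere (the KL term is undefined otherwise).
#' @param reg_weight Positive regularization weight (default 0.1).
#' @return A list of class `met_reg_problem` with elements `phi`
#'   (constraint matrix, grid-points x constraints), `mu`, `reference`,
#'   `reg_weight`.
#' @export
met_reg_problem <- function(constraints, reference, reg_weight = 0.1) {
  if (!is.numeric(reg_weight) || reg_weight <= 0) {
    abort("`reg_weight` must be positive", class = "metaif_domain_error")
  }
  if (any(reference$mass <= 0)) {
    abort("reference density must be strictly positive on its grid",
          class = "metaif_reference_support")
  }
  basis <- constraints_basis(constraints)
  phi <- basis_matrix(basis, reference$x)
  structure(list(
    phi = phi, mu = constraints$mu, basis = basis,
    reference = reference, reg_weight = reg_weight
  ), class = "met_reg_problem")
}

met_reg_objective <- function(problem, p) {
  g <- problem$reference$mass
  resid <- problem$mu - as.numeric(crossprod(problem$phi, p))
  kl <- sum(ifelse(p > 0, p * log(p / g), 0))
  sum(resid^2) + problem$reg_weight * kl
}

#' Primal solver for the regularized maximum-entropy problem
#'
#' Minimizes `J(p)` directly over the probability simplex via a softmax
#' parameterization and BFGS, independent of the dual route. The objective
#' is convex in p, and the KL term keeps the optimum in the interior, so
#' the stationary point found is the global minimizer; convergence is
#' verified by the KKT residual (the centered gradient on the simplex).
#'
#' @param problem A [met_reg_problem()].
#' @param tol KKT residual target (default 1e-9).
#' @param max_iter BFGS iteration cap.
#' @return A `grid_density` with attributes `objective` and `kkt_residual`.
#' @export
solve_primal <- function(problem, tol = 1e-9, max_iter = 2000) {
  g <- problem$reference$mass
  phi <- problem$phi
  mu <- problem$mu
  w <- problem$reg_weight
  m <- length(g)
  grad_p <- function(p) {
    resid <- mu - as.numeric(crossprod(phi, p))
    -2 * as.numeric(phi %*% resid) + w * (log(p / g) + 1)
  }
  fn <- function(u) {
    p <- softmax(u)
    met_reg_objective(problem, p)
  }
  gr <- function(u) {
    p <- softmax(u)
    gp <- grad_p(p)
    p * (gp - sum(p * gp))
  }
  res <- optim(log(g), fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-15))
  # a second start from the flat point guards against a poor BFGS path
  res2 <- optim(rep(0, m), fn, gr, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-15))
  if (res2$value < res$value) res <- res2
  p <- softmax(res$par)
  kkt_of <- function(p) {
    gp <- grad_p(p)
    max(abs(gp - sum(p * gp))[p > 1e-13])
  }
  # mirror-descent (exponentiated-gradient) refinement with backtracking:
  # monotone on the convex objective, so it can only tighten the KKT point
  obj <- met_reg_objective(problem, p)
  eta <- 1 / max(1, w)
  for (it in seq_len(5000)) {
    if (kkt_of(p) < tol) break
    gp <- grad_p(p)
    repeat {
      q <- p * exp(-eta * (gp - max(gp)))
      q <- q / sum(q)
      obj_q <- met_reg_objective(problem, q)
      if (obj_q <= obj + 1e-15) break
      eta <- eta / 2
      if (eta < 1e-14) break
    }
    if (obj_q > obj + 1e-15) break
    if (obj - obj_q < 1e-16 && kkt_of(q) >= kkt_of(p)) { p <- q; break }
    p <- q
    obj <- obj_q
    eta <- eta * 1.5
  }
  kkt <- kkt_of(p)
  out <- grid_density(problem$reference$x, p)
  attr(out, "objective") <- met_reg_objective(problem, p)
  attr(out, "kkt_residual") <- kkt
  out
}

softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

#' Dual solver for the regularized maximum-entropy problem
#'
#' Maximizes the smooth low-dimensional Fenchel dual
#' `D(lambda) = lambda' mu - ||lambda||^2 / 4 -
#'  reg_weight * ln sum_j g_j exp([phi' lambda]_j / reg_weight)`
#' by BFGS with analytic gradient, then reconstructs
#' `p_j = g_j exp(s_j / reg_weight) / Z` with `s = phi lambda`. At the
#' optimum the moment residual equals `lambda / 2`, and the exponent of the
#' reconstruction divided by `-reg_weight` gives the effective
#' maximum-entropy multipliers of the hard-constrained limit.
#'
#' @param problem A [met_reg_problem()].
#' @return A list of class `met_reg_dual` with `p_hat` (a `grid_density`),
#'   `lambda_dual`, `lambda_effective` (named like the basis, excluding the
#'   constant), `log_partition`, `moment_residual`, `primal_objective`,
#'   `gradient_norm`, `converged`.
#' @export
solve_dual <- function(problem) {
  g <- problem$reference$mass
  phi <- problem$phi
  mu <- problem$mu
  w <- problem$reg_weight
  nlam <- length(mu)
  p_of <- function(lam) {
    s <- as.numeric(phi %*% lam) / w
    smax <- max(s)
    u <- g * exp(s - smax)
    list(p = u / sum(u), logz = log(sum(u)) + smax)
  }
  neg_d <- function(lam) {
    s <- as.numeric(phi %*% lam) / w
    smax <- max(s)
    lse <- log(sum(g * exp(s - smax))) + smax
    -(sum(lam * mu) - sum(lam^2) / 4 - w * lse)
  }
  neg_grad <- function(lam) {
    st <- p_of(lam)
    -(mu - lam / 2 - as.numeric(crossprod(phi, st$p)))
  }
  res <- optim(numeric(nlam), neg_d, neg_grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  lam <- res$par
  gnorm <- sqrt(sum(neg_grad(lam)^2))
  if (gnorm > 1e-5) {
    warn(paste0("dual solve finished with gradient norm ",
                formatC(gnorm, digits = 3, format = "e")))
  }
  st <- p_of(lam)
  p_hat <- grid_density(problem$reference$x, st$p)
  lambda_eff <- -lam / w
  names(lambda_eff) <- paste0("lambda_", basis_labels(problem$basis))
  structure(list(
    p_hat = p_hat,
    lambda_dual = lam,
    lambda_effective = lambda_eff,
    log_partition = st$logz,
    moment_residual = sqrt(sum((mu - as.numeric(crossprod(phi, st$p)))^2)),
    primal_objective = met_reg_objective(problem, st$p),
    gradient_norm = gnorm,
    converged = gnorm <= 1e-5
  ), class = "met_reg_dual")
}

#' Log-partition function on a grid measure
#'
#' Computes `ln sum_j g_j exp(s_j)` with max-subtraction, the logarithmic
#' Laplace transform of the reference measure evaluated at the exponent
#' vector `s`. For a product-form reference over independent coordinates it
#' decomposes into a sum of per-coordinate transforms.
#'
#' @param s Exponent vector.
#' @param g A [grid_density()] (or a bare mass vector of matching length).
#' @return The scalar log-partition value.
#' @export
log_partition <- function(s, g) {
  mass <- if (inherits(g, "grid_density")) g$mass else g
  if (length(s) != length(mass)) {
    abort("`s` and the reference must have the same length",
          class = "metaif_domain_error")
  }
  smax <- max(s)
  log(sum(mass * exp(s - smax))) + smax
}

#' Full MET/REG estimation pipeline
#'
#' The four-stage soft-constrained maximum-entropy fit: (1) moment targets
#' as sample means of the basis functions; (2) a kernel-density reference
#' on a grid spanning `[min/2, 2 max]` of the samples; (3) the convex dual
#' solve; (4) projection of the solution onto the requested parametric
#' family by moment matching (`gamma`: `psi(alpha) + ln beta = E[ln X]`,
#' `alpha beta = E[X]`; `erlang`: nearest positive integer shape with the
#' scale refit to preserve the mean; `exponential`: mean match; `weibull`:
#' mean/variance match).
#'
#' @param samples Positive observations.
#' @param basis Constraint basis (default `{1, ln x, x}`).
#' @param reg_weight Regularization weight (default 0.1); smaller values
#'   enforce the moments harder.
#' @param family_target Output family (default `"gamma"`).
#' @param grid_size Reference grid resolution (default 512).
#' @return A list of class `met_reg_fit` with `family` (an
#'   [aif_family()]), `dual` (the [solve_dual()] result), `constraints`,
#'   `reference`, `reg_weight`, `kl_to_reference`.
#' @export
met_reg_pipeline <- function(samples, basis = me_basis(c("log", "identity")),
                             reg_weight = 0.1, family_target = "gamma",
                             grid_size = 512) {
  check_positive_sample(samples)
  constraints <- compute_moments(samples, basis)
  reference <- kde_reference(samples, grid_size = grid_size,
                             from = min(samples) / 2, to = 2 * max(samples))
  problem <- met_reg_problem(constraints, reference, reg_weight = reg_weight)
  dual <- solve_dual(problem)
  p <- dual$p_hat
  m_id <- sum(p$mass * p$x)
  m_log <- sum(p$mass * log(p$x))
  fam <- project_to_family(family_target, m_id, m_log,
                           m2 = sum(p$mass * p$x^2))
  kl <- sum(ifelse(p$mass > 0, p$mass * log(p$mass / reference$mass), 0))
  structure(list(
    family = fam, dual = dual, constraints = constraints,
    reference = reference, reg_weight = reg_weight,
    kl_to_reference = kl
  ), class = "met_reg_fit")
}

project_to_family <- function(family_target, m_id, m_log, m2) {
  rhs <- m_log - log(m_id)
  gamma_shape <- function() {
    if (rhs >= 0) {
      abort("moments admit no gamma density (E[ln X] >= ln E[X])",
            class = "metaif_infeasible")
    }
    f <- function(la) digamma(exp(la)) - la - rhs
    uniroot(f, lower = log(1e-4), upper = log(1e6), tol = 1e-14)$root |> exp()
  }
  switch(family_target,
    exponential = aif_family("exponential", beta = m_id),
    gamma = {
      a <- gamma_shape()
      aif_family("gamma", alpha = a, beta = m_id / a)
    },
    erlang = {
      a <- max(1, round(gamma_shape()))
      aif_family("erlang", alpha = a, beta = m_id / a)
    },
    weibull = {
      cv2 <- m2 / m_id^2 - 1
      if (cv2 <= 0) {
        abort("degenerate moments for a Weibull projection",
              class = "metaif_infeasible")
      }
      f <- function(a) lgamma(1 + 2 / a) - 2 * lgamma(1 + 1 / a) - log1p(cv2)
      a <- uniroot(f, lower = 0.05, upper = 100, tol = 1e-13)$root
      aif_family("weibull", alpha = a, beta = m_id / gamma(1 + 1 / a))
    },
    abort(paste0("unknown family target: ", family_target),
          class = "metaif_domain_error")
  )
}

#' @export
print.met_reg_fit <- function(x, ...) {
  cat("MET/REG fit (reg_weight =", x$reg_weight, ")\n  family: ")
  print(x$family)
  cat("  moment residual:",
      formatC(x$dual$moment_residual, digits = 3, format = "e"),
      " KL to reference:", formatC(x$kl_to_reference, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.met_reg_fit <- function(x, ...) {
  tibble(
    family = x$family$family, alpha = x$family$alpha, beta = x$family$beta,
    reg_weight = x$reg_weight, moment_residual = x$dual$moment_residual,
    kl_to_reference = x$kl_to_reference, log_partition = x$dual$log_partition
  )
}

#' @export
tidy.met_reg_fit <- function(x, ...) {
  tibble(term = names(x$dual$lambda_effective),
         lambda = unname(x$dual$lambda_effective))
}
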