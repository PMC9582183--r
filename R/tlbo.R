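#' Teaching-learning-based optimization (TLBO)
#'
#' A population metaheuristic with two phases per iteration. In the teacher
#' phase every learner moves toward the current best solution:
#' `Z_new = Z_old + r (Z_teacher - S_F M)` with `r ~ U[0,1]` drawn per
#' learner, teaching factor `S_F` equal to 1 or 2 with equal probability,
#' and `M` the per-dimension population mean. In the learner phase each
#' learner pairs with a random distinct partner and moves toward the better
#' of the two: `Z_new = Z_old + r (Z_better - Z_worse)`. Moves are clipped
#' to the box bounds and accepted greedily (only if the objective improves),
#' so the best-so-far value is non-increasing.
#'
#' @param objective Function: numeric vector of length `length(lower)` in,
#'   finite scalar out (minimized).
#' @param lower,upper Box bounds, one finite value per dimension.
#' @param pop_size Population size (>= 2, default 30).
#' @param max_iters Teacher+learner iterations (default 200).
#' @param seed Optional integer seed; the run is then fully deterministic
#'   and the global RNG state is untouched.
#' @param tol Stop early once the best objective value falls below this.
#' @return A list of class `tlbo_result`: `par`, `value`, `trace` (tibble
#'   with `iteration`, `best_value`), `evaluations`.
#' @examples
#' tlbo_optimize(function(z) sum(z^2), c(-5, -5), c(5, 5),
#'               pop_size = 20, max_iters = 50, seed = 1)$value
#' @export
tlbo_optimize <- function(objective, lower, upper, pop_size = 30,
                          max_iters = 200, seed = NULL, tol = -Inf) {
  if (length(lower) != length(upper) || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(upper <= lower)) {
    abort("bounds must be finite with upper > lower elementwise",
          class = "metaif_config_error")
  }
  if (pop_size < 2) {
    abort("`pop_size` must be at least 2", class = "metaif_config_error")
  }
  if (max_iters < 0) {
    abort("`max_iters` must be non-negative", class = "metaif_config_error")
  }
  run <- function() tlbo_run(objective, lower, upper, pop_size, max_iters, tol)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

tlbo_run <- function(objective, lower, upper, pop_size, max_iters, tol) {
  dim <- length(lower)
  pop <- matrix(runif(pop_size * dim, rep(lower, each = pop_size),
                      rep(upper, each = pop_size)),
                nrow = pop_size)
  fvals <- apply(pop, 1, objective)
  n_eval <- pop_size
  best_trace <- numeric(max_iters)
  iter_done <- 0
  for (iter in seq_len(max_iters)) {
    tp <- tlbo_teacher_phase(pop, fvals, objective, lower, upper)
    pop <- tp$pop; fvals <- tp$fvals; n_eval <- n_eval + tp$n_eval
    lp <- tlbo_learner_phase(pop, fvals, objective, lower, upper)
    pop <- lp$pop; fvals <- lp$fvals; n_eval <- n_eval + lp$n_eval
    best_trace[iter] <- min(fvals)
    iter_done <- iter
    if (best_trace[iter] < tol) break
  }
  ibest <- which.min(fvals)
  structure(list(
    par = pop[ibest, ],
    value = fvals[ibest],
    trace = tibble(iteration = seq_len(iter_done),
                   best_value = best_trace[seq_len(iter_done)]),
    evaluations = n_eval
  ), class = "tlbo_result")
}

#' @rdname tlbo_optimize
#' @param pop Population matrix, one learner per row.
#' @param fvals Current objective values, one per learner.
#' @export
tlbo_teacher_phase <- function(pop, fvals, objective, lower, upper) {
  n <- nrow(pop)
  teacher <- pop[which.min(fvals), ]
  m <- colMeans(pop)
  n_eval <- 0
  for (i in seq_len(n)) {
    r <- runif(1)
    sf <- sample(1:2, 1)
    cand <- clip_bounds(pop[i, ] + r * (teacher - sf * m), lower, upper)
    f <- objective(cand)
    n_eval <- n_eval + 1
    if (f < fvals[i]) {
      pop[i, ] <- cand
      fvals[i] <- f
    }
  }
  list(pop = pop, fvals = fvals, n_eval = n_eval)
}

#' @rdname tlbo_optimize
#' @export
tlbo_learner_phase <- function(pop, fvals, objective, lower, upper) {
  n <- nrow(pop)
  if (n < 2) {
    abort("learner phase needs at least two learners",
          class = "metaif_config_error")
  }
  n_eval <- 0
  for (i in seq_len(n)) {
    j <- sample(seq_len(n)[-i], 1)
    r <- runif(1)
    step <- if (fvals[i] <= fvals[j]) pop[i, ] - pop[j, ] else pop[j, ] - pop[i, ]
    cand <- clip_bounds(pop[i, ] + r * step, lower, upper)
    f <- objective(cand)
    n_eval <- n_eval + 1
    if (f < fvals[i]) {
      pop[i, ] <- cand
      fvals[i] <- f
    }
  }
  list(pop = pop, fvals = fvals, n_eval = n_eval)
}

clip_bounds <- function(z, lower, upper) pmin(pmax(z, lower), upper)

#' @export
print.tlbo_result <- function(x, ...) {
  cat("TLBO result: best value", formatC(x$value, digits = 6, format = "g"),
      "after", nrow(x$trace), "iterations,", x$evaluations, "evaluations\n")
  invisible(x)
}

#' @export
autoplot.tlbo_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best objective (log scale)")
}

#' Export a TLBO trace as CSV
#'
#' @param result A `tlbo_result`.
#' @param path Output path.
#' @export
write_tlbo_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Maximum-entropy multipliers via TLBO
#'
#' Solves the same moment system as [solve_lambda_newton()] by minimizing
#' the squared moment residual `sum_i (E_p[phi_i](lambda) - mu_i)^2` with
#' [tlbo_optimize()] over the free multipliers. The dual is convex, so the
#' metaheuristic and the Newton solver share a unique optimum; an optional
#' Newton polish (off by default) can refine the TLBO point when the
#' multipliers feed further computation.
#'
#' @inheritParams solve_lambda_newton
#' @param bounds Half-width of the symmetric search box per free
#'   multiplier, or a 2-row matrix `rbind(lower, upper)`.
#' @param pop_size,max_iters,seed Passed to [tlbo_optimize()].
#' @param polish Number of Newton refinement steps after TLBO (default 0).
#' @return A `maxent_fit` with an extra `tlbo` element (the raw
#'   `tlbo_result`).
#' @export
solve_lambda_tlbo <- function(constraints, support = NULL, bounds = 12,
                              pop_size = 30, max_iters = 200, seed = NULL,
                              polish = 0) {
  basis <- constraints_basis(constraints)
  mu <- constraints$mu
  if (is.null(support)) support <- default_support(constraints)
  quad <- me_quadrature(max(support[1], 1e-12), support[2])
  phi_free <- basis_matrix(basis, quad$x)[, -1, drop = FALSE]
  mu_free <- mu[-1]
  nfree <- length(mu_free)
  if (is.matrix(bounds)) {
    lower <- bounds[1, ]; upper <- bounds[2, ]
  } else {
    lower <- rep(-abs(bounds), nfree); upper <- rep(abs(bounds), nfree)
  }
  objective <- function(lam) {
    st <- me_dual_state(lam, phi_free, quad$w)
    sum((st$moments - mu_free)^2)
  }
  res <- tlbo_optimize(objective, lower, upper, pop_size = pop_size,
                       max_iters = max_iters, seed = seed)
  lam <- res$par
  if (polish > 0) {
    for (k in seq_len(polish)) {
      st <- me_dual_state(lam, phi_free, quad$w)
      grad <- mu_free - st$moments
      step <- tryCatch(solve(st$cov + diag(1e-12, nfree), -grad),
                       error = function(e) numeric(nfree))
      lam <- lam + step
    }
  }
  st <- me_dual_state(lam, phi_free, quad$w)
  residual <- max(abs(st$moments - mu_free))
  lambda <- c(st$logz, lam)
  names(lambda) <- paste0("lambda_", basis_labels(basis))
  fit <- structure(list(
    lambda = lambda, basis = basis, support = support,
    moments = constraints, residual = residual,
    iterations = nrow(res$trace), converged = residual < 1e-6,
    quad = quad, tlbo = res
  ), class = "maxent_fit")
  fit$entropy <- differential_entropy(fit)
  fit
}
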