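# random soft-constrained problems on modest grids
random_problem <- function(reg_weight = NULL) {
  m <- sample(20:40, 1)
  xg <- sort(runif(m, 0.05, 6))
  while (any(diff(xg) <= 0)) xg <- sort(runif(m, 0.05, 6))
  g <- grid_density(xg, runif(m, 0.2, 2))
  mc <- compute_moments(rgamma(150, runif(1, 1, 4), scale = runif(1, 0.3, 1)),
                        me_basis(c("log", "identity")))
  met_reg_problem(mc, g, reg_weight = reg_weight %||% 10^runif(1, -2, 1))
}

test_that("log-partition is a safe log-sum-exp", {
  g <- grid_density(1:4, rep(0.25, 4))
  expect_equal(log_partition(rep(0, 4), g), 0)
  expect_equal(log_partition(c(-Inf, -Inf, -Inf, 5) + c(0, 0, 0, 0),
                             grid_density(1:4, c(0, 0, 0, 1) + 1e-300)),
               5, tolerance = 1e-12)
  withr::with_seed(2, {
    s <- rnorm(100)
    mass <- runif(100); mass <- mass / sum(mass)
    expect_equal(log_partition(s, grid_density(sort(runif(100, 1, 2)), mass)),
                 log(sum(mass * exp(s))), tolerance = 1e-12)
  })
  # extreme magnitudes do not overflow
  expect_true(is.finite(log_partition(c(1e4, 0), grid_density(1:2, c(0.5, 0.5)))))
})

test_that("reference satisfying the constraints is the optimum, and the
           huge-weight limit returns the reference", {
  xg <- seq(0.1, 5, length.out = 30)
  g <- kde_reference(withr::with_seed(4, rgamma(500, 2, scale = 0.5)),
                     grid_size = 30, from = 0.1, to = 5)
  # targets = moments of g itself -> J(g) = 0 is the global minimum
  phi <- basis_matrix(me_basis(c("log", "identity")), g$x)
  mc <- tibble::tibble(tag = c("const", "log", "identity"),
                       exponent = NA_real_,
                       mu = as.numeric(crossprod(phi, g$mass)))
  mc$mu[1] <- 1
  class(mc) <- c("moment_constraints", class(mc))
  for (w in c(0.01, 1)) {
    prob <- met_reg_problem(mc, g, reg_weight = w)
    p <- solve_primal(prob)
    expect_lt(max(abs(p$mass - g$mass)), 1e-5)
  }
  # strong regularization pins the solution at the reference even for
  # mismatched targets
  mc2 <- mc
  mc2$mu[2:3] <- mc2$mu[2:3] + 0.3
  p <- solve_dual(met_reg_problem(mc2, g, reg_weight = 1e6))$p_hat
  expect_lt(max(abs(p$mass - g$mass)), 1e-4)
})

test_that("primal and dual solutions agree on random problems and never
           beat the reference objective", {
  withr::with_seed(17, {
    for (i in 1:20) {
      prob <- random_problem()
      pp <- solve_primal(prob)
      dd <- solve_dual(prob)
      expect_lt(max(abs(pp$mass - dd$p_hat$mass)), 1e-5)
      expect_lte(attr(pp, "objective"),
                 metaif:::met_reg_objective(prob, prob$reference$mass) + 1e-12)
    }
  })
})

test_that("small 5-point problem matches a brute-force simplex search", {
  xg <- c(0.5, 1, 1.5, 2, 3)
  g <- grid_density(xg, rep(0.2, 5))
  mc <- tibble::tibble(tag = c("const", "log", "identity"),
                       exponent = NA_real_, mu = c(1, 0.1, 1.4))
  class(mc) <- c("moment_constraints", class(mc))
  prob <- met_reg_problem(mc, g, reg_weight = 0.1)
  p <- solve_primal(prob)
  # oracle: refine around the optimum by random search on the simplex
  best <- metaif:::met_reg_objective(prob, p$mass)
  withr::with_seed(5, {
    cand <- purrr::map_dbl(1:5000, function(i) {
      q <- as.numeric(p$mass) + runif(5, -0.02, 0.02)
      q <- pmax(q, 1e-9); q <- q / sum(q)
      metaif:::met_reg_objective(prob, q)
    })
  })
  expect_lte(best, min(cand) + 1e-6)
})

test_that("moment residual shrinks monotonically along the regularization
           path", {
  mc <- gamma_constraints(2, 0.5)
  xg <- seq(0.01, 8, length.out = 200)
  g <- grid_density(xg, dgamma(xg, 2.3, scale = 0.45) + 1e-6)
  resid <- purrr::map_dbl(c(10, 1, 0.1, 0.01), function(w) {
    solve_dual(met_reg_problem(mc, g, reg_weight = w))$moment_residual
  })
  expect_true(all(diff(resid) < 0))
})

test_that("log-partition is convex in lambda (midpoint test)", {
  withr::with_seed(23, {
    prob <- random_problem()
    for (i in 1:20) {
      l1 <- rnorm(3); l2 <- rnorm(3)
      f <- function(l) log_partition(as.numeric(prob$phi %*% l),
                                     prob$reference)
      expect_lte(f((l1 + l2) / 2), (f(l1) + f(l2)) / 2 + 1e-12)
    }
  })
})

test_that("pipeline recovers gamma parameters from large samples", {
  x <- withr::with_seed(6, rgamma(1e5, 2, scale = 0.5))
  fit <- met_reg_pipeline(x, reg_weight = 0.01)
  expect_lt(abs(fit$family$alpha - 2) / 2, 0.05)
  # huge weight: the family is the moment-match of the reference itself
  fit_big <- met_reg_pipeline(x, reg_weight = 1e6)
  ref <- fit_big$reference
  m_id <- sum(ref$mass * ref$x)
  m_log <- sum(ref$mass * log(ref$x))
  proj <- metaif:::project_to_family("gamma", m_id, m_log,
                                     sum(ref$mass * ref$x^2))
  expect_equal(fit_big$family$alpha, proj$alpha, tolerance = 1e-3)
  # erlang target produces an integer shape preserving the mean
  fe <- met_reg_pipeline(x, reg_weight = 0.01, family_target = "erlang")
  expect_equal(fe$family$alpha, round(fe$family$alpha))
  expect_equal(fe$family$alpha * fe$family$beta,
               fit$family$alpha * fit$family$beta, tolerance = 1e-2)
})

test_that("zero-mass reference points are rejected", {
  mc <- gamma_constraints(2, 1)
  g <- tibble::tibble(x = 1:3, mass = c(0.5, 0.5, 0))
  class(g) <- c("grid_density", class(g))
  expect_error(met_reg_problem(mc, g, 0.1),
               class = "metaif_reference_support")
})
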