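test_that("moments are sample means of the basis functions", {
  mc <- compute_moments(rep(3, 10), me_basis(c("log", "identity")))
  expect_equal(mc$mu, c(1, log(3), 3))
  mc <- compute_moments(c(1, exp(1)), me_basis("log"))
  expect_equal(mc$mu, c(1, 0.5))
  expect_error(compute_moments(c(1, -1), me_basis("log")),
               class = "metaif_domain_error")
})

test_that("moments of large gamma samples match the closed forms", {
  x <- withr::with_seed(21, rgamma(1e5, 2, scale = 0.5))
  mc <- compute_moments(x, me_basis(c("log", "identity")))
  expect_lt(abs(mc$mu[3] - 1) / 1, 0.01)
  expect_lt(abs(mc$mu[2] - (digamma(2) + log(0.5))), 0.02)
})

test_that("mean-only constraint yields the exponential density", {
  mc <- tibble::tibble(tag = c("const", "identity"), exponent = NA_real_,
                       mu = c(1, 2))
  fit <- solve_lambda_newton(mc)
  expect_equal(unname(fit$lambda[2]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$lambda[1]), -log(0.5), tolerance = 1e-8)
})

test_that("log + identity constraints recover the gamma multipliers", {
  fit <- solve_lambda_newton(gamma_constraints(2, 0.5))
  expect_equal(unname(fit$lambda[2:3]), c(-1, 2), tolerance = 1e-7)
  # and the family view inverts the multiplier map
  fam <- lambda_to_family(fit$lambda, fit$basis)
  expect_equal(fam$alpha, 2, tolerance = 1e-7)
  expect_equal(fam$beta, 0.5, tolerance = 1e-7)
})

test_that("the printed moment pair admits no equality-constrained gamma", {
  # psi(alpha) < ln(alpha) for every alpha > 0, so E[ln X] - ln E[X] must
  # be negative; -0.446 - ln(0.335) is +0.648
  alphas <- exp(seq(log(1e-3), log(1e4), length.out = 400))
  expect_true(all(digamma(alphas) - log(alphas) < 0))
  mc <- tibble::tibble(tag = c("const", "log", "identity"),
                       exponent = NA_real_, mu = c(1, -0.446, 0.335))
  expect_error(solve_lambda_newton(mc), class = "metaif_infeasible")
})

test_that("maximum-entropy densities normalize and evaluate correctly", {
  fit <- solve_lambda_newton(gamma_constraints(2.5, 0.4))
  quad <- metaif:::me_quadrature(1e-10, fit$support[2])
  mass <- sum(quad$w * density_eval(fit, quad$x))
  expect_lt(abs(mass - 1), 1e-6)
  expect_equal(density_eval(fit, -1), 0)
  expect_equal(density_eval(fit, fit$support[2] * 2), 0)
  # exponential multipliers (-ln r, r) give density r at the origin
  efit <- solve_lambda_newton(
    tibble::tibble(tag = c("const", "identity"), exponent = NA_real_,
                   mu = c(1, 1 / 3)))
  expect_equal(density_eval(efit, 1e-9), 3, tolerance = 1e-6)
})

test_that("gamma multipliers reproduce the textbook gamma pdf pointwise", {
  fl <- family_to_lambda(aif_family("gamma", 2.719, 0.237))
  xs <- c(0.05, 0.2, 0.644, 1.5, 3)
  phi <- basis_matrix(fl$basis, xs)
  expect_equal(exp(-as.numeric(phi %*% fl$lambda)),
               dgamma(xs, 2.719, scale = 0.237), tolerance = 1e-10)
})

test_that("differential entropy matches closed forms", {
  # uniform on (0, 1] as a maxent fit with no free constraints
  fit <- solve_lambda_newton(
    tibble::tibble(tag = "const", exponent = NA_real_, mu = 1),
    support = c(1e-12, 1))
  expect_equal(fit$entropy, 0, tolerance = 1e-6)
  expect_equal(family_entropy(aif_family("exponential", beta = 1.554)),
               1 + log(1.554))
  a <- 2.719; b <- 0.237
  expect_equal(family_entropy(aif_family("gamma", a, b)),
               a + log(b) + lgamma(a) + (1 - a) * digamma(a))
  gfit <- solve_lambda_newton(gamma_constraints(a, b))
  expect_equal(gfit$entropy, family_entropy(aif_family("gamma", a, b)),
               tolerance = 1e-8)
})

test_that("newton solution is entropy-optimal among perturbed densities
           satisfying the constraints", {
  mc <- gamma_constraints(2, 0.5)
  fit <- solve_lambda_newton(mc)
  quad <- fit$quad
  phi <- basis_matrix(fit$basis, quad$x)
  p0 <- density_eval(fit, quad$x) * quad$w
  phi_free <- phi[, 2:3]
  # reproject a perturbed mass vector onto the moment constraints by
  # exponential tilting (Newton on the tilt multipliers)
  reproject <- function(pert) {
    lam <- c(0, 0)
    for (it in 1:20) {
      q <- pert * exp(-as.numeric(phi_free %*% lam))
      q <- q / sum(q)
      delta <- as.numeric(crossprod(phi_free, q)) - mc$mu[2:3]
      if (max(abs(delta)) < 1e-11) break
      centered <- sweep(phi_free, 2, as.numeric(crossprod(phi_free, q)))
      covq <- crossprod(centered, centered * q)
      lam <- lam + solve(covq + diag(1e-12, 2), delta)
    }
    q
  }
  worst <- Inf
  withr::with_seed(31, {
    for (rep in 1:200) {
      pert <- p0 * exp(runif(length(p0), -0.5, 0.5))
      q <- reproject(pert / sum(pert))
      dens <- q / quad$w
      h <- -sum(q * log(pmax(dens, 1e-300)))
      worst <- min(worst, fit$entropy - h)
    }
  })
  expect_gte(worst, -1e-6)
})

test_that("family/multiplier maps are mutually inverse on random draws", {
  withr::with_seed(41, {
    for (i in 1:100) {
      fam <- if (i %% 2 == 0) {
        aif_family("gamma", alpha = runif(1, 0.3, 6), beta = runif(1, 0.1, 4))
      } else {
        aif_family("weibull", alpha = runif(1, 0.3, 5), beta = runif(1, 0.1, 4))
      }
      fl <- family_to_lambda(fam)
      back <- lambda_to_family(fl$lambda, fl$basis)
      expect_equal(back$alpha, fam$alpha, tolerance = 1e-10)
      expect_equal(back$beta, fam$beta, tolerance = 1e-10)
    }
  })
  # Weibull with shape 1 degenerates to the exponential mapping
  fl <- family_to_lambda(aif_family("weibull", alpha = 1, beta = 2))
  expect_equal(unname(fl$lambda[2]), 0)
  expect_equal(unname(fl$lambda[3]), 0.5)
  # inverse map pins the published fits
  fl <- family_to_lambda(aif_family("gamma", 2.719, 0.237))
  expect_equal(unname(fl$lambda[2]), -1.719)
  expect_equal(unname(fl$lambda[3]), 1 / 0.237)
  w <- family_to_lambda(aif_family("weibull", 2.6, 1.738))
  expect_equal(lambda_to_family(w$lambda, w$basis)$beta, 1.738,
               tolerance = 1e-10)
})

test_that("lambda map recognizes the exponential and the erlang view", {
  basis <- me_basis(c("log", "identity"))
  fam <- lambda_to_family(c(log(2), 0, 0.5), basis)
  expect_equal(fam$family, "exponential")
  expect_equal(fam$beta, 2)
  fam <- lambda_to_family(c(lgamma(2) + 2 * log(0.5), -1, 2), basis)
  expect_equal(fam$family, "gamma")
  expect_true(attr(fam, "also_erlang"))
  expect_error(lambda_to_family(c(0, 1, 1), me_basis(c("identity", "xlogx"))),
               class = "metaif_unsupported_family")
  expect_error(aif_family("erlang", alpha = 2.5), class = "metaif_domain_error")
})
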