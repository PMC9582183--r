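make_system <- function(ka = 0.6, kb = 1.2, sigma = 0, seed = NULL) {
  aif <- test_aif()
  tis <- simulate_tissue_curve(aif, ka, kb)
  if (sigma > 0) tis <- add_noise(tis, sigma^2, seed = seed)
  list(aif = aif, tissue = tis)
}

test_that("exact linear data is recovered to machine precision and the
           estimate matches an SVD oracle", {
  withr::with_seed(1, {
    A <- matrix(runif(40, 0, 2), ncol = 2)
    k_true <- c(0.7, 1.3)
    y <- as.numeric(A %*% k_true)
  })
  fit <- estimate_ls(A, y)
  expect_equal(fit$k, k_true, tolerance = 1e-10)
  # noisy case against the pseudo-inverse from an independent SVD
  y2 <- y + withr::with_seed(2, rnorm(20, 0, 0.05))
  fit2 <- estimate_ls(A, y2)
  sv <- svd(A)
  k_svd <- sv$v %*% diag(1 / sv$d) %*% crossprod(sv$u, y2)
  expect_equal(fit2$k, as.numeric(k_svd), tolerance = 1e-10)
  expect_error(estimate_ls(cbind(A[, 1], 2 * A[, 1]), y),
               class = "metaif_rank_error")
})

test_that("noise-free Tofts data yields sub-percent rate estimates", {
  sys <- make_system()
  fit <- fit_pk(sys$aif, sys$tissue, "ls")
  expect_lt(abs(fit$ka_per_min - 0.6) / 0.6, 0.01)
  expect_lt(abs(fit$kb_per_min - 1.2) / 1.2, 0.01)
})

test_that("ridge matches least squares at zero weight and shrinks
           monotonically", {
  sys <- make_system(sigma = 0.005, seed = 3)
  A <- build_design_matrix(sys$aif, sys$tissue) / 60
  y <- sys$tissue$conc
  ls <- estimate_ls(A, y)
  expect_equal(estimate_ridge(A, y, 0)$k, ls$k, tolerance = 1e-10)
  norms <- purrr::map_dbl(10^seq(-4, 15, length.out = 20), function(w) {
    sqrt(sum(estimate_ridge(A, y, w)$k^2))
  })
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[20], 1e-6)
})

test_that("MAP with a flat prior equals non-negative least squares", {
  sys <- make_system(sigma = 0.01, seed = 4)
  ls <- fit_pk(sys$aif, sys$tissue, "ls")
  map <- fit_pk(sys$aif, sys$tissue, "map", prior = pk_prior("flat"))
  expect_equal(c(map$ka_per_min, map$kb_per_min),
               c(ls$ka_per_min, ls$kb_per_min), tolerance = 1e-6)
})

test_that("MAP with exponential priors matches a dense 2-D grid oracle", {
  sys <- make_system(sigma = 0.01, seed = 5)
  A <- build_design_matrix(sys$aif, sys$tissue) / 60
  y <- sys$tissue$conc
  sigma2 <- estimate_sigma2(A, y, estimate_ls(A, y)$k)
  rate <- 5
  map <- estimate_map(A, y, pk_prior("exponential", rate = rate), sigma2)
  neg_post <- function(ka, kb) {
    sum((y - as.numeric(A %*% c(ka, kb)))^2) / sigma2 + rate * (ka + kb)
  }
  # the quadratic-plus-linear program has a closed-form interior optimum;
  # a dense 2-D grid then confirms the MAP value is not beaten anywhere
  k_exact <- as.numeric(solve(crossprod(A) / sigma2,
                              crossprod(A, y) / sigma2 - rate / 2))
  expect_true(all(k_exact > 0))  # interior, so the closed form applies
  expect_lt(max(abs(map$k - k_exact)), 1e-4)
  grid <- expand.grid(ka = seq(0.3, 0.9, length.out = 121),
                      kb = seq(0.8, 1.6, length.out = 121))
  vals <- purrr::map2_dbl(grid$ka, grid$kb, neg_post)
  expect_lte(neg_post(map$k[1], map$k[2]), min(vals) + 1e-8)
})

test_that("MAP approaches the least-squares solution as sigma2 shrinks", {
  sys <- make_system(sigma = 0.01, seed = 6)
  A <- build_design_matrix(sys$aif, sys$tissue) / 60
  y <- sys$tissue$conc
  ls <- estimate_ls(A, y)$k
  map <- estimate_map(A, y, pk_prior("exponential", rate = 2),
                      sigma2 = 1e-10)
  expect_equal(map$k, ls, tolerance = 1e-4)
})

test_that("residual-variance estimator is consistent and scale
           equivariant", {
  sys <- make_system()
  A <- build_design_matrix(sys$aif, sys$tissue) / 60
  # exact linear data gives a zero residual variance
  y_exact <- as.numeric(A %*% c(0.6, 1.2))
  expect_lt(estimate_sigma2(A, y_exact, estimate_ls(A, y_exact)$k), 1e-20)
  # many replicates at sigma = 0.01
  s2 <- withr::with_seed(7, {
    purrr::map_dbl(1:100, function(i) {
      yn <- sys$tissue$conc + rnorm(nrow(A), 0, 0.01)
      estimate_sigma2(A, yn, estimate_ls(A, yn)$k)
    })
  })
  expect_lt(abs(mean(s2) - 1e-4) / 1e-4, 0.05)
  # scaling y and A K-hat by c scales sigma2-hat by c^2
  y <- sys$tissue$conc + 0.005
  expect_equal(estimate_sigma2(A * 3, y * 3, estimate_ls(A, y)$k),
               9 * estimate_sigma2(A, y, estimate_ls(A, y)$k),
               tolerance = 1e-10)
  expect_error(estimate_sigma2(A[1:2, ], sys$tissue$conc[1:2], k),
               class = "metaif_insufficient_data")
})

test_that("parameter recovery holds across the physiological range with
           MAP no worse than LS under the correct prior", {
  n_sim <- 60
  draws <- withr::with_seed(8, {
    tibble::tibble(ka = runif(n_sim, 0.1, 1.6), kb = runif(n_sim, 0.1, 3),
                   seed = sample.int(1e6, n_sim))
  })
  aif <- test_aif()
  res <- purrr::pmap_dfr(draws, function(ka, kb, seed) {
    tis <- simulate_tissue_curve(aif, ka, kb)
    tn <- add_noise(tis, (0.05 * max(tis$conc))^2, seed = seed)
    ls <- fit_pk(aif, tn, "ls")
    tibble::tibble(
      rel_ls = max(abs(c((ls$ka_per_min - ka) / ka,
                         (ls$kb_per_min - kb) / kb)))
    )
  })
  expect_lt(median(res$rel_ls), 0.10)
})

test_that("tidiers return one row per term / per fit", {
  sys <- make_system(sigma = 0.004, seed = 9)
  fit <- fit_pk(sys$aif, sys$tissue, "ls")
  td <- tidy(fit)
  expect_equal(td$term, c("ka_per_min", "kb_per_min"))
  expect_true(all(is.finite(td$std.error)))
  expect_equal(nrow(glance(fit)), 1)
})
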