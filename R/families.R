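#' Parametric AIF density families
#'
#' The concentration-value densities handled by the package: exponential,
#' Weibull, gamma, and Erlang (gamma with integer shape). All use the
#' shape/scale convention `alpha`, `beta`; the exponential has `alpha = 1`.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`, `"erlang"`.
#' @param alpha Shape parameter (> 0; positive integer for Erlang; fixed to
#'   1 for the exponential).
#' @param beta Scale parameter (> 0).
#' @return A list of class `aif_family`.
#' @examples
#' aif_family("gamma", alpha = 2.719, beta = 0.237)
#' @export
aif_family <- function(family = c("exponential", "weibull", "gamma", "erlang"),
                       alpha = 1, beta = 1) {
  family <- match.arg(family)
  if (family == "exponential") alpha <- 1
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    abort("`alpha` and `beta` must be positive", class = "metaif_domain_error")
  }
  if (family == "erlang" && abs(alpha - round(alpha)) > 1e-8) {
    abort("Erlang shape must be a positive integer",
          class = "metaif_domain_error")
  }
  if (family == "erlang") alpha <- round(alpha)
  structure(list(family = family, alpha = alpha, beta = beta),
            class = "aif_family")
}

#' @export
print.aif_family <- function(x, ...) {
  cat(sprintf("%s(alpha = %g, beta = %g)\n", x$family, x$alpha, x$beta))
  invisible(x)
}

family_pdf <- function(fam, x) {
  switch(fam$family,
    exponential = dexp(x, rate = 1 / fam$beta),
    weibull = dweibull(x, shape = fam$alpha, scale = fam$beta),
    dgamma(x, shape = fam$alpha, scale = fam$beta)
  )
}

family_quantile <- function(fam, p) {
  switch(fam$family,
    exponential = qexp(p, rate = 1 / fam$beta),
    weibull = qweibull(p, shape = fam$alpha, scale = fam$beta),
    qgamma(p, shape = fam$alpha, scale = fam$beta)
  )
}

family_sample <- function(fam, n) {
  switch(fam$family,
    exponential = stats::rexp(n, rate = 1 / fam$beta),
    weibull = rweibull(n, shape = fam$alpha, scale = fam$beta),
    rgamma(n, shape = fam$alpha, scale = fam$beta)
  )
}

family_mean <- function(fam) {
  switch(fam$family,
    exponential = fam$beta,
    weibull = fam$beta * gamma(1 + 1 / fam$alpha),
    fam$alpha * fam$beta
  )
}

family_entropy <- function(fam) {
  a <- fam$alpha
  b <- fam$beta
  switch(fam$family,
    exponential = 1 + log(b),
    weibull = 0.5772156649015329 * (1 - 1 / a) + log(b / a) + 1,
    a + log(b) + lgamma(a) + (1 - a) * digamma(a)
  )
}

#' Map a parametric family to its maximum-entropy multipliers
#'
#' Writes the family density as `exp(-lambda_0 - lambda_1 phi_1 - lambda_2
#' phi_2)`. Gamma (and Erlang, and the exponential as gamma with shape 1)
#' uses the basis `{1, ln x, x}` with `lambda_log = -(alpha - 1)`,
#' `lambda_identity = 1/beta`, `lambda_0 = ln Gamma(alpha) + alpha ln beta`;
#' Weibull uses `{1, ln x, x^alpha}` with `lambda_log = -(alpha - 1)`,
#' `lambda_power = beta^-alpha`, `lambda_0 = -ln(alpha / beta^alpha)`.
#'
#' @param fam An [aif_family()].
#' @return A list with `basis` (an [me_basis()]) and named `lambda`.
#' @examples
#' family_to_lambda(aif_family("gamma", 2.719, 0.237))
#' @export
family_to_lambda <- function(fam) {
  a <- fam$alpha
  b <- fam$beta
  if (fam$family == "weibull") {
    basis <- me_basis(c("log", "power"), exponent = a)
    lambda <- c(-log(a / b^a), -(a - 1), b^(-a))
  } else {
    basis <- me_basis(c("log", "identity"))
    lambda <- c(lgamma(a) + a * log(b), -(a - 1), 1 / b)
  }
  names(lambda) <- paste0("lambda_", basis_labels(basis))
  list(basis = basis, lambda = lambda)
}

#' Recover the parametric family behind a multiplier vector
#'
#' Pattern-matches the basis: `{1, ln x, x}` identifies a gamma
#' (exponential when the log multiplier is 0; flagged `also_erlang` when the
#' implied shape is an integer); `{1, ln x, x^a}` identifies a Weibull with
#' shape `a`. The inverse of [family_to_lambda()].
#'
#' @param lambda Named or ordered multiplier vector `(lambda_0, lambda_1,
#'   lambda_2)` matching `basis`.
#' @param basis An [me_basis()] of three functions starting with the
#'   constant.
#' @return An [aif_family()], possibly with attribute `also_erlang`.
#' @export
lambda_to_family <- function(lambda, basis) {
  tags <- basis$tag
  lam <- unname(lambda)
  if (identical(tags, c("const", "log", "identity"))) {
    a <- 1 - lam[2]
    b <- 1 / lam[3]
    if (!is.finite(a) || a <= 0 || !is.finite(b) || b <= 0) {
      abort("multipliers do not define a normalizable gamma density",
            class = "metaif_unsupported_family")
    }
    fam <- if (abs(a - 1) < 1e-10) {
      aif_family("exponential", beta = b)
    } else {
      aif_family("gamma", alpha = a, beta = b)
    }
    attr(fam, "also_erlang") <- abs(a - round(a)) < 1e-8
    return(fam)
  }
  if (identical(tags, c("const", "log", "power"))) {
    a <- basis$exponent[3]
    if (abs(lam[2] + (a - 1)) > 1e-6) {
      abort("log multiplier is inconsistent with a Weibull of this shape",
            class = "metaif_unsupported_family")
    }
    b <- lam[3]^(-1 / a)
    return(aif_family("weibull", alpha = a, beta = b))
  }
  abort("basis pattern matches no supported family",
        class = "metaif_unsupported_family")
}

#' @export
tidy.aif_family <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @export
glance.aif_family <- function(x, ...) {
  tibble(family = x$family, alpha = x$alpha, beta = x$beta,
         mean = family_mean(x), entropy = family_entropy(x))
}

#' Serialize a fitted family to JSON
#'
#' @param fam An [aif_family()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
family_to_json <- function(fam, path = NULL) {
  fl <- family_to_lambda(fam)
  obj <- list(
    family = fam$family, alpha = fam$alpha, beta = fam$beta,
    lambdas = unname(fl$lambda),
    basis_tags = basis_labels(fl$basis)
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
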