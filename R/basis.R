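#' Moment-constraint basis functions
#'
#' The maximum-entropy machinery works with a small dictionary of basis
#' functions phi_i(x) on x > 0: the constant 1, ln(x), x itself, x ln(x),
#' and real powers x^a. A basis is a tibble with columns `tag` and
#' `exponent` (`NA` except for `power`), always starting with the constant.
#'
#' @param tags Character vector from `{"const", "log", "identity", "xlogx",
#'   "power"}`. A leading `"const"` is added if missing.
#' @param exponent Exponent(s) for the `power` entries, recycled in order;
#'   must be positive.
#' @return A tibble of class `me_basis`.
#' @examples
#' me_basis(c("log", "identity"))
#' me_basis(c("log", "power"), exponent = 2.6)
#' @export
me_basis <- function(tags, exponent = NULL) {
  known <- c("const", "log", "identity", "xlogx", "power")
  if (!all(tags %in% known)) {
    abort(paste0("unknown basis tag(s): ",
                 paste(setdiff(tags, known), collapse = ", ")),
          class = "metaif_domain_error")
  }
  if (tags[1] != "const") tags <- c("const", tags)
  if (anyDuplicated(tags[tags != "power"])) {
    abort("basis functions must be pairwise distinct",
          class = "metaif_domain_error")
  }
  npow <- sum(tags == "power")
  expo <- rep(NA_real_, length(tags))
  if (npow > 0) {
    if (is.null(exponent) || length(exponent) != npow) {
      abort("supply one `exponent` per power basis function",
            class = "metaif_domain_error")
    }
    if (any(exponent <= 0)) {
      abort("power exponents must be positive", class = "metaif_domain_error")
    }
    expo[tags == "power"] <- exponent
  }
  out <- tibble(tag = tags, exponent = expo)
  class(out) <- c("me_basis", class(out))
  out
}

#' Evaluate a basis at points x
#'
#' @param basis An [me_basis()].
#' @param x Positive numeric vector (non-positive x is allowed only for
#'   bases without `log`/`xlogx` terms).
#' @return A `length(x)` by `nrow(basis)` matrix.
#' @export
basis_matrix <- function(basis, x) {
  needs_log <- any(basis$tag %in% c("log", "xlogx"))
  if (needs_log && any(x <= 0)) {
    abort("log-type basis functions need strictly positive x",
          class = "metaif_domain_error")
  }
  cols <- purrr::map2(basis$tag, basis$exponent, function(tag, a) {
    switch(tag,
      const = rep(1, length(x)),
      log = log(x),
      identity = x,
      xlogx = x * log(x),
      power = x^a
    )
  })
  do.call(cbind, cols)
}

basis_labels <- function(basis) {
  ifelse(basis$tag == "power",
         sprintf("power(%g)", basis$exponent),
         basis$tag)
}

#' Sample moments of basis functions
#'
#' Computes the moment constraints mu_i as plain sample means of phi_i(x)
#' over the observations (the numerical-expectation step of the
#' maximum-entropy fit). mu for the constant is 1 by construction.
#'
#' @param samples Positive numeric observations (must be strictly positive
#'   when the basis contains `log` or `xlogx`).
#' @param basis An [me_basis()]; default `{1, ln x, x}` (the gamma-family
#'   signature).
#' @return A tibble of class `moment_constraints` with columns `tag`,
#'   `exponent`, `mu`.
#' @examples
#' compute_moments(rgamma(100, 2, scale = 0.5))
#' @export
compute_moments <- function(samples, basis = me_basis(c("log", "identity"))) {
  if (length(samples) < 1 || anyNA(samples)) {
    abort("`samples` must be non-missing", class = "metaif_domain_error")
  }
  phi <- basis_matrix(basis, samples)
  mu <- colMeans(phi)
  mu[1] <- 1
  out <- tibble(tag = basis$tag, exponent = basis$exponent, mu = mu)
  class(out) <- c("moment_constraints", class(out))
  out
}

constraints_basis <- function(constraints) {
  me_basis(constraints$tag,
           exponent = constraints$exponent[constraints$tag == "power"])
}
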