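# Shared fixtures built in code.

# equality constraint set whose exact maximum-entropy solution is
# Gamma(shape = alpha, scale = beta): E[ln X] = psi(alpha) + ln(beta),
# E[X] = alpha * beta
gamma_constraints <- function(alpha, beta) {
  out <- tibble::tibble(
    tag = c("const", "log", "identity"),
    exponent = NA_real_,
    mu = c(1, digamma(alpha) + log(beta), alpha * beta)
  )
  class(out) <- c("moment_constraints", class(out))
  out
}

gamma_lambda_free <- function(alpha, beta) c(-(alpha - 1), 1 / beta)

# smooth test AIF on the acquisition grid
test_aif <- function(n_frames = 46, dt = 11.9) {
  generate_aif_curve(n_frames = n_frames, dt = dt)
}

# closed-form KL between two gamma densities (shape/scale), in nats
gamma_gamma_kl <- function(a1, b1, a2, b2) {
  (a1 - a2) * digamma(a1) - lgamma(a1) + lgamma(a2) +
    a2 * (log(b2) - log(b1)) + a1 * (b1 - b2) / b2
}
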