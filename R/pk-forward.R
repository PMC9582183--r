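#' Two-compartment (Tofts) forward model
#'
#' Simulates the tissue concentration driven by an arterial input function
#' under the two-compartment exchange model
#' `dC_T/dt = Ka C_p(t) - Kb C_T(t)`, i.e.
#' `C_T(t) = Ka * integral_0^t C_p(s) exp(-Kb (t - s)) ds`.
#'
#' The AIF is treated as piecewise linear between its samples (zero before
#' the first sample), and the convolution is integrated exactly on each
#' interval against the exponential kernel, so the discrete forward model is
#' self-consistent with an ODE integration of the same interpolated input.
#'
#' @param aif A [concentration_curve()] holding the plasma concentration
#'   C_p(t).
#' @param ka_per_min,kb_per_min Exchange rate constants in 1/min (>= 0).
#'   Times are stored in seconds; rates are converted internally.
#' @return A `conc_curve` with the tissue concentration on the same grid.
#' @examples
#' aif <- concentration_curve(seq(0, 300, by = 11.9 * 2)[1:10],
#'                            c(0, 0, 1, 3, 4, 3, 2, 1.5, 1.2, 1))
#' simulate_tissue_curve(aif, ka_per_min = 0.6, kb_per_min = 1.2)
#' @export
simulate_tissue_curve <- function(aif, ka_per_min, kb_per_min) {
  if (ka_per_min < 0 || kb_per_min < 0) {
    abort("rate constants must be non-negative", class = "metaif_domain_error")
  }
  check_time_grid(aif$time_s)
  ka <- ka_per_min / 60
  kb <- kb_per_min / 60
  t <- aif$time_s
  cp <- aif$conc
  n <- length(t)
  ct <- numeric(n)
  # recursion: C_T(t_{i+1}) = C_T(t_i) e^{-kb h} + ka * int over the interval
  for (i in seq_len(n - 1)) {
    h <- t[i + 1] - t[i]
    a <- cp[i]
    b <- (cp[i + 1] - cp[i]) / h
    ct[i + 1] <- ct[i] * exp(-kb * h) +
      ka * interval_conv(a, b, h, kb)
  }
  concentration_curve(t, ct)
}

# exact integral of (a + b*u) * exp(-kb*(h - u)) du over u in [0, h];
# series expansion near kb*h = 0 keeps it stable for small rates
interval_conv <- function(a, b, h, kb) {
  z <- kb * h
  if (z < 1e-6) {
    # e1 = (1 - exp(-z))/kb -> h*(1 - z/2 + z^2/6); e2 -> h^2*(1/2 - z/3 ...)
    e1 <- h * (1 - z / 2 + z^2 / 6 - z^3 / 24)
    e2 <- h^2 * (1 / 2 - z / 3 + z^2 / 8 - z^3 / 30)
  } else {
    em <- exp(-z)
    e1 <- (1 - em) / kb
    e2 <- h / kb - (1 - em) / kb^2
  }
  a * e1 + b * e2
}

#' Murase design matrix of the linearized two-compartment model
#'
#' Rewrites the Tofts solution as a linear system in (Ka, Kb): row i is
#' `( integral_0^{t_i} C_p ds, -integral_0^{t_i} C_T ds )`, so that
#' `C_T = A K`. Integrals are cumulative trapezoids on the sampling grid;
#' the first row is (0, 0) when the grid starts at the first sample.
#'
#' @param aif,tissue `conc_curve`s on the same grid.
#' @return An n x 2 numeric matrix with attribute `time_s` (the grid).
#' @export
build_design_matrix <- function(aif, tissue) {
  check_same_grid(aif, tissue)
  t <- aif$time_s
  A <- cbind(
    cum_trapz(t, aif$conc),
    -cum_trapz(t, tissue$conc)
  )
  colnames(A) <- c("int_cp", "neg_int_ct")
  attr(A, "time_s") <- t
  A
}

cum_trapz <- function(t, y) {
  as.numeric(pracma::cumtrapz(t, y))
}
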