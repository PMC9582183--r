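#' Concentration-time curves
#'
#' A concentration curve is a tibble with a strictly increasing time column
#' `time_s` (seconds, first time >= 0) and a finite concentration column
#' `conc` (mmol/L). All pharmacokinetic and density-estimation functions in
#' the package consume and return this shape.
#'
#' @param time_s Numeric vector of acquisition times in seconds.
#' @param conc Numeric vector of concentrations in mmol/L, same length.
#' @return A tibble of class `conc_curve` with columns `time_s`, `conc`.
#' @examples
#' concentration_curve(c(0, 11.9, 23.8), c(0, 0.4, 0.9))
#' @export
concentration_curve <- function(time_s, conc) {
  time_s <- as.double(time_s)
  conc <- as.double(conc)
  if (length(time_s) < 2) {
    abort("a concentration curve needs at least 2 time points",
          class = "metaif_invalid_grid")
  }
  if (length(conc) != length(time_s)) {
    abort("`time_s` and `conc` must have the same length",
          class = "metaif_invalid_grid")
  }
  check_time_grid(time_s)
  if (!all(is.finite(conc))) {
    abort("concentrations must be finite", class = "metaif_invalid_curve")
  }
  out <- tibble(time_s = time_s, conc = conc)
  class(out) <- c("conc_curve", class(out))
  out
}

check_time_grid <- function(time_s) {
  if (anyNA(time_s) || !all(is.finite(time_s))) {
    abort("times must be finite", class = "metaif_invalid_grid")
  }
  if (time_s[1] < 0) {
    abort("first time must be >= 0", class = "metaif_invalid_grid")
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0) {
    abort(
      paste0("time grid must be strictly increasing (violated at row ",
             bad[1] + 1, ")"),
      class = "metaif_invalid_grid"
    )
  }
  invisible(time_s)
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$time_s - b$time_s) > 1e-9)) {
    abort("curves are not sampled on the same time grid",
          class = "metaif_grid_mismatch")
  }
  invisible(TRUE)
}

#' Add white Gaussian measurement noise to a curve
#'
#' Adds i.i.d. centered Gaussian noise of variance `sigma2` to the
#' concentration values, the acquisition noise model of the linearized
#' two-compartment system.
#'
#' @param curve A [concentration_curve()].
#' @param sigma2 Noise variance in (mmol/L)^2; must be >= 0.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the global RNG state is left untouched.
#' @return A `conc_curve` tibble.
#' @export
add_noise <- function(curve, sigma2, seed = NULL) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || is.na(sigma2) || sigma2 < 0) {
    abort("`sigma2` must be a single non-negative number",
          class = "metaif_domain_error")
  }
  if (sigma2 == 0) return(curve)
  draw <- function() rnorm(nrow(curve), mean = 0, sd = sqrt(sigma2))
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  concentration_curve(curve$time_s, curve$conc + eps)
}

#' Convert a longitudinal relaxation-time curve to concentration
#'
#' Converts measured T1 values to Gd-DTPA concentration via
#' `C(t) = (1/r1) * (1/T1(t) - 1/T10)`, with `r1` the in vivo longitudinal
#' relaxivity of protons. `T10` is the pre-contrast baseline T1, typically
#' the average over the first few frames.
#'
#' @param time_s Times in seconds.
#' @param t1_s T1 relaxation times in seconds (all > 0).
#' @param t10_s Baseline T1 in seconds; defaults to the mean of the first
#'   `baseline_frames` values.
#' @param r1 Relaxivity in l/s/mmol; default 4.24.
#' @param baseline_frames Frames averaged for the default `t10_s` (4).
#' @return A `conc_curve` tibble.
#' @examples
#' signal_to_concentration(c(0, 12), c(1, 0.5), t10_s = 1)
#' @export
signal_to_concentration <- function(time_s, t1_s, t10_s = NULL, r1 = 4.24,
                                    baseline_frames = 4) {
  if (any(!is.finite(t1_s)) || any(t1_s <= 0)) {
    abort("all T1 values must be positive", class = "metaif_domain_error")
  }
  if (r1 <= 0) abort("`r1` must be positive", class = "metaif_domain_error")
  if (is.null(t10_s)) {
    t10_s <- mean(t1_s[seq_len(min(baseline_frames, length(t1_s)))])
  }
  if (t10_s <= 0) abort("`t10_s` must be positive", class = "metaif_domain_error")
  conc <- (1 / r1) * (1 / t1_s - 1 / t10_s)
  concentration_curve(time_s, conc)
}

#' Read and write concentration curves
#'
#' Curve files are delimited text with a header; the delimiter (comma,
#' semicolon or tab) is autodetected from the header line. The first column
#' is time in seconds, the second concentration in mmol/L. The writer emits
#' CSV with 10 significant digits, so a write/read round trip is lossless to
#' ~1e-9 relative.
#'
#' @param path File path.
#' @return `read_curve()` returns a `conc_curve` tibble.
#' @export
read_curve <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    abort("empty curve file", class = "metaif_parse_error")
  }
  delim <- if (grepl(";", header)) ";" else if (grepl("\t", header)) "\t" else ","
  if (!grepl("[A-Za-z]", header)) {
    abort("curve file must start with a header row", class = "metaif_parse_error")
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) {
    abort("curve file needs a time column and a value column",
          class = "metaif_parse_error")
  }
  tm <- suppressWarnings(as.double(df[[1]]))
  vl <- suppressWarnings(as.double(df[[2]]))
  if (anyNA(tm) || anyNA(vl)) {
    abort(paste0("non-numeric cell at row ",
                 which(is.na(tm) | is.na(vl))[1] + 1L),
          class = "metaif_parse_error")
  }
  bad <- which(diff(tm) <= 0)
  if (length(bad) > 0) {
    # +2: one for the header line, one for diff() indexing
    abort(paste0("time column must be strictly increasing (violated at row ",
                 bad[1] + 2L, ")"),
          class = "metaif_invalid_grid")
  }
  concentration_curve(tm, vl)
}

#' @rdname read_curve
#' @param curve A `conc_curve`.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(
    time_s = formatC(curve$time_s, digits = 10, format = "g"),
    value = formatC(curve$conc, digits = 10, format = "g")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
autoplot.conc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "concentration (mmol/L)")
}
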