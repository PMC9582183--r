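#' Synthetic AIF curve generator
#'
#' Emulates the study acquisition: `n_frames` samples at `dt` seconds
#' (default 46 x 11.9 s), with the first `baseline_frames` pre-bolus frames
#' at zero. Two temporal shapes are available:
#'
#' * `shape = "family"` (default): the post-bolus concentration values are
#'   the exact plotting-position quantiles of the target [aif_family()],
#'   arranged in time by rank-matching a smooth gamma-variate bolus
#'   template (fast rise, slow washout). The curve therefore looks like a
#'   first-pass bolus while its value histogram follows the target family
#'   exactly -- the quantity the density estimators see.
#' * `shape = "biexponential"`: `D (a1 exp(-m1 t) + a2 exp(-m2 t))` with
#'   the widely used population constants as defaults (`a1 = 3.99`,
#'   `a2 = 4.78` kg/L, `m1 = 0.144`, `m2 = 0.0111` 1/min, `dose = 0.1`
#'   mmol/kg), time measured from bolus arrival.
#'
#' For pure density-estimation tests, [sample_aif_values()] draws i.i.d.
#' values from the family directly.
#'
#' @param n_frames Number of frames (default 46).
#' @param dt Frame spacing in seconds (default 11.9).
#' @param family Target [aif_family()] for the value distribution
#'   (default gamma(2.719, 0.237), the reference AIF-value density).
#' @param baseline_frames Zeroed pre-bolus frames (default 4).
#' @param shape `"family"` or `"biexponential"`.
#' @param biexp Named list overriding the bi-exponential constants.
#' @param template_peak_s,template_shape Gamma-variate template: seconds
#'   from bolus arrival to peak (default 60) and sharpness (default 3).
#' @return A `conc_curve` with attribute `aif_family`.
#' @examples
#' generate_aif_curve()
#' @export
generate_aif_curve <- function(n_frames = 46, dt = 11.9,
                               family = aif_family("gamma", 2.719, 0.237),
                               baseline_frames = 4,
                               shape = c("family", "biexponential"),
                               biexp = list(), template_peak_s = 60,
                               template_shape = 3) {
  shape <- match.arg(shape)
  if (n_frames < 4 || dt <= 0) {
    abort("need n_frames >= 4 and dt > 0", class = "metaif_domain_error")
  }
  t <- (seq_len(n_frames) - 1) * dt
  values <- numeric(n_frames)
  post <- seq(baseline_frames + 1, n_frames)
  tau <- t[post] - t[baseline_frames + 1]  # time since bolus arrival
  if (shape == "biexponential") {
    pars <- utils::modifyList(
      list(a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111, dose = 0.1),
      biexp
    )
    tau_min <- tau / 60
    values[post] <- pars$dose *
      (pars$a1 * exp(-pars$m1 * tau_min) + pars$a2 * exp(-pars$m2 * tau_min))
  } else {
    m <- length(post)
    q <- family_quantile(family, (seq_len(m) - 0.5) / m)
    # gamma-variate bolus template; its ranks place the quantiles in time
    template <- (tau / template_peak_s)^template_shape *
      exp(template_shape * (1 - tau / template_peak_s))
    template[1] <- template[1] + 1e-12  # break the tie with late washout
    values[post] <- sort(q)[rank(template, ties.method = "first")]
  }
  out <- concentration_curve(t, values)
  attr(out, "aif_family") <- family
  out
}

#' @rdname generate_aif_curve
#' @param n Number of i.i.d. draws.
#' @param seed Optional seed.
#' @export
sample_aif_values <- function(n, family = aif_family("gamma", 2.719, 0.237),
                              seed = NULL) {
  draw <- function() family_sample(family, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate one synthetic subject
#'
#' Couples the AIF to the two-compartment forward model and adds white
#' Gaussian measurement noise to the tissue curve.
#'
#' @inheritParams generate_aif_curve
#' @param ka_per_min,kb_per_min True rate constants (1/min).
#' @param sigma Noise standard deviation in mmol/L; `sigma_frac` of the
#'   peak noise-free tissue value when `NULL`.
#' @param sigma_frac Fractional noise level (default 0.02).
#' @param seed Optional seed for the noise draw.
#' @param aif Optional pre-built AIF curve (defaults to
#'   [generate_aif_curve()] with the remaining arguments).
#' @return A list with `aif`, `tissue` (noisy), `tissue_true`, and `truth`
#'   (a one-row tibble of the generating parameters).
#' @export
generate_subject <- function(ka_per_min, kb_per_min, sigma = NULL,
                             sigma_frac = 0.02, seed = NULL, aif = NULL,
                             n_frames = 46, dt = 11.9,
                             family = aif_family("gamma", 2.719, 0.237)) {
  if (is.null(aif)) {
    aif <- generate_aif_curve(n_frames = n_frames, dt = dt, family = family)
  }
  tissue_true <- simulate_tissue_curve(aif, ka_per_min, kb_per_min)
  if (is.null(sigma)) sigma <- sigma_frac * max(tissue_true$conc)
  tissue <- add_noise(tissue_true, sigma^2, seed = seed)
  truth <- tibble(
    ka_per_min = ka_per_min, kb_per_min = kb_per_min,
    sigma = sigma, seed = seed %||% NA_integer_
  )
  list(aif = aif, tissue = tissue, tissue_true = tissue_true, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Mirrors the 12-subject layout of the study: per-subject `ka` is drawn
#' uniformly from `ka_range` (default the printed per-patient range
#' `[0.16, 1.54]` 1/min) and `kb` from `kb_range`; the tissue noise SD is
#' `sigma_frac` of each subject's peak tissue value.
#'
#' @inheritParams generate_subject
#' @param n_subjects Cohort size (default 12).
#' @param ka_range,kb_range Uniform sampling ranges in 1/min.
#' @param seed Master seed; subject-level noise seeds are derived from it,
#'   so the whole cohort is reproducible.
#' @return A list of class `metaif_cohort` with `subjects` (list) and
#'   `manifest` (tibble with one row per subject).
#' @examples
#' cohort <- generate_cohort(n_subjects = 3, seed = 1)
#' cohort$manifest
#' @export
generate_cohort <- function(n_subjects = 12, ka_range = c(0.16, 1.54),
                            kb_range = c(0.2, 3), sigma_frac = 0.02,
                            seed = NULL, n_frames = 46, dt = 11.9,
                            family = aif_family("gamma", 2.719, 0.237)) {
  if (n_subjects < 1) {
    abort("`n_subjects` must be at least 1", class = "metaif_domain_error")
  }
  draw <- function() {
    tibble(
      subject = seq_len(n_subjects),
      ka_per_min = runif(n_subjects, ka_range[1], ka_range[2]),
      kb_per_min = runif(n_subjects, kb_range[1], kb_range[2]),
      noise_seed = sample.int(2^30, n_subjects)
    )
  }
  pars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  subjects <- purrr::pmap(
    list(pars$ka_per_min, pars$kb_per_min, pars$noise_seed),
    function(ka, kb, s) {
      generate_subject(ka, kb, sigma_frac = sigma_frac, seed = s,
                       n_frames = n_frames, dt = dt, family = family)
    }
  )
  manifest <- dplyr::bind_cols(
    pars,
    dplyr::bind_rows(purrr::map(subjects, function(s) {
      tibble(sigma = s$truth$sigma)
    })),
    tibble(n_frames = n_frames, dt = dt,
           aif_family = family$family, aif_alpha = family$alpha,
           aif_beta = family$beta, sigma_frac = sigma_frac,
           master_seed = seed %||% NA_integer_)
  )
  structure(list(subjects = subjects, manifest = manifest),
            class = "metaif_cohort")
}

#' Write / read a cohort as plain-text files
#'
#' Writes `subject_<k>_aif.csv`, `subject_<k>_tissue.csv` and
#' `manifest.json` under `dir`. `read_cohort_manifest()` restores the
#' manifest tibble exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::iwalk(cohort$subjects, function(s, k) {
    write_curve(s$aif, file.path(dir, sprintf("subject_%02d_aif.csv", k)))
    write_curve(s$tissue, file.path(dir, sprintf("subject_%02d_tissue.csv", k)))
  })
  jsonlite::write_json(cohort$manifest,
                       file.path(dir, "manifest.json"),
                       digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_manifest <- function(dir) {
  as_tibble(jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE))
}
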