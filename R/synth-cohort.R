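#' Configuration for the synthetic regional-power cohort generator
#'
#' Builds the configuration object consumed by [simulate_power_cohort()].
#' The generator draws strictly positive regional oscillatory powers from a
#' log-normal model: for each subject, band, region and hemisphere,
#' `log P = mu(group, band, region, hemisphere) + sigma * Z`. Healthy
#' controls carry a small baseline hemispheric bias (healthy brains are
#' measurably lateralized), and each patient group receives a multiplicative
#' power elevation `exp(delta)` on the hemisphere ipsilateral to its focus
#' (left hemisphere for `LtMTLE`, right for `RtMTLE`).
#'
#' Under this model the laterality index of a cell is
#' `tanh((log P_L - log P_R) / 2)`, so a baseline mean laterality `b`
#' corresponds to a fixed log-power offset `2 * atanh(b)`, and an ipsilateral
#' elevation `delta` shifts the noise-free laterality by
#' `tanh(delta / 2) = (e^delta - 1)/(e^delta + 1)` relative to baseline.
#'
#' @param n_ctr,n_lt,n_rt Group sizes; defaults 102, 16 and 19 mirror a
#'   healthy-control database and left/right patient cohorts.
#' @param baseline_li_mean Baseline control-group laterality per band x
#'   region; either a single number or a 7 x 4 matrix (bands in rows, regions
#'   in columns, canonical order).
#' @param effect_delta Ipsilateral log-power elevation per band x region for
#'   the patient groups; single number or 7 x 4 matrix, all entries >= 0.
#'   `NULL` selects the package default pattern: largest in the temporal and
#'   parietal lobes in the theta/alpha bands, smaller elsewhere (see
#'   [default_effect_delta()]).
#' @param noise_cv Within-group coefficient of variation of power (> 0);
#'   the log-normal sigma is `sqrt(log(1 + noise_cv^2))`.
#' @param age_range Ages are drawn uniformly on this interval (years).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `synth_config`.
#' @seealso [simulate_power_cohort()]
#' @export
synth_config <- function(n_ctr = 102, n_lt = 16, n_rt = 19,
                         baseline_li_mean = 0.05,
                         effect_delta = NULL,
                         noise_cv = 0.3,
                         age_range = c(8, 75),
                         seed = 1L) {
  n_ctr <- as.integer(n_ctr); n_lt <- as.integer(n_lt); n_rt <- as.integer(n_rt)
  if (any(is.na(c(n_ctr, n_lt, n_rt))) || min(n_ctr, n_lt, n_rt) < 2) {
    stop("group sizes n_ctr, n_lt, n_rt must all be >= 2", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv <= 0) {
    stop("noise_cv must be a single positive number", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("age_range must be an increasing pair of ages", call. = FALSE)
  }
  if (is.null(effect_delta)) effect_delta <- default_effect_delta()
  baseline <- expand_band_region(baseline_li_mean, "baseline_li_mean")
  delta <- expand_band_region(effect_delta, "effect_delta")
  if (any(delta < 0)) stop("effect_delta must be >= 0 everywhere", call. = FALSE)
  if (any(abs(baseline) >= 1)) {
    stop("baseline_li_mean entries must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  structure(
    list(n_ctr = n_ctr, n_lt = n_lt, n_rt = n_rt,
         baseline_li_mean = baseline, effect_delta = delta,
         noise_cv = noise_cv, age_range = as.numeric(age_range),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic MEG power cohort configuration\n")
  cat(sprintf("  groups: CTR n=%d, LtMTLE n=%d, RtMTLE n=%d\n",
              x$n_ctr, x$n_lt, x$n_rt))
  cat(sprintf("  noise_cv: %.3g   age range: [%g, %g]   seed: %d\n",
              x$noise_cv, x$age_range[1], x$age_range[2], x$seed))
  cat(sprintf("  max effect_delta: %.3g (ipsilateral log-power elevation)\n",
              max(x$effect_delta)))
  invisible(x)
}

#' Default ipsilateral effect pattern for synthetic patient cohorts
#'
#' Effect sizes (log-power elevations on the focus side) are concentrated in
#' the temporal and parietal lobes and peak in the theta band, tapering into
#' the neighbouring bands; frontal and occipital regions carry smaller
#' effects. This emulates the qualitative topography of band-power changes
#' reported for unilateral mesial temporal lobe epilepsy, where lateralized
#' elevations are most marked temporo-parietally in theta and adjacent bands.
#'
#' @return A 7 x 4 numeric matrix (bands x regions, canonical order).
#' @export
default_effect_delta <- function() {
  m <- matrix(0.15, nrow = 7, ncol = 4,
              dimnames = list(band_levels(), meg_regions()))
  m[, c("temporal", "parietal")] <- 0.25
  m[c("theta", "alpha"), c("temporal", "parietal")] <- 0.5
  m[c("beta", "low_gamma"), c("temporal", "parietal")] <- 0.35
  m["delta", c("temporal", "parietal")] <- 0.2
  m
}

expand_band_region <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) {
    x <- matrix(x, nrow = 7, ncol = 4)
  }
  if (!is.matrix(x) || !identical(dim(x), c(7L, 4L))) {
    stop(what, " must be a scalar or a 7 x 4 (band x region) matrix",
         call. = FALSE)
  }
  dimnames(x) <- list(band_levels(), meg_regions())
  x
}

#' Simulate a regional band-power cohort with known ground truth
#'
#' Generates per-subject regional oscillatory power tables for a
#' three-group cohort (left-focus patients, right-focus patients, healthy
#' controls) under the log-normal model described in [synth_config()].
#' Setting `effect_delta = 0` everywhere makes the patient groups
#' exchangeable with controls up to the shared baseline bias, which is the
#' null configuration used by the calibration tests.
#'
#' @param config A [synth_config()] object.
#' @return A tibble in long format with one row per subject x band x region x
#'   hemisphere: columns `subject_id`, `group`, `age`, `band`, `region`,
#'   `hemisphere`, `power`. All powers are strictly positive; each subject
#'   has exactly 7 x 4 x 2 = 56 rows.
#' @examples
#' cohort <- simulate_power_cohort(synth_config(n_ctr = 4, n_lt = 2, n_rt = 2))
#' dplyr::count(cohort, group)
#' @export
simulate_power_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("config must be created by synth_config()", call. = FALSE)
  }
  withr_seed(config$seed, {
    groups <- c(rep("CTR", config$n_ctr), rep("LtMTLE", config$n_lt),
                rep("RtMTLE", config$n_rt))
    n <- length(groups)
    ids <- sprintf("S%03d", seq_len(n))
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    sigma <- sqrt(log(1 + config$noise_cv^2))

    grid <- tidyr::expand_grid(
      band = band_levels(), region = meg_regions(), hemisphere = hemi_levels()
    )
    half_bias <- atanh(config$baseline_li_mean)  # +/- on L/R log-power

    # per-group mean log-power over the 56-cell grid
    bias <- ifelse(grid$hemisphere == "L", 1, -1) *
      half_bias[cbind(grid$band, grid$region)]
    delta <- config$effect_delta[cbind(grid$band, grid$region)]
    mu_by_group <- cbind(
      CTR = bias,
      LtMTLE = bias + ifelse(grid$hemisphere == "L", 1, 0) * delta,
      RtMTLE = bias + ifelse(grid$hemisphere == "R", 1, 0) * delta
    )
    mu <- mu_by_group[, groups, drop = FALSE]  # 56 x n
    powers <- exp(mu + sigma * matrix(stats::rnorm(nrow(grid) * n),
                                      nrow = nrow(grid)))

    tibble::tibble(
      subject_id = rep(ids, each = nrow(grid)),
      group = as_group_factor(rep(groups, each = nrow(grid))),
      age = rep(ages, each = nrow(grid)),
      band = as_band_factor(rep(grid$band, n)),
      region = as_region_factor(rep(grid$region, n)),
      hemisphere = as_hemi_factor(rep(grid$hemisphere, n)),
      power = as.vector(powers)
    )
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
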