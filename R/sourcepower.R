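#' Minimum-norm source inversion with a spatial-coherence prior
#'
#' Reconstructs per-source time series from one sensor epoch with the linear
#' inverse `J = R G' (G R G' + lambda I)^{-1} B`, where `G` is the gain
#' matrix, `B` the sensor data, and `R` a source-space coherence kernel
#' `R_ij = exp(-||s_i - s_j||^2 / (2 sigma^2))` that encodes the prior that
#' neighbouring sources co-activate (the idea behind coherence-prior /
#' sLORETA-like inverses). The operator is linear and fully deterministic.
#'
#' @param epoch Channels x samples matrix (one epoch of sensor data).
#' @param fm A `meg_forward` model; `nrow(fm$gain)` must match the epoch's
#'   channel count.
#' @param lambda_reg Tikhonov regularization (> 0). Default: 0.1 x mean
#'   diagonal of `G R G'`.
#' @param smoothness_sigma Coherence kernel width; default 0.2 x geometry
#'   radius.
#' @return Sources x samples matrix of reconstructed activity.
#' @export
invert_coherent <- function(epoch, fm, lambda_reg = NULL,
                            smoothness_sigma = NULL) {
  stopifnot(inherits(fm, "meg_forward"), is.matrix(epoch))
  if (nrow(epoch) != nrow(fm$gain)) {
    stop("epoch has ", nrow(epoch), " channels but gain expects ",
         nrow(fm$gain), call. = FALSE)
  }
  if (is.null(smoothness_sigma)) smoothness_sigma <- 0.2 * fm$radius
  R <- coherence_kernel(fm$source_locations, smoothness_sigma)
  G <- fm$gain
  GRGt <- G %*% R %*% t(G)
  if (is.null(lambda_reg)) lambda_reg <- 0.1 * mean(diag(GRGt))
  if (!is.numeric(lambda_reg) || lambda_reg <= 0) {
    stop("lambda_reg must be > 0 (regularized Gram matrix would be singular)",
         call. = FALSE)
  }
  W <- R %*% t(G) %*% solve(GRGt + lambda_reg * diag(nrow(G)))
  W %*% epoch
}

coherence_kernel <- function(locs, sigma) {
  d2 <- as.matrix(stats::dist(locs))^2
  exp(-d2 / (2 * sigma^2))
}

#' Morlet-wavelet band power of source time series
#'
#' Oscillatory power in one frequency band: the series is convolved with
#' complex Morlet wavelets (fixed number of cycles, default 7) on a 1-Hz
#' in-band frequency grid, squared magnitudes are averaged over time with
#' the edge samples (half a wavelet support on each side) excluded, and the
#' per-frequency powers are averaged over the grid.
#'
#' @param source_series Sources x samples matrix (or a numeric vector for a
#'   single series).
#' @param band Band name or a list with `lo`/`hi` in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param cycles Morlet cycles (time-frequency trade-off).
#' @return Non-negative power per source (numeric vector).
#' @export
morlet_band_power <- function(source_series, band, sampling_rate,
                              cycles = 7) {
  if (is.vector(source_series)) {
    source_series <- matrix(source_series, nrow = 1)
  }
  band <- resolve_band(band)
  if (band$hi >= sampling_rate / 2) {
    stop("band above Nyquist", call. = FALSE)
  }
  freqs <- seq(max(ceiling(band$lo), 1), floor(band$hi), by = 1)
  n <- ncol(source_series)
  powers <- matrix(0, nrow = nrow(source_series), ncol = length(freqs))
  for (j in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[j], sampling_rate, cycles)
    half <- (length(w) - 1) %/% 2
    if (n <= 2 * half + 1) {
      stop("series too short for a ", cycles, "-cycle wavelet at ",
           freqs[j], " Hz", call. = FALSE)
    }
    keep <- (half + 1):(n - half)
    for (i in seq_len(nrow(source_series))) {
      coef <- conv_same_complex(source_series[i, ], w)
      powers[i, j] <- mean(Mod(coef[keep])^2)
    }
  }
  rowMeans(powers)
}

# Complex Morlet wavelet, L1-normalized envelope so a unit sinusoid at the
# wavelet's centre frequency yields |coef| ~ 1/2 independent of frequency.
morlet_wavelet <- function(freq, sampling_rate, cycles) {
  sd_t <- cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sd_t * sampling_rate)
  t <- (-half:half) / sampling_rate
  env <- exp(-t^2 / (2 * sd_t^2))
  env <- env / sum(env)
  env * exp(2i * pi * freq * t)
}

# 'same'-length complex convolution via FFT.
conv_same_complex <- function(x, w) {
  nx <- length(x); nw <- length(w)
  nfft <- stats::nextn(nx + nw - 1, 2)
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - nx))) *
                     stats::fft(c(w, rep(0, nfft - nw))),
                     inverse = TRUE) / nfft
  half <- (nw - 1) %/% 2
  full[(half + 1):(half + nx)]
}

#' Average per-trial source power into a source image
#'
#' @param per_trial_powers List of per-source power vectors, one per trial
#'   (retained epoch); all the same length.
#' @param band Band label to attach.
#' @return A `meg_source_image`: `power` (per source), `band`,
#'   `n_trials_averaged`.
#' @export
average_trials <- function(per_trial_powers, band = NA_character_) {
  if (length(per_trial_powers) < 1) {
    stop("no trials to average", call. = FALSE)
  }
  lens <- vapply(per_trial_powers, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("trials have differing source counts", call. = FALSE)
  }
  p <- Reduce(`+`, per_trial_powers) / length(per_trial_powers)
  structure(
    list(power = p, band = band, n_trials_averaged = length(per_trial_powers)),
    class = "meg_source_image"
  )
}

#' @export
print.meg_source_image <- function(x, ...) {
  cat(sprintf("Source image (%s): %d sources, %d trial(s) averaged\n",
              x$band, length(x$power), x$n_trials_averaged))
  invisible(x)
}

#' Summarize a source image into regional powers
#'
#' Mean source power within each region x hemisphere cell of the forward
#' model: the regional powers that feed the laterality index.
#'
#' @param img A `meg_source_image` (or bare power vector).
#' @param fm The `meg_forward` model the image is aligned to.
#' @param band Band label for the output rows (defaults to the image's).
#' @return Tibble with columns `band`, `region`, `hemisphere`, `power`
#'   (8 rows, one per region x hemisphere).
#' @export
summarize_regions <- function(img, fm, band = NULL) {
  stopifnot(inherits(fm, "meg_forward"))
  power <- if (inherits(img, "meg_source_image")) img$power else img
  if (is.null(band)) {
    band <- if (inherits(img, "meg_source_image")) img$band else NA_character_
  }
  if (length(power) != ncol(fm$gain)) {
    stop("image has ", length(power), " sources but forward model has ",
         ncol(fm$gain), call. = FALSE)
  }
  cells <- tidyr::expand_grid(region = meg_regions(), hemisphere = hemi_levels())
  cells$power <- purrr::map2_dbl(cells$region, cells$hemisphere, function(r, h) {
    i <- fm$region_labels == r & fm$hemisphere_labels == h
    if (!any(i)) {
      stop("degenerate geometry: no sources in ", r, "/", h, call. = FALSE)
    }
    mean(power[i])
  })
  tibble::tibble(band = band, region = as_region_factor(cells$region),
                 hemisphere = as_hemi_factor(cells$hemisphere),
                 power = cells$power)
}

#' Full source-power pipeline for one subject's epochs
#'
#' Convenience wrapper running, for each requested band: band-pass
#' filtering, coherence-prior inversion per retained epoch, Morlet band
#' power per epoch (trial), trial averaging, and regional summarization.
#'
#' @param ep A `meg_epochs` object (already artifact-rejected and
#'   notch-filtered).
#' @param fm A `meg_forward` model.
#' @param bands Subset of [meg_bands()] rows (default all seven).
#' @param ... Passed to [invert_coherent()].
#' @return Regional power tibble: `band`, `region`, `hemisphere`, `power`.
#' @export
source_band_power <- function(ep, fm, bands = meg_bands(), ...) {
  stopifnot(inherits(ep, "meg_epochs"))
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    filtered <- bandpass_filter(ep, b)
    trial_powers <- lapply(filtered$epochs, function(e) {
      j <- invert_coherent(e, fm, ...)
      morlet_band_power(j, b, ep$sampling_rate)
    })
    img <- average_trials(trial_powers, band = as.character(b$band))
    summarize_regions(img, fm)
  })
}
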