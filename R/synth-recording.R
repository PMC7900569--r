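#' Simulate a multi-channel MEG sensor recording on a toy geometry
#'
#' Produces a sensor-space time series as a gain-projected sum of sinusoidal
#' sources, plus white sensor noise and a utility-frequency (power-line)
#' sinusoid common to all channels. Selected epochs can be contaminated with
#' a large-amplitude excursion so that downstream artifact rejection has a
#' known ground truth.
#'
#' @param n_channels Number of sensors (placed on a unit hemisphere).
#' @param duration_s Recording length in seconds.
#' @param components A data frame (or tibble) of oscillatory sources with
#'   columns `freq_hz`, `amplitude_ft` and `source` (index into the forward
#'   model's source grid). May have zero rows.
#' @param fm Forward model from [toy_forward_model()]; its gain matrix must
#'   have `n_channels` rows.
#' @param utility_hz Power-line frequency, 50 or 60 Hz.
#' @param utility_amplitude_ft Amplitude of the power-line component (fT).
#' @param noise_sd_ft White-noise standard deviation per channel (fT).
#' @param artifact_epochs Integer indices of 10-s epochs to contaminate with
#'   a 7000 fT excursion (1-based, relative to [segment_epochs()] with the
#'   default epoch length).
#' @param sampling_rate_hz Sampling rate (Hz); must exceed twice the highest
#'   band edge (240 Hz).
#' @param seed Integer seed.
#' @return A `meg_recording`: list with `data` (channels x samples matrix,
#'   fT), `sampling_rate`, `utility_hz` and the sensor geometry.
#' @examples
#' fm <- toy_forward_model()
#' rec <- simulate_recording(duration_s = 20, fm = fm, seed = 1)
#' dim(rec$data)
#' @export
simulate_recording <- function(n_channels = 32, duration_s = 300,
                               components = NULL, fm = NULL,
                               utility_hz = 50, utility_amplitude_ft = 100,
                               noise_sd_ft = 20, artifact_epochs = integer(),
                               sampling_rate_hz = 1000, seed = 1L) {
  if (!utility_hz %in% c(50, 60)) {
    stop("utility_hz must be 50 or 60", call. = FALSE)
  }
  if (sampling_rate_hz <= 2 * 120) {
    stop("sampling_rate_hz must exceed 240 Hz (twice the highest band edge)",
         call. = FALSE)
  }
  if (is.null(fm)) fm <- toy_forward_model(n_sensors = n_channels)
  if (nrow(fm$gain) != n_channels) {
    stop("forward model has ", nrow(fm$gain), " sensors, expected ",
         n_channels, call. = FALSE)
  }
  if (is.null(components)) {
    components <- tibble::tibble(freq_hz = numeric(), amplitude_ft = numeric(),
                                 source = integer())
  }
  if (any(components$amplitude_ft < 0)) {
    stop("component amplitudes must be >= 0", call. = FALSE)
  }
  n_samp <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n_samp) - 1) / sampling_rate_hz

  withr_seed(seed, {
    x <- matrix(0, nrow = n_channels, ncol = n_samp)
    if (nrow(components) > 0) {
      for (k in seq_len(nrow(components))) {
        src <- as.integer(components$source[k])
        if (src < 1 || src > ncol(fm$gain)) {
          stop("component source index out of range", call. = FALSE)
        }
        phase <- stats::runif(1, 0, 2 * pi)
        s <- components$amplitude_ft[k] *
          sin(2 * pi * components$freq_hz[k] * t + phase)
        x <- x + fm$gain[, src, drop = FALSE] %*% matrix(s, nrow = 1)
      }
    }
    if (utility_amplitude_ft > 0) {
      line <- utility_amplitude_ft * sin(2 * pi * utility_hz * t)
      x <- x + matrix(rep(line, each = n_channels), nrow = n_channels)
    }
    if (noise_sd_ft > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd_ft),
                      nrow = n_channels)
    }
    ep_len <- 10 * sampling_rate_hz
    for (ep in artifact_epochs) {
      i0 <- (ep - 1) * ep_len + 1
      if (i0 < 1 || i0 + ep_len - 1 > n_samp) {
        stop("artifact epoch ", ep, " outside the recording", call. = FALSE)
      }
      # a single 7000 fT spike mid-epoch on channel 1
      x[1, i0 + ep_len %/% 2] <- 7000
    }
    new_recording(x, sampling_rate_hz, utility_hz, fm)
  })
}

new_recording <- function(data, sampling_rate, utility_hz, fm = NULL) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  structure(
    list(data = data, sampling_rate = sampling_rate, utility_hz = utility_hz,
         forward_model = fm),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf(
    "MEG recording: %d channels x %d samples (%.1f s at %g Hz), utility %g Hz\n",
    nrow(x$data), ncol(x$data), ncol(x$data) / x$sampling_rate,
    x$sampling_rate, x$utility_hz))
  invisible(x)
}

#' Write / read a recording as a plain-text array with a JSON sidecar
#'
#' The sample matrix is stored as headerless CSV (channels in rows) and the
#' metadata (`sampling_rate_hz`, `utility_hz`) as a JSON sidecar next to it.
#'
#' @param rec A `meg_recording`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `meg_recording`.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- sprintf('{"sampling_rate_hz": %s, "utility_hz": %s}',
                  format(rec$sampling_rate), format(rec$utility_hz))
  writeLines(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  data <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(data) <- NULL
  meta <- readLines(paste0(path, ".json"), warn = FALSE)
  sr <- as.numeric(sub('.*"sampling_rate_hz": *([0-9.eE+-]+).*', "\\1", meta))
  uh <- as.numeric(sub('.*"utility_hz": *([0-9.eE+-]+).*', "\\1", meta))
  new_recording(data, sr, uh)
}
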