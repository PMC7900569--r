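#' Canonical frequency bands
#'
#' The seven resting-state MEG bands used throughout the package, from delta
#' to the high-frequency-oscillation (HFO) band. The delta band's printed
#' lower edge of 0 Hz is implemented as 0.3 Hz, the hardware high-pass of the
#' recording chain, because a true 0-Hz filter edge is unrealizable.
#'
#' @return A tibble with columns `band` (ordered factor, band-major feature
#'   order), `lo` and `hi` (Hz).
#' @examples
#' meg_bands()
#' @export
meg_bands <- function() {
  tibble::tibble(
    band = factor(band_levels(), levels = band_levels()),
    lo   = c(0.3, 4, 8, 13, 26, 41, 81),
    hi   = c(3, 7, 12, 25, 40, 80, 120)
  )
}

band_levels <- function() {
  c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma", "hfo")
}

#' @rdname meg_bands
#' @export
meg_regions <- function() {
  c("frontal", "temporal", "parietal", "occipital")
}

hemi_levels <- function() c("L", "R")

group_levels <- function() c("LtMTLE", "RtMTLE", "CTR")

#' Names of the 28 laterality-index features in canonical order
#'
#' Feature order is band-major: all four regions of delta, then theta, and so
#' on through HFO. The order is fixed so the 28-element predictor vector is
#' reproducible across runs.
#'
#' @return Character vector of length 28, `"<band>.<region>"`.
#' @export
li_feature_names <- function() {
  as.vector(vapply(
    band_levels(),
    function(b) paste(b, meg_regions(), sep = "."),
    character(4)
  ))
}

as_band_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), band_levels())
  if (length(bad) > 0) {
    stop("unknown band label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = band_levels())
}

as_region_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), meg_regions())
  if (length(bad) > 0) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = meg_regions())
}

as_hemi_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), hemi_levels())
  if (length(bad) > 0) {
    stop("unknown hemisphere label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = hemi_levels())
}

as_group_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), group_levels())
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = group_levels())
}
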