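#' Split a recording into fixed-length epochs
#'
#' Divides the continuous sensor series into non-overlapping segments
#' (default 10 s); any trailing remainder shorter than one epoch is dropped.
#'
#' @param rec A `meg_recording`.
#' @param epoch_length_s Epoch length in seconds.
#' @return A `meg_epochs` object: list of channels x samples blocks plus
#'   `epoch_length_s`, `kept_indices` (original epoch indices),
#'   `sampling_rate` and `utility_hz`.
#' @export
segment_epochs <- function(rec, epoch_length_s = 10) {
  stopifnot(inherits(rec, "meg_recording"))
  len <- round(epoch_length_s * rec$sampling_rate)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1) {
    stop("recording shorter than one epoch (", epoch_length_s, " s)",
         call. = FALSE)
  }
  epochs <- lapply(seq_len(n_ep), function(i) {
    rec$data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
  })
  new_epochs(epochs, epoch_length_s, seq_len(n_ep), rec$sampling_rate,
             rec$utility_hz)
}

new_epochs <- function(epochs, epoch_length_s, kept, sampling_rate,
                       utility_hz) {
  structure(
    list(epochs = epochs, epoch_length_s = epoch_length_s,
         kept_indices = as.integer(kept), sampling_rate = sampling_rate,
         utility_hz = utility_hz),
    class = "meg_epochs"
  )
}

#' @export
print.meg_epochs <- function(x, ...) {
  cat(sprintf("MEG epochs: %d x %g s (kept of original: %s)\n",
              length(x$epochs), x$epoch_length_s,
              paste(range(x$kept_indices), collapse = "-")))
  invisible(x)
}

#' Reject epochs containing large-amplitude artifacts
#'
#' An epoch is discarded if the absolute signal on any channel exceeds the
#' threshold at any sample (default 6000 fT). `kept_indices` keeps track of
#' the surviving epochs' original positions.
#'
#' @param ep A `meg_epochs` object.
#' @param threshold_ft Rejection threshold in fT (> 0).
#' @return A `meg_epochs` object with the contaminated epochs removed.
#' @export
reject_epochs <- function(ep, threshold_ft = 6000) {
  stopifnot(inherits(ep, "meg_epochs"))
  if (threshold_ft <= 0) stop("threshold_ft must be > 0", call. = FALSE)
  keep <- vapply(ep$epochs, function(e) max(abs(e)) <= threshold_ft,
                 logical(1))
  if (!any(keep)) {
    stop("all epochs rejected at ", threshold_ft,
         " fT; downstream power is undefined", call. = FALSE)
  }
  new_epochs(ep$epochs[keep], ep$epoch_length_s, ep$kept_indices[keep],
             ep$sampling_rate, ep$utility_hz)
}

# Zero-phase (forward-backward) application of an IIR filter to every
# channel of every epoch; shape-preserving.
apply_filtfilt <- function(ep, filt) {
  epochs <- lapply(ep$epochs, function(e) {
    out <- t(apply(e, 1, function(ch) signal::filtfilt(filt, ch)))
    dim(out) <- dim(e)
    out
  })
  new_epochs(epochs, ep$epoch_length_s, ep$kept_indices, ep$sampling_rate,
             ep$utility_hz)
}

#' Remove the power-line component with a zero-phase band-stop filter
#'
#' A 4th-order Butterworth band-stop filter, 2 Hz wide and centred on the
#' site's utility frequency, applied forward and backward so the net phase
#' response is zero. Attenuation at the utility frequency exceeds 20 dB
#' while frequencies more than 3 Hz away are essentially untouched.
#'
#' @param ep A `meg_epochs` object.
#' @param utility_hz Line frequency (50 or 60 Hz); defaults to the value
#'   recorded with the epochs.
#' @return Filtered `meg_epochs`, same shape and epoch count.
#' @export
notch_filter <- function(ep, utility_hz = ep$utility_hz) {
  stopifnot(inherits(ep, "meg_epochs"))
  nyq <- ep$sampling_rate / 2
  if (utility_hz >= nyq) stop("utility_hz at or above Nyquist", call. = FALSE)
  w <- c(utility_hz - 1, utility_hz + 1) / nyq
  filt <- signal::butter(4, w, type = "stop")
  apply_filtfilt(ep, filt)
}

#' Band-limit epochs to one frequency band
#'
#' Zero-phase 4th-order Butterworth filtering to the band's `[lo, hi]` Hz
#' passband. In-band sinusoids are preserved (well under 1 dB loss away from
#' the edges); components an octave or more outside are attenuated by more
#' than 20 dB.
#'
#' @param ep A `meg_epochs` object.
#' @param band One row of [meg_bands()] (or any list with `lo` and `hi` in
#'   Hz), or a band name.
#' @return Filtered `meg_epochs`, same shape and epoch count.
#' @export
bandpass_filter <- function(ep, band) {
  stopifnot(inherits(ep, "meg_epochs"))
  band <- resolve_band(band)
  nyq <- ep$sampling_rate / 2
  if (band$hi >= nyq) {
    stop("band edge ", band$hi, " Hz at or above Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  filt <- signal::butter(4, c(band$lo, band$hi) / nyq, type = "pass")
  apply_filtfilt(ep, filt)
}

resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1) {
    tbl <- meg_bands()
    i <- match(band, as.character(tbl$band))
    if (is.na(i)) stop("unknown band name: ", band, call. = FALSE)
    return(list(name = band, lo = tbl$lo[i], hi = tbl$hi[i]))
  }
  if (!is.null(band$lo) && !is.null(band$hi) && band$lo < band$hi) {
    nm <- if (!is.null(band$band)) as.character(band$band) else
      if (!is.null(band$name)) band$name else NA_character_
    return(list(name = nm, lo = as.numeric(band$lo), hi = as.numeric(band$hi)))
  }
  stop("band must be a band name or have numeric lo < hi", call. = FALSE)
}
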