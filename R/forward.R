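#' Toy sensor/source geometry and gain matrix
#'
#' Builds a desk-scale stand-in for an MEG forward model: sensors on a unit
#' hemisphere, sources on a concentric hemisphere of radius 0.8, and a gain
#' matrix from an inverse-square distance kernel. Sources are placed in
#' fixed clusters around one centre per region x hemisphere cell (frontal,
#' temporal, parietal, occipital; left/right by the sign of the lateral x
#' coordinate), so every cell is guaranteed non-empty and the geometry is
#' fully deterministic. No biophysical (single-shell/Sarvas) modelling is
#' attempted; the geometry exists so that inversion, band power and regional
#' summaries can be exercised with known ground truth.
#'
#' @param n_sensors Number of sensors, placed by a Fibonacci spiral on the
#'   unit hemisphere.
#' @param sources_per_cell Sources per region x hemisphere cell (>= 1).
#' @return A `meg_forward` object: `gain` (sensors x sources),
#'   `sensor_locations`, `source_locations` (3-column matrices),
#'   `region_labels`, `hemisphere_labels` and `radius`.
#' @examples
#' fm <- toy_forward_model()
#' table(fm$region_labels, fm$hemisphere_labels)
#' @export
toy_forward_model <- function(n_sensors = 32, sources_per_cell = 3) {
  stopifnot(n_sensors >= 4, sources_per_cell >= 1)
  sensors <- fibonacci_hemisphere(n_sensors)

  centres <- rbind(
    frontal   = c(0.50,  0.75, 0.44),
    temporal  = c(0.90,  0.00, 0.30),
    parietal  = c(0.45, -0.30, 0.85),
    occipital = c(0.40, -0.85, 0.35)
  )
  centres <- centres / sqrt(rowSums(centres^2))
  radius <- 0.8

  locs <- list(); regions <- character(); hemis <- character()
  # fixed tangential offsets -> deterministic cluster per cell
  offs <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(-0.1, 0.05), c(0.05, -0.1),
                c(-0.05, -0.08), c(0.08, 0.08), c(-0.08, 0.1))
  if (sources_per_cell > nrow(offs)) {
    stop("sources_per_cell must be <= ", nrow(offs), call. = FALSE)
  }
  for (h in c("L", "R")) {
    sgn <- if (h == "L") -1 else 1
    for (r in rownames(centres)) {
      c0 <- centres[r, ] * c(sgn, 1, 1)
      # orthonormal tangent basis at c0
      u <- c(-c0[2], c0[1], 0)
      if (sum(u^2) < 1e-9) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      v <- c(c0[2] * u[3] - c0[3] * u[2],
             c0[3] * u[1] - c0[1] * u[3],
             c0[1] * u[2] - c0[2] * u[1])
      for (k in seq_len(sources_per_cell)) {
        p <- c0 + offs[k, 1] * u + offs[k, 2] * v
        p <- radius * p / sqrt(sum(p^2))
        # keep sources strictly on their hemisphere
        if (sign(p[1]) != sgn) p[1] <- sgn * abs(p[1])
        locs[[length(locs) + 1]] <- p
        regions <- c(regions, r)
        hemis <- c(hemis, h)
      }
    }
  }
  src <- do.call(rbind, locs)
  gain <- inverse_square_gain(sensors, src)
  structure(
    list(gain = gain, sensor_locations = sensors, source_locations = src,
         region_labels = regions, hemisphere_labels = hemis, radius = radius),
    class = "meg_forward"
  )
}

#' @export
print.meg_forward <- function(x, ...) {
  cat(sprintf("Toy MEG forward model: %d sensors x %d sources (radius %g)\n",
              nrow(x$gain), ncol(x$gain), x$radius))
  print(table(region = x$region_labels, hemisphere = x$hemisphere_labels))
  invisible(x)
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # covers (0, 1): upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

inverse_square_gain <- function(sensors, sources, eps = 0.05) {
  d2 <- outer(rowSums(sensors^2), rep(1, nrow(sources))) +
    outer(rep(1, nrow(sensors)), rowSums(sources^2)) -
    2 * sensors %*% t(sources)
  1 / (pmax(d2, 0) + eps)
}
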