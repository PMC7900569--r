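#' Read and write long-format regional power tables
#'
#' The on-disk cohort format is a plain CSV with columns `subject_id`,
#' `group`, `age`, `band`, `region`, `hemisphere`, `power`. Reading
#' validates the header, the categorical domains, power positivity (with
#' the offending row number in the error) and per-subject completeness
#' (56 cells each).
#'
#' @param path CSV path.
#' @return `read_power_table()`: a validated tibble as produced by
#'   [simulate_power_cohort()]. `write_power_table()`: `path`, invisibly.
#' @export
read_power_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "age", "band", "region", "hemisphere",
                "power")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    stop("power table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_levels <- function(col, domain) {
    bad <- which(!tbl[[col]] %in% domain)
    if (length(bad) > 0) {
      stop("row ", bad[1], ": unknown ", col, " '", tbl[[col]][bad[1]], "'",
           call. = FALSE)
    }
  }
  check_levels("group", group_levels())
  check_levels("band", band_levels())
  check_levels("region", meg_regions())
  check_levels("hemisphere", hemi_levels())
  bad_p <- which(!is.finite(tbl$power) | tbl$power <= 0)
  if (length(bad_p) > 0) {
    stop("row ", bad_p[1], ": power must be a positive number, got ",
         tbl$power[bad_p[1]], call. = FALSE)
  }
  tbl <- dplyr::mutate(tbl,
                       group = as_group_factor(.data$group),
                       band = as_band_factor(.data$band),
                       region = as_region_factor(.data$region),
                       hemisphere = as_hemi_factor(.data$hemisphere))
  check_complete_cells(tbl)
  tbl
}

#' @param cohort Power tibble to serialize.
#' @rdname read_power_table
#' @export
write_power_table <- function(cohort, path) {
  out <- dplyr::mutate(cohort, dplyr::across(
    dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
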