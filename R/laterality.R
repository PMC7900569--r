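#' Laterality index of a left/right power pair
#'
#' `LI = (P_L - P_R) / (P_L + P_R)`, the classic normalized hemispheric
#' asymmetry of regional oscillatory power. It lies in (-1, 1); +1 means
#' fully left-dominant power ("right-to-left dominance" convention), -1
#' fully right-dominant. Undefined when `P_L + P_R = 0`, so non-positive
#' powers (below `1e-12`) raise an error rather than being clamped.
#'
#' @param p_left,p_right Strictly positive powers (vectorized).
#' @return Numeric vector of laterality indices in (-1, 1).
#' @examples
#' compute_li(2, 1)   # 1/3, left-dominant
#' compute_li(1, 3)   # -0.5
#' @export
compute_li <- function(p_left, p_right) {
  if (any(!is.finite(p_left)) || any(!is.finite(p_right)) ||
      any(p_left < 1e-12) || any(p_right < 1e-12)) {
    stop("laterality index requires strictly positive finite powers",
         call. = FALSE)
  }
  (p_left - p_right) / (p_left + p_right)
}

#' Per-subject laterality indices from a regional power table
#'
#' Computes the 28 laterality indices (7 bands x 4 regions) for every
#' subject in a long-format power table. Rows are ordered band-major (all
#' regions of delta, then theta, ... HFO), the fixed feature order used by
#' the classifier.
#'
#' @param powers Long tibble with columns `subject_id`, `band`, `region`,
#'   `hemisphere`, `power` (and optionally `group`, `age`, carried through).
#'   Every subject must have a complete 7 x 4 x 2 table.
#' @return Long tibble: `subject_id` (+ `group`, `age` if present), `band`,
#'   `region`, `li`, with attribute `baseline_corrected = FALSE`.
#' @export
li_table <- function(powers) {
  required <- c("subject_id", "band", "region", "hemisphere", "power")
  missing_cols <- setdiff(required, names(powers))
  if (length(missing_cols) > 0) {
    stop("power table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  powers <- dplyr::mutate(powers,
                          band = as_band_factor(.data$band),
                          region = as_region_factor(.data$region),
                          hemisphere = as_hemi_factor(.data$hemisphere))
  check_complete_cells(powers)

  meta_cols <- intersect(c("group", "age"), names(powers))
  wide <- tidyr::pivot_wider(powers, names_from = "hemisphere",
                             values_from = "power")
  out <- dplyr::mutate(wide, li = compute_li(.data$L, .data$R))
  out <- dplyr::select(out, dplyr::all_of(c("subject_id", meta_cols,
                                            "band", "region", "li")))
  out <- dplyr::arrange(out, .data$subject_id, .data$band, .data$region)
  attr(out, "baseline_corrected") <- FALSE
  out
}

check_complete_cells <- function(powers) {
  counts <- dplyr::count(powers, .data$subject_id, .data$band, .data$region,
                         .data$hemisphere)
  if (any(counts$n != 1) || any(table(counts$subject_id) != 56)) {
    full <- tidyr::expand_grid(
      subject_id = unique(powers$subject_id),
      band = band_levels(), region = meg_regions(), hemisphere = hemi_levels()
    )
    have <- paste(powers$subject_id, powers$band, powers$region,
                  powers$hemisphere)
    want <- paste(full$subject_id, full$band, full$region, full$hemisphere)
    miss <- setdiff(want, have)
    dup <- counts[counts$n > 1, ]
    msg <- character()
    if (length(miss) > 0) {
      msg <- c(msg, paste0("missing cells: ",
                           paste(utils::head(miss, 5), collapse = "; "),
                           if (length(miss) > 5) " ..."))
    }
    if (nrow(dup) > 0) msg <- c(msg, paste0(nrow(dup), " duplicated cell(s)"))
    stop("incomplete power table - ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Healthy-control baseline laterality
#'
#' The arithmetic mean laterality index of the control group in each band x
#' region cell. Healthy brains show systematic lateralization, so patient
#' indices are referenced to this baseline before group comparison.
#'
#' @param li Long laterality tibble from [li_table()] including a `group`
#'   column with `CTR` subjects.
#' @return Tibble `band`, `region`, `baseline_li` (28 rows).
#' @export
ctr_baseline <- function(li) {
  if (!"group" %in% names(li)) stop("li table has no group column", call. = FALSE)
  ctr <- dplyr::filter(li, .data$group == "CTR")
  if (dplyr::n_distinct(ctr$subject_id) < 2) {
    stop("baseline requires at least 2 control subjects", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(ctr, .data$band, .data$region),
                   baseline_li = mean(.data$li), .groups = "drop")
}

#' Subtract the control baseline from laterality indices
#'
#' Entry-wise subtraction of the control-group mean laterality per band x
#' region. Corrected values lie in (-2, 2).
#'
#' @param li Long laterality tibble from [li_table()].
#' @param baseline Baseline tibble from [ctr_baseline()] (computed on a
#'   control cohort).
#' @return Tibble of the same shape with corrected `li`; attribute
#'   `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(li, baseline) {
  if (!all(c("band", "region", "baseline_li") %in% names(baseline))) {
    stop("baseline must come from ctr_baseline()", call. = FALSE)
  }
  if (nrow(baseline) != 28) {
    stop("baseline must cover all 28 band x region cells", call. = FALSE)
  }
  out <- dplyr::left_join(li, baseline, by = c("band", "region"))
  out <- dplyr::mutate(out, li = .data$li - .data$baseline_li)
  out <- dplyr::select(out, -"baseline_li")
  attr(out, "baseline_corrected") <- TRUE
  out
}

#' Laterality features as a subjects x 28 matrix
#'
#' Reshapes the long laterality table into the fixed band-major 28-column
#' feature matrix used by the classifier.
#'
#' @param li Long laterality tibble.
#' @return Numeric matrix, one row per subject (rownames = subject ids),
#'   columns in [li_feature_names()] order; attribute `groups` holds each
#'   subject's group if present.
#' @export
li_matrix <- function(li) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(li, feature = paste(.data$band, .data$region, sep = ".")),
    id_cols = "subject_id", names_from = "feature", values_from = "li"
  )
  m <- as.matrix(wide[, li_feature_names(), drop = FALSE])
  rownames(m) <- wide$subject_id
  if ("group" %in% names(li)) {
    g <- dplyr::distinct(li, .data$subject_id, .data$group)
    attr(m, "groups") <- stats::setNames(as.character(g$group), g$subject_id)[
      wide$subject_id]
  }
  m
}
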