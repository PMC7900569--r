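#' Bootstrap one-sample test of laterality against zero
#'
#' Resamples the values with replacement (default 20,000 times), computes
#' the mean of each resample, and reports the smaller of the two tail
#' proportions: the fraction of resampled means strictly above zero, or
#' strictly below zero. Resampled means exactly equal to zero count toward
#' neither tail. With all input values identically zero the statistic is
#' degenerate and the p value is defined as 0.5 (flagged via the
#' `"degenerate"` attribute).
#'
#' @param values Numeric vector (>= 2 values), e.g. one group's
#'   baseline-corrected laterality indices for one band x region.
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param two_sided Double the smaller tail (capped at 1)? Default `FALSE`,
#'   the literal smaller-tail rule.
#' @return A single p value in [0, 1].
#' @export
bootstrap_one_sample <- function(values, n_resamples = 20000, seed = 1L,
                                 two_sided = FALSE) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  if (all(values == 0)) {
    return(structure(0.5, degenerate = TRUE))
  }
  values <- sort(values)  # seeded result independent of input order
  withr_seed(seed, {
    n <- length(values)
    means <- colMeans(matrix(sample(values, n * n_resamples, replace = TRUE),
                             nrow = n))
    smaller_tail(means, two_sided)
  })
}

#' Bootstrap two-sample test of a group difference in laterality
#'
#' Per iteration, each group is resampled with replacement independently and
#' the difference of resampled group means is taken; the p value is the
#' smaller tail proportion of that difference distribution around zero
#' (strict inequalities; ties to neither tail).
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @inheritParams bootstrap_one_sample
#' @return A single p value in [0, 1].
#' @export
bootstrap_two_sample <- function(group_a, group_b, n_resamples = 20000,
                                 seed = 1L, two_sided = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  group_a <- sort(group_a); group_b <- sort(group_b)
  withr_seed(seed, {
    na <- length(group_a); nb <- length(group_b)
    ma <- colMeans(matrix(sample(group_a, na * n_resamples, replace = TRUE),
                          nrow = na))
    mb <- colMeans(matrix(sample(group_b, nb * n_resamples, replace = TRUE),
                          nrow = nb))
    smaller_tail(ma - mb, two_sided)
  })
}

smaller_tail <- function(stat, two_sided = FALSE) {
  p <- min(mean(stat > 0), mean(stat < 0))
  if (two_sided) p <- min(2 * p, 1)
  p
}

#' Benjamini-Hochberg FDR control over a family of p values
#'
#' Step-up adjusted p values via [stats::p.adjust()]; a test is significant
#' when its adjusted p value is at or below `q`.
#'
#' @param p_values Numeric vector of raw p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return Tibble: `p_raw`, `p_fdr`, `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_fdr = adj, significant = adj <= q)
}

#' Bootstrap laterality tests for every band x region cell
#'
#' For each of the 28 band x region cells, runs the bootstrap one-sample
#' test against zero within each patient group (is the baseline-corrected
#' laterality shifted away from the control reference?) and the bootstrap
#' two-sample test between the left-focus and right-focus groups. FDR is
#' controlled separately within each test family (28 tests each) by the
#' Benjamini-Hochberg step-up rule.
#'
#' @param li Baseline-corrected long laterality tibble containing the two
#'   patient groups.
#' @param n_resamples Bootstrap resamples per test.
#' @param seed Integer seed (varied deterministically across cells).
#' @param q FDR level.
#' @return Tibble: `band`, `region`, `test` (`one_sample_LtMTLE`,
#'   `one_sample_RtMTLE`, `two_sample`), `mean_li` (or mean difference),
#'   `p_raw`, `p_fdr`, `significant`.
#' @export
li_group_tests <- function(li, n_resamples = 20000, seed = 1L, q = 0.05) {
  cells <- tidyr::expand_grid(band = band_levels(), region = meg_regions())
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    b <- cells$band[i]; r <- cells$region[i]
    lt <- dplyr::filter(li, .data$band == b, .data$region == r,
                        .data$group == "LtMTLE")$li
    rt <- dplyr::filter(li, .data$band == b, .data$region == r,
                        .data$group == "RtMTLE")$li
    s <- seed + 17L * i
    tibble::tibble(
      band = b, region = r,
      test = c("one_sample_LtMTLE", "one_sample_RtMTLE", "two_sample"),
      mean_li = c(mean(lt), mean(rt), mean(lt) - mean(rt)),
      p_raw = c(
        as.numeric(bootstrap_one_sample(lt, n_resamples, seed = s)),
        as.numeric(bootstrap_one_sample(rt, n_resamples, seed = s + 1L)),
        bootstrap_two_sample(lt, rt, n_resamples, seed = s + 2L)
      )
    )
  })
  res <- dplyr::group_by(res, .data$test)
  res <- dplyr::mutate(res,
                       p_fdr = stats::p.adjust(.data$p_raw, method = "BH"),
                       significant = .data$p_fdr <= q)
  dplyr::ungroup(res)
}
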