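#' Two-way factorial ANOVA of baseline-corrected laterality
#'
#' Fits the 2 (group: left-focus vs right-focus) x 4 (region) full-factorial
#' ANOVA for one frequency band. Each subject contributes its four regional
#' laterality values, treated as independent cells of the design. Sums of
#' squares are Type III with sum-to-zero contrasts (the design is unbalanced:
#' group sizes differ), computed via [car::Anova()].
#'
#' @param li Long laterality tibble (one band) with columns `subject_id`,
#'   `group` (levels `LtMTLE`, `RtMTLE`), `region`, `li`.
#' @return A `meg_anova` object. `$effects` is a tibble with one row per
#'   effect (`group_main`, `region_main`, `interaction`): `df`, `SS`, `MS`,
#'   `F`, `p_parametric`, `degenerate`. The model frame is retained for
#'   bootstrap evaluation.
#' @seealso [bootstrap_f_pvalue()] for the pooled-bootstrap significance.
#' @export
li_anova <- function(li) {
  d <- prepare_anova_frame(li)
  n <- nrow(d)
  counts <- table(d$group, d$region)
  if (any(counts < 1)) stop("empty group x region cell", call. = FALSE)
  if (length(unique(table(d$subject_id))) > 1) {
    stop("each subject must contribute one value per region", call. = FALSE)
  }

  degenerate <- stats::var(d$li) < 1e-24
  if (degenerate) {
    effects <- tibble::tibble(
      effect = c("group_main", "region_main", "interaction"),
      df = c(1L, 3L, 3L), SS = 0, MS = 0, F = 0, p_parametric = 1,
      degenerate = TRUE
    )
  } else {
    fit <- stats::lm(li ~ group * region, data = d,
                     contrasts = list(group = "contr.sum",
                                      region = "contr.sum"))
    a <- car::Anova(fit, type = 3)
    rows <- c(group_main = "group", region_main = "region",
              interaction = "group:region")
    idx <- match(rows, rownames(a))
    effects <- tibble::tibble(
      effect = names(rows),
      df = as.integer(a$Df[idx]),
      SS = a$`Sum Sq`[idx],
      MS = a$`Sum Sq`[idx] / a$Df[idx],
      F = a$`F value`[idx],
      p_parametric = a$`Pr(>F)`[idx],
      degenerate = FALSE
    )
  }
  structure(
    list(effects = effects, frame = d,
         band = if ("band" %in% names(li)) as.character(li$band[1]) else NA),
    class = "meg_anova"
  )
}

prepare_anova_frame <- function(li) {
  needed <- c("subject_id", "group", "region", "li")
  miss <- setdiff(needed, names(li))
  if (length(miss) > 0) {
    stop("laterality table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("band" %in% names(li) && dplyr::n_distinct(li$band) > 1) {
    stop("li_anova() analyses one band at a time; filter the table first",
         call. = FALSE)
  }
  d <- dplyr::filter(li, .data$group %in% c("LtMTLE", "RtMTLE"))
  d <- dplyr::mutate(d,
                     group = factor(as.character(.data$group),
                                    levels = c("LtMTLE", "RtMTLE")),
                     region = as_region_factor(.data$region))
  if (any(table(d$group) < 2 * 4)) {
    stop("need at least 2 subjects per patient group", call. = FALSE)
  }
  # canonical row order: results (incl. seeded bootstrap) must not depend
  # on how the input table happened to be sorted
  d <- dplyr::arrange(d, .data$group, .data$region, .data$subject_id)
  as.data.frame(d)
}

#' @export
print.meg_anova <- function(x, ...) {
  cat(sprintf("2 x 4 factorial ANOVA of laterality (band: %s)\n", x$band))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.meg_anova <- function(x, ...) x$effects

#' @export
glance.meg_anova <- function(x, ...) {
  tibble::tibble(band = x$band, n_obs = nrow(x$frame),
                 n_subjects = dplyr::n_distinct(x$frame$subject_id))
}

# Type III projection matrices for the 2x4 design: for each effect,
# M_e = H(full) - H(full minus that effect's columns); F is then a pair of
# quadratic forms in y, which lets the pooled bootstrap evaluate thousands
# of resampled response vectors with three matrix products.
anova_projectors <- function(frame) {
  X <- stats::model.matrix(~ group * region, data = frame,
                           contrasts.arg = list(group = "contr.sum",
                                                region = "contr.sum"))
  asgn <- attr(X, "assign")  # 0 intercept, 1 group, 2 region, 3 interaction
  hat_of <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    Xs %*% solve(crossprod(Xs), t(Xs))
  }
  H_full <- hat_of(seq_len(ncol(X)))
  n <- nrow(X)
  M_res <- diag(n) - H_full
  eff <- list(group_main = 1L, region_main = 2L, interaction = 3L)
  proj <- lapply(eff, function(a) {
    H_red <- hat_of(which(asgn != a))
    list(M = H_full - H_red, df = sum(asgn == a))
  })
  list(proj = proj, M_res = M_res, df_res = n - ncol(X))
}

# F statistics for response matrix Y (n x B) under precomputed projectors.
anova_f_many <- function(pr, Y) {
  ss_res <- colSums(Y * (pr$M_res %*% Y))
  out <- sapply(names(pr$proj), function(e) {
    p <- pr$proj[[e]]
    ss <- colSums(Y * (p$M %*% Y))
    (ss / p$df) / (ss_res / pr$df_res)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(pr$proj)))
  out
}

#' Pooled-bootstrap significance of the factorial ANOVA F statistics
#'
#' Evaluates the observed F statistics against a pooled bootstrap null: all
#' observations are resampled with replacement regardless of group and
#' region (default 20,000 resamples), redealt into the original design
#' cells, and the F statistics recomputed. The significance level is the
#' smaller of the two tail proportions (fraction of resampled F strictly
#' above, or strictly below, the observed F); ties count toward neither
#' tail. The smaller-tail rule follows the source procedure literally and is
#' not doubled; set `two_sided = TRUE` to double it.
#'
#' @param anova A `meg_anova` from [li_anova()].
#' @param n_resamples Number of bootstrap resamples (default 20,000).
#' @param seed Integer seed.
#' @param two_sided Double the smaller tail (capped at 1)? Default `FALSE`.
#' @return The `meg_anova` with a `p_boot` column added to `$effects`.
#' @export
bootstrap_f_pvalue <- function(anova, n_resamples = 20000, seed = 1L,
                               two_sided = FALSE) {
  stopifnot(inherits(anova, "meg_anova"))
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  if (any(anova$effects$degenerate)) {
    anova$effects$p_boot <- 1
    return(anova)
  }
  pr <- anova_projectors(anova$frame)
  y <- anova$frame$li
  n <- length(y)
  f_orig <- stats::setNames(anova$effects$F, anova$effects$effect)

  withr_seed(seed, {
    p_boot <- stats::setNames(numeric(3), names(f_orig))
    upper <- lower <- stats::setNames(numeric(3), names(f_orig))
    B <- n_resamples
    chunk <- 2000L
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      Y <- matrix(sample(y, n * b, replace = TRUE), nrow = n)
      Fb <- anova_f_many(pr, Y)
      for (e in names(f_orig)) {
        upper[e] <- upper[e] + sum(Fb[, e] > f_orig[e])
        lower[e] <- lower[e] + sum(Fb[, e] < f_orig[e])
      }
      done <- done + b
    }
    p_boot <- pmin(upper, lower) / B
    if (two_sided) p_boot <- pmin(2 * p_boot, 1)
    anova$effects$p_boot <- unname(p_boot[anova$effects$effect])
    anova
  })
}

#' Factorial-ANOVA summary across all seven bands
#'
#' Runs [li_anova()] and [bootstrap_f_pvalue()] band by band and stacks the
#' results into one table shaped like a published ANOVA summary: one row per
#' band x effect with `F`, `MS`, `p` (parametric) and `p_boot`.
#'
#' @param li Baseline-corrected long laterality tibble for the two patient
#'   groups (all bands).
#' @param n_resamples Bootstrap resamples per band.
#' @param seed Integer seed (incremented per band).
#' @return Tibble: `band`, `effect`, `df`, `F`, `MS`, `p`, `p_boot`.
#' @export
li_anova_table <- function(li, n_resamples = 20000, seed = 1L) {
  purrr::map_dfr(band_levels(), function(b) {
    sub <- dplyr::filter(li, .data$band == b)
    a <- li_anova(sub)
    a <- bootstrap_f_pvalue(a, n_resamples = n_resamples,
                            seed = seed + match(b, band_levels()))
    tibble::tibble(band = b, effect = a$effects$effect, df = a$effects$df,
                   F = a$effects$F, MS = a$effects$MS,
                   p = a$effects$p_parametric, p_boot = a$effects$p_boot)
  })
}
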