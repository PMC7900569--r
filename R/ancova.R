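#' Mass-univariate group contrast of source power with an age covariate
#'
#' For every source location, tests the group effect on oscillatory power
#' after regressing out age (age as a nuisance covariate), using the extra
#' sum-of-squares F statistic of `power ~ age + group` against
#' `power ~ age`. Family-wise error across sources is controlled by
#' max-statistic permutation: group labels are permuted (ages stay attached
#' to their subjects), the maximum F over sources is recorded per
#' permutation, and each source's corrected p value is the fraction of
#' permutation maxima at or above its observed F.
#'
#' @param images Subjects x sources matrix of source power for one band
#'   (rows aligned with `groups`/`ages`).
#' @param groups Factor/character of group membership per subject; exactly
#'   the two groups named in `contrast` are used.
#' @param ages Numeric ages per subject.
#' @param contrast Length-2 character, the pair of groups to compare
#'   (e.g. `c("LtMTLE", "CTR")`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Family-wise significance level.
#' @return Tibble: `source`, `F`, `p_fwe`, `significant`, plus attributes
#'   `contrast` and `n_perm`.
#' @export
mass_univariate_ancova <- function(images, groups, ages,
                                   contrast = c("LtMTLE", "CTR"),
                                   n_perm = 1000, seed = 1L, alpha = 0.05) {
  stopifnot(is.matrix(images), length(groups) == nrow(images),
            length(ages) == nrow(images), length(contrast) == 2)
  keep <- as.character(groups) %in% contrast
  Y <- images[keep, , drop = FALSE]
  g <- factor(as.character(groups)[keep], levels = contrast)
  a <- ages[keep]
  if (any(table(g) < 2)) {
    stop("need at least 2 subjects per group in the contrast", call. = FALSE)
  }
  n <- nrow(Y)
  f_of <- function(g_perm) {
    X1 <- stats::model.matrix(~ a + g_perm)
    if (qr(X1)$rank < ncol(X1)) stop("rank-deficient design", call. = FALSE)
    X0 <- stats::model.matrix(~ a)
    H1 <- X1 %*% solve(crossprod(X1), t(X1))
    H0 <- X0 %*% solve(crossprod(X0), t(X0))
    rss1 <- colSums(Y * ((diag(n) - H1) %*% Y))
    ss_g <- colSums(Y * ((H1 - H0) %*% Y))
    df1 <- n - ncol(X1)
    (ss_g / 1) / (rss1 / df1)
  }
  f_obs <- f_of(g)
  withr_seed(seed, {
    max_f <- vapply(seq_len(n_perm), function(b) max(f_of(sample(g))),
                    numeric(1))
    p_fwe <- vapply(f_obs, function(f) mean(max_f >= f), numeric(1))
    out <- tibble::tibble(source = seq_len(ncol(Y)), F = f_obs,
                          p_fwe = p_fwe, significant = p_fwe <= alpha)
    attr(out, "contrast") <- contrast
    attr(out, "n_perm") <- n_perm
    out
  })
}
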