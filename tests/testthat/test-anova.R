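# balanced 2x4 cell-means oracle: classic sums-of-squares decomposition
balanced_ss_oracle <- function(d) {
  r <- nrow(d) / 8
  g <- mean(d$li)
  mi <- tapply(d$li, d$group, mean)
  mj <- tapply(d$li, d$region, mean)
  mij <- tapply(d$li, list(d$group, d$region), mean)
  ss_a <- 4 * r * sum((mi - g)^2)
  ss_b <- 2 * r * sum((mj - g)^2)
  inter <- outer(mi - g, mj - g, "+") + g
  ss_ab <- r * sum((mij - inter)^2)
  ss_e <- sum((d$li - mij[cbind(as.character(d$group),
                                as.character(d$region))])^2)
  list(F_group = (ss_a / 1) / (ss_e / (nrow(d) - 8)),
       F_region = (ss_b / 3) / (ss_e / (nrow(d) - 8)),
       F_inter = (ss_ab / 3) / (ss_e / (nrow(d) - 8)),
       MS_group = ss_a, MS_region = ss_b / 3, MS_inter = ss_ab / 3)
}

toy_li <- function(n_per_group = 6, shift = 0.4, seed = 31,
                   interaction = 0) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(2 * n_per_group),
                      region = meg_regions())
  grid$group <- ifelse(grid$subject <= n_per_group, "LtMTLE", "RtMTLE")
  tibble::tibble(
    subject_id = sprintf("P%02d", grid$subject),
    group = grid$group, region = grid$region,
    li = rnorm(nrow(grid), sd = 0.2) +
      ifelse(grid$group == "LtMTLE", shift, 0) +
      ifelse(grid$group == "LtMTLE" & grid$region == "temporal",
             interaction, 0)
  )
}

test_that("balanced additive designs match the textbook SS decomposition", {
  d <- toy_li(shift = 0.5, interaction = 0)
  a <- li_anova(d)
  o <- balanced_ss_oracle(prepare_frame <- meglaterality:::prepare_anova_frame(d))
  eff <- a$effects
  expect_equal(eff$F[eff$effect == "group_main"], o$F_group, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "region_main"], o$F_region,
               tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "interaction"], o$F_inter,
               tolerance = 1e-10)
  expect_equal(eff$MS[eff$effect == "group_main"], o$MS_group,
               tolerance = 1e-10)
  # additive truth: interaction F below the group main effect F
  expect_lt(eff$F[eff$effect == "interaction"],
            eff$F[eff$effect == "group_main"])
})

test_that("constant data give F = 0 with the degenerate flag", {
  d <- toy_li(shift = 0)
  d$li <- 0.7
  a <- li_anova(d)
  expect_true(all(a$effects$degenerate))
  expect_equal(a$effects$F, rep(0, 3))
  ab <- bootstrap_f_pvalue(a, 100, seed = 1)
  expect_equal(ab$effects$p_boot, rep(1, 3))
})

test_that("the bootstrap projector F path reproduces car's Type III F", {
  d <- toy_li(n_per_group = 5, shift = 0.3, interaction = 0.4, seed = 33)
  # make it unbalanced: drop one subject
  d <- d[d$subject_id != "P01", ]
  a <- li_anova(d)
  pr <- meglaterality:::anova_projectors(a$frame)
  f_fast <- meglaterality:::anova_f_many(pr, matrix(a$frame$li, ncol = 1))
  expect_equal(as.numeric(f_fast[1, a$effects$effect]), a$effects$F,
               tolerance = 1e-10)
})

test_that("null group labels leave F unexceptional under permutation", {
  d <- toy_li(shift = 0, seed = 35)
  a <- li_anova(d)
  f_obs <- a$effects$F[a$effects$effect == "group_main"]
  set.seed(36)
  subs <- unique(d$subject_id)
  f_perm <- replicate(200, {
    perm <- setNames(sample(d$group[match(subs, d$subject_id)]), subs)
    d2 <- d; d2$group <- perm[d$subject_id]
    eff <- li_anova(d2)$effects
    eff$F[eff$effect == "group_main"]
  })
  p_perm <- mean(f_perm >= f_obs)
  expect_gt(p_perm, 0.01)
})

test_that("pooled-bootstrap p values behave at the extremes", {
  strong <- toy_li(shift = 3, seed = 37)
  a <- bootstrap_f_pvalue(li_anova(strong), 2000, seed = 2)
  expect_lt(a$effects$p_boot[a$effects$effect == "group_main"], 0.001)
  # several seeds: a strong synthetic effect is always detected
  eff <- matrix(0, 7, 4); eff[2, ] <- 1.0
  ps <- vapply(1:5, function(s) {
    co <- simulate_power_cohort(
      synth_config(n_ctr = 2, n_lt = 16, n_rt = 19, effect_delta = eff,
                   seed = 40 + s))
    li <- dplyr::filter(li_table(co), group != "CTR", band == "theta")
    ab <- bootstrap_f_pvalue(li_anova(li), 2000, seed = s)
    ab$effects$p_boot[ab$effects$effect == "group_main"]
  }, numeric(1))
  expect_true(all(ps < 0.001))
})

test_that("bootstrap p values are order-invariant and seed-reproducible", {
  d <- toy_li(shift = 0.3, seed = 39)
  a1 <- bootstrap_f_pvalue(li_anova(d), 500, seed = 7)
  a2 <- bootstrap_f_pvalue(li_anova(d[sample(nrow(d)), ]), 500, seed = 7)
  expect_equal(a1$effects$p_boot, a2$effects$p_boot)
})

test_that("guard rails: band mixing and tiny groups are refused", {
  co <- small_cohort(seed = 41)
  li <- dplyr::filter(li_table(co), group != "CTR")
  expect_error(li_anova(li), "one band")
  one_band <- dplyr::filter(li, band == "theta")
  tiny <- dplyr::filter(one_band,
                        !(group == "LtMTLE" &
                            subject_id != one_band$subject_id[1]))
  expect_error(li_anova(tiny), "at least 2 subjects")
})
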