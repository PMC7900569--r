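test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- synth_config(n_ctr = 5, n_lt = 3, n_rt = 3, seed = 7)
  a <- simulate_power_cohort(cfg)
  b <- simulate_power_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_power_cohort(synth_config(n_ctr = 5, n_lt = 3, n_rt = 3,
                                           seed = 8))
  expect_false(identical(a$power, c2$power))
})

test_that("cohorts have the right shape and strictly positive powers", {
  co <- small_cohort()
  expect_equal(nrow(co), (12 + 6 + 6) * 56)
  expect_true(all(co$power > 0))
  expect_equal(unname(table(co$group)[c("CTR", "LtMTLE", "RtMTLE")]) / 56,
               c(12, 6, 6), ignore_attr = TRUE)
  per_subj <- table(co$subject_id)
  expect_true(all(per_subj == 56))
  ages <- unique(co[, c("subject_id", "age")])$age
  expect_true(all(ages >= 8 & ages <= 75))
})

test_that("noise-free zero-effect limit reproduces the baseline laterality", {
  cfg <- synth_config(n_ctr = 3, n_lt = 2, n_rt = 2, effect_delta = 0,
                      baseline_li_mean = 0.1, noise_cv = 1e-9, seed = 2)
  li <- li_table(simulate_power_cohort(cfg))
  expect_equal(li$li, rep(0.1, nrow(li)), tolerance = 1e-6)
})

test_that("mean laterality shift matches the generator's closed-form expectation", {
  delta <- 0.5
  cv <- 0.3
  eff <- matrix(0, 7, 4); eff[2, 2] <- delta  # theta x temporal
  n <- 4000
  cfg <- synth_config(n_ctr = n, n_lt = n, n_rt = 2, baseline_li_mean = 0,
                      effect_delta = eff, noise_cv = cv, seed = 42)
  co <- simulate_power_cohort(cfg)
  lt <- cell_li_oracle(co, "theta", "temporal", "LtMTLE")
  ctr <- cell_li_oracle(co, "theta", "temporal", "CTR")
  observed <- mean(lt) - mean(ctr)

  # Exact expectation under the generator's law: LI = tanh((delta + s Z)/2),
  # s = sqrt(2) * sigma_log, by numerical quadrature (CTR term is 0 by
  # symmetry).
  sigma <- sqrt(log(1 + cv^2))
  s <- sqrt(2) * sigma
  expected <- stats::integrate(
    function(z) tanh((delta + s * z) / 2) * stats::dnorm(z),
    -8, 8
  )$value
  mc_se <- sqrt(stats::var(lt) / n + stats::var(ctr) / n)
  expect_lt(abs(observed - expected), 3 * mc_se)
  # and the quadrature value itself sits near the noise-free closed form
  expect_equal(expected, (exp(delta) - 1) / (exp(delta) + 1), tolerance = 0.05)
})

test_that("with zero effect the two patient groups are exchangeable (null fidelity)", {
  # >= 500 replicate null cohorts at reduced bootstrap reps; iid subjects,
  # so one large generation split into replicates is distribution-identical.
  reps <- 500
  n_lt <- 16; n_rt <- 19   # the cohort sizes the analysis targets
  cfg <- synth_config(n_ctr = 2, n_lt = n_lt * reps, n_rt = n_rt * reps,
                      effect_delta = 0, seed = 77)
  co <- simulate_power_cohort(cfg)
  lt <- cell_li_oracle(co, "alpha", "parietal", "LtMTLE")
  rt <- cell_li_oracle(co, "alpha", "parietal", "RtMTLE")
  rej <- vapply(seq_len(reps), function(r) {
    a <- lt[((r - 1) * n_lt + 1):(r * n_lt)]
    b <- rt[((r - 1) * n_rt + 1):(r * n_rt)]
    bootstrap_two_sample(a, b, n_resamples = 300, seed = r) < 0.025
  }, logical(1))
  # smaller-tail rule at threshold 0.025 ~ two-sided 0.05
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("group-mean laterality difference grows monotonically with effect size", {
  deltas <- c(0, 0.25, 0.5, 1)
  n <- 1500
  means <- vapply(seq_along(deltas), function(i) {
    eff <- matrix(0, 7, 4); eff[2, 2] <- deltas[i]
    co <- simulate_power_cohort(
      synth_config(n_ctr = 2, n_lt = n, n_rt = 2, baseline_li_mean = 0,
                   effect_delta = eff, seed = 100 + i))
    mean(cell_li_oracle(co, "theta", "temporal", "LtMTLE"))
  }, numeric(1))
  # consecutive means separated by > -3 SE (non-decreasing up to MC noise)
  se <- 0.2 / sqrt(n)
  expect_true(all(diff(means) > -3 * sqrt(2) * se))
  expect_gt(means[4], means[1])
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_ctr = 1), "group sizes")
  expect_error(synth_config(noise_cv = 0), "noise_cv")
  expect_error(synth_config(effect_delta = -0.1), "effect_delta")
  expect_error(synth_config(baseline_li_mean = 1), "baseline_li_mean")
  expect_error(synth_config(effect_delta = matrix(0, 3, 4)), "7 x 4")
  expect_error(synth_config(age_range = c(50, 10)), "age_range")
})
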