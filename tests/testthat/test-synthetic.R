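# analytic-mode spec used across recovery tests: deterministic timings,
# realistic survival and fecundity
analytic_spec <- function(fecundity = 40) {
  treatment_spec("analytic", n = 50,
                 death_prob = c(0.05, 0.02, 0, 0.03),
                 duration_mean = c(8, 3, 2, 3), duration_jitter = 0,
                 p_female = 0.8, apop_mean = 2,
                 ovi_peak_day = 6, ovi_window = 20, fecundity = fecundity,
                 longevity_female = c(17, 0), longevity_male = c(14, 0))
}

test_that("a fixed seed reproduces the cohort bit-for-bit", {
  a <- generate_cohort(preset_spec("control"), seed = 123)
  b <- generate_cohort(preset_spec("control"), seed = 123)
  expect_identical(a, b)
  c2 <- generate_cohort(preset_spec("control"), seed = 124)
  expect_false(identical(a, c2))
})

test_that("a deathless deterministic spec produces identical development", {
  spec <- treatment_spec("det", n = 20,
                         death_prob = c(0, 0, 0, 0),
                         duration_mean = c(8, 3, 2, 3), duration_jitter = 0,
                         p_female = 1, apop_mean = 1,
                         ovi_peak_day = 3, ovi_window = 10, fecundity = 20,
                         longevity_female = c(12, 0),
                         longevity_male = c(10, 0))
  co <- generate_cohort(spec, seed = 1)
  expect_true(all(co$entry[, "adult"] == 16))
  expect_true(all(co$records$sex == "F"))
  expect_true(all(co$records$death_age == 28))
})

test_that("generated cohorts converge to the preset targets at large n", {
  targets <- list(control = c(mort = 0.06, sexratio = (47 / 50) * (41 / 47),
                              fec = 49.93),
                  paw1 = c(mort = 0.42, sexratio = (29 / 50) * (21 / 29),
                           fec = 37.14),
                  paw2 = c(mort = 0.26, sexratio = (37 / 50) * (25 / 37),
                           fec = 32.52))
  for (p in names(targets)) {
    co <- generate_cohort(preset_spec(p), seed = match(p, names(targets)),
                          n = 5000)
    tg <- targets[[p]]
    r <- co$records
    expect_equal(stage_summaries(co)$immature_mortality, tg[["mort"]],
                 tolerance = 0.12)
    expect_equal(sum(r$sex == "F") / co$n01, tg[["sexratio"]],
                 tolerance = 0.05)
    fem <- r$sex == "F"
    expect_equal(mean(rowSums(co$eggs)[fem]), tg[["fec"]], tolerance = 0.03)
  }
})

test_that("analytic expected schedules obey closed-form survival", {
  # no mortality: l_x = 1 up to the fixed female death age
  spec0 <- treatment_spec("nodeath", n = 10,
                          death_prob = c(0, 0, 0, 0),
                          duration_mean = c(8, 3, 2, 3), duration_jitter = 0,
                          p_female = 1, apop_mean = 1,
                          ovi_peak_day = 3, ovi_window = 10, fecundity = 20,
                          longevity_female = c(12, 0),
                          longevity_male = c(10, 0))
  es <- expected_schedules(spec0)
  expect_equal(unname(es$l_x), c(rep(1, 28), 0))
  # egg-stage mortality p scales every post-egg survival by (1 - p)
  spec_p <- treatment_spec("eggdeath", n = 10,
                           death_prob = c(0.2, 0, 0, 0),
                           duration_mean = c(8, 3, 2, 3), duration_jitter = 0,
                           p_female = 1, apop_mean = 1,
                           ovi_peak_day = 3, ovi_window = 10, fecundity = 20,
                           longevity_female = c(12, 0),
                           longevity_male = c(10, 0))
  esp <- expected_schedules(spec_p)
  post_egg <- 9:28
  expect_equal(unname(esp$l_x[post_egg]), rep(0.8, length(post_egg)))
  # net maternity integrates to P(adult) * P(female) * fecundity
  expect_equal(sum(esp$l_x * esp$m_x), expected_r0(spec_p))
})

test_that("expected_schedules refuses non-deterministic specs", {
  expect_error(expected_schedules(preset_spec("control")), "analytic mode")
})

test_that("generated cohorts recover the analytic intrinsic rate", {
  spec <- analytic_spec()
  r_expected <- solve_intrinsic_rate(expected_schedules(spec))$r
  for (seed in 1:5) {
    co <- generate_cohort(spec, seed = seed, n = 500)
    r_emp <- solve_intrinsic_rate(compute_schedules(co))$r
    expect_lt(abs(r_emp - r_expected), 0.015)
  }
})

test_that("preset R0 on large cohorts matches the closed form within 2 percent", {
  # a single n = 5000 cohort has relative Monte-Carlo SE of R0 up to ~1.8%
  # (sd of lifetime eggs ~ 20), so the 2% criterion is applied to the mean
  # over ten seeds (relative SE ~ 0.55%, making 2% a > 3.5-sigma bound)
  for (p in c("control", "paw1", "paw2")) {
    spec <- preset_spec(p)
    r0_emp <- mean(vapply(1:10, function(s)
      net_reproductive_rate(compute_schedules(
        generate_cohort(spec, seed = s, n = 5000))), numeric(1)))
    expect_equal(r0_emp, expected_r0(spec), tolerance = 0.02)
  }
})

test_that("invalid specs are rejected at construction", {
  expect_error(treatment_spec("bad", death_prob = c(2, 0, 0, 0),
                              duration_mean = c(8, 3, 2, 3),
                              p_female = 0.8, apop_mean = 2,
                              ovi_peak_day = 3, ovi_window = 10,
                              fecundity = 10,
                              longevity_female = c(10, 1),
                              longevity_male = c(8, 1)))
  expect_error(treatment_spec("bad", death_prob = c(0, 0, 0, 0),
                              duration_mean = c(0.5, 3, 2, 3),
                              p_female = 0.8, apop_mean = 2,
                              ovi_peak_day = 3, ovi_window = 10,
                              fecundity = 10,
                              longevity_female = c(10, 1),
                              longevity_male = c(8, 1)))
})
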