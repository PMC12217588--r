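test_that("resampling identical individuals yields zero SE everywhere", {
  co <- mk_cohort(lapply(1:8, function(i) mk_female(paste0("f", i))))
  b <- bootstrap_cohort(co, B = 50, seed = 1)
  expect_true(all(b$se == 0))
  # every parameter defined for an all-female cohort is valid in all replicates;
  # male_longevity is never defined here and is reported with zero valid draws
  defined <- b$parameter != "male_longevity"
  expect_true(all(b$B_valid[defined] == 50))
  expect_equal(b$B_valid[!defined], 0L)
  expect_true(all(b$degenerate == !defined))
})

test_that("a single replicate is degenerate with SE 0 by convention", {
  co <- generate_cohort(preset_spec("control"), seed = 2)
  b <- bootstrap_cohort(co, B = 1, seed = 1, parameters = c("R0", "r"))
  expect_true(all(b$se == 0))
  expect_true(all(b$degenerate))
})

test_that("bootstrap results are bit-reproducible under a fixed seed", {
  co <- generate_cohort(preset_spec("paw2"), seed = 5)
  b1 <- bootstrap_cohort(co, B = 300, seed = 77)
  b2 <- bootstrap_cohort(co, B = 300, seed = 77)
  expect_identical(b1, b2)
  t1 <- paired_bootstrap_test(co, co, "R0", B = 200, seed = 3)
  t2 <- paired_bootstrap_test(co, co, "R0", B = 200, seed = 3)
  expect_identical(t1, t2)
})

test_that("point estimates from the resampling path equal the schedule pipeline", {
  co <- generate_cohort(preset_spec("control"), seed = 4)
  b <- bootstrap_cohort(co, B = 2, seed = 1)
  sch <- compute_schedules(co)
  fit <- solve_intrinsic_rate(sch)
  est <- function(p) b$estimate[b$parameter == p]
  expect_equal(est("R0"), net_reproductive_rate(sch))
  expect_equal(est("r"), fit$r, tolerance = 1e-9)
  expect_equal(est("lambda"), fit$lambda, tolerance = 1e-9)
  expect_equal(est("T"), fit$T, tolerance = 1e-8)
  rs <- reproductive_summary(co)$table
  expect_equal(est("fecundity"), rs$mean[rs$statistic == "fecundity"])
  expect_equal(est("APOP"), rs$mean[rs$statistic == "APOP"])
  expect_equal(est("sex_ratio"), rs$mean[rs$statistic == "sex_ratio"])
  expect_equal(est("immature_mortality"),
               stage_summaries(co)$immature_mortality)
})

test_that("the paired test keeps the null and detects a gross difference", {
  co <- generate_cohort(preset_spec("control"), seed = 10)
  nul <- paired_bootstrap_test(co, co, "fecundity", B = 1000, seed = 1)
  expect_false(nul$significant)
  expect_true(nul$ci_lo <= 0 && nul$ci_hi >= 0)
  # same demographic structure but ten-fold fecundity difference
  base <- preset_spec("control")
  lo <- treatment_spec("lowfec", n = 50,
                       death_prob = base$death_prob,
                       duration_mean = base$duration_mean,
                       p_female = base$p_female, apop_mean = base$apop_mean,
                       ovi_peak_day = base$ovi_peak_day,
                       ovi_window = base$ovi_window, fecundity = 5,
                       longevity_female = base$longevity_female,
                       longevity_male = base$longevity_male)
  a <- generate_cohort(base, seed = 21)
  b <- generate_cohort(lo, seed = 22)
  pw <- paired_bootstrap_test(a, b, "fecundity", B = 1000, seed = 2)
  expect_true(pw$significant)
  expect_gt(pw$difference, 0)
})

test_that("control-like and PAW1-like cohorts separate in r", {
  a <- generate_cohort(preset_spec("control"), seed = 31)
  b <- generate_cohort(preset_spec("paw1"), seed = 32)
  pw <- paired_bootstrap_test(a, b, "r", B = 1500, seed = 5)
  expect_true(pw$significant)
  expect_gt(pw$difference, 0)
})

test_that("the bootstrap SE stabilises as B grows", {
  co <- generate_cohort(preset_spec("control"), seed = 6)
  se1 <- bootstrap_cohort(co, B = 3000, seed = 1, parameters = "R0")$se
  se2 <- bootstrap_cohort(co, B = 12000, seed = 2, parameters = "R0")$se
  expect_lt(abs(se1 - se2) / se2, 0.1)
})

test_that("replicates without females are dropped for female-conditional parameters only", {
  # one female among many males: some resamples draw no female
  inds <- c(list(mk_female("f1", total_eggs = 30)),
            lapply(1:9, function(i)
              mk_ind(paste0("m", i), "M", c(0, 8, 11, 13, 16), 30)))
  co <- mk_cohort(inds)
  b <- bootstrap_cohort(co, B = 500, seed = 8,
                        parameters = c("R0", "fecundity", "APOP"))
  bv <- function(p) b$B_valid[b$parameter == p]
  expect_equal(bv("R0"), 500)            # R0 = 0 is a defined outcome
  expect_lt(bv("fecundity"), 500)        # no-female replicates dropped
  expect_equal(bv("fecundity"), bv("APOP"))
})
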