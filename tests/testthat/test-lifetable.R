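test_that("schedules for tiny hand-checked cohorts are exact", {
  # one individual, alive 3 days as an egg
  co <- mk_cohort(list(mk_ind("a", "N", c(0), 3)))
  sch <- compute_schedules(co)
  expect_equal(sch$l_x, c("0" = 1, "1" = 1, "2" = 1, "3" = 0),
               ignore_attr = TRUE)
  expect_true(all(sch$m_x == 0))
  # two individuals, one dies at age 1
  co2 <- mk_cohort(list(mk_ind("a", "N", c(0), 1), mk_ind("b", "N", c(0), 4)))
  sch2 <- compute_schedules(co2)
  expect_equal(unname(sch2$l_x[2]), 0.5)
})

test_that("schedule computation matches the per-day census oracle exactly", {
  for (p in c("control", "paw1", "paw2")) {
    co <- generate_cohort(preset_spec(p), seed = match(p, c("control", "paw1", "paw2")))
    sch <- compute_schedules(co)
    orc <- oracle_schedules(co)
    expect_equal(unname(sch$s_xj), orc$s_xj)
    expect_equal(unname(sch$f_xj), orc$f_xj)
    expect_equal(unname(sch$l_x), orc$l_x)
    expect_equal(unname(sch$m_x), orc$m_x)
    expect_equal(unname(sch$E_xj), orc$E_xj)
  }
})

test_that("eggs are conserved and survival never increases", {
  for (seed in 1:5) {
    co <- generate_cohort(preset_spec("control"), seed = seed)
    sch <- compute_schedules(co)
    total_eggs <- sum(co$eggs[!co$records$excluded, ])
    expect_equal(sum(sch$l_x * sch$m_x), total_eggs / co$n01)
    expect_true(all(diff(sch$l_x) <= 1e-12))
    expect_true(all(sch$s_xj >= 0 & sch$s_xj <= 1))
    expect_equal(unname(sch$s_xj[1, ]), c(1, 0, 0, 0, 0, 0))
  }
})

test_that("count-matched control cohort reaches the published female plateau", {
  sch <- compute_schedules(reference_cohort("control"))
  expect_equal(max(sch$s_xj[, "adult_female"]), 0.82)
})

test_that("reproductive summary arithmetic on a single female is exact", {
  co <- mk_cohort(list(mk_female("f1", total_eggs = 32, death = 33)))
  rs <- reproductive_summary(co)
  tab <- rs$table
  get <- function(s) tab$mean[tab$statistic == s]
  expect_equal(get("APOP"), 1)
  expect_equal(get("TPOP"), 17)
  expect_equal(get("female_longevity"), 17)
  expect_equal(get("fecundity"), 32)
  expect_equal(get("oviposition_days"), 16)
})

test_that("both sex-ratio definitions are reported", {
  rs <- reproductive_summary(reference_cohort("control"))
  tab <- rs$table
  expect_equal(tab$mean[tab$statistic == "sex_ratio"], 41 / 50)
  expect_equal(tab$mean[tab$statistic == "sex_ratio_adults"], 41 / 47)
})

test_that("fecundity mean times female count recovers total cohort eggs", {
  for (p in c("control", "paw1", "paw2")) {
    co <- generate_cohort(preset_spec(p), seed = 8)
    rs <- reproductive_summary(co)
    tab <- rs$table
    nF <- sum(co$records$sex == "F" & !co$records$excluded)
    expect_equal(tab$mean[tab$statistic == "fecundity"] * nF, rs$total_eggs)
  }
})

test_that("cohorts without reproducing females flag statistics as undefined", {
  co <- mk_cohort(list(mk_ind("m1", "M", c(0, 8, 11, 13, 16), 30),
                       mk_ind("m2", "M", c(0, 8, 11, 13, 16), 25)))
  rs <- reproductive_summary(co)
  expect_true(all(c("APOP", "TPOP", "fecundity") %in% rs$undefined))
  tab <- rs$table
  expect_true(is.na(tab$mean[tab$statistic == "fecundity"]))
  expect_false(isTRUE(tab$mean[tab$statistic == "fecundity"] == 0))
})
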