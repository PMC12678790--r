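test_that("relative differences follow the formula, clamp and reject zeros", {
  expect_equal(relative_difference(0.5, 0.5), 0)
  expect_equal(relative_difference(0.4, 0.5), 25)
  expect_warning(d <- relative_difference(0.2, 0.5), "clamp")
  expect_equal(d, 100)
  expect_warning(d0 <- relative_difference(0, 0.5), "undefined")
  expect_true(is.na(d0))
})

test_that("difference classification uses a strict threshold boundary", {
  expect_equal(classify_difference(4, 5), "low_difference")
  expect_equal(classify_difference(-20, 5), "high_difference")
  expect_equal(classify_difference(5, 5), "high_difference")  # |d| == t
  expect_equal(classify_difference(-5, 5), "high_difference")
  expect_warning(classify_difference(1, 20), "range")
})

test_that("KM and log-rank match the hand-rolled oracles exactly", {
  fx <- survival_fixture()
  sf <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
  km <- oracle_km(fx$time, fx$event)
  at_events <- summary(sf, times = km$time)
  expect_equal(at_events$surv, km$surv, tolerance = 1e-12)

  sd <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ fx$group)
  expect_equal(unname(sd$chisq), oracle_logrank(fx$time, fx$event, fx$group),
               tolerance = 1e-12)
})

test_that("single-site stratification orients HR and honours symmetry", {
  rec <- suppressWarnings(simulate_prognosis_cohort(
    prognosis_config(n_sites = 1, risk_min_sites = 1, p_shallow = 0.4,
                     planted_hr = 6, censor_rate = 0.3, seed = 33)))
  st <- single_site_stratify(rec, "site01", threshold = 5)
  expect_gt(st$hr, 1)  # low-difference (shallow-like) patients do worse
  expect_lt(st$logrank_p, 0.05)
  # swapping the risk orientation inverts the hazard ratio
  rec_sw <- rec
  # make every low-difference site high-difference and vice versa
  d <- relative_difference(rec$tumor_meth, rec$adjacent_meth)
  low <- abs(d) < 5
  rec_sw$adjacent_meth[low] <- rec$tumor_meth[low] * 1.3
  rec_sw$adjacent_meth[!low] <- rec$tumor_meth[!low]
  st_sw <- single_site_stratify(rec_sw, "site01", threshold = 5)
  expect_equal(st_sw$hr, 1 / st$hr, tolerance = 1e-8)
  # extreme separation: all early events in one group
  rec2 <- data.frame(patient = sprintf("q%02d", 1:20), site = "s",
                     tumor_meth = rep(c(0.5, 0.5), 10),
                     adjacent_meth = rep(c(0.5, 0.8), 10),
                     time = rep(c(1, 50), 10),
                     event = rep(c(TRUE, FALSE), 10))
  st2 <- suppressWarnings(single_site_stratify(rec2, "s"))
  expect_gt(st2$hr, 100)
  expect_lt(st2$logrank_p, 1e-4)
  # a degenerate single-group split is reported, not an error
  rec3 <- rec2
  rec3$adjacent_meth <- rec3$tumor_meth
  st3 <- single_site_stratify(rec3, "s")
  expect_true(is.na(st3$hr))
})

test_that("threshold sweep grows the low group and attenuates planted HRs", {
  rec <- suppressWarnings(simulate_prognosis_cohort(prognosis_config(seed = 10)))
  sw <- suppressWarnings(threshold_sweep(rec, thresholds = 3:15))
  for (s in unique(sw$site)) {
    expect_true(!is.unsorted(sw$n_low[sw$site == s]))
  }
  expect_true(all(sw$n_low + sw$n_high == 59))
})

test_that("combined model counts sites, is monotone in N and flags gaps", {
  rec <- suppressWarnings(simulate_prognosis_cohort(prognosis_config(seed = 12)))
  sites <- unique(rec$site)
  # patient shallow at 3 of the sites with N = 2 is high-risk
  truth <- attr(rec, "truth")
  cm2 <- suppressWarnings(combined_model(rec, sites, N = 2))
  m <- merge(cm2$risk, truth, by = "patient")
  expect_equal(m$n_low, m$n_shallow_sites)
  expect_identical(m$high_risk.x, m$n_shallow_sites >= 2)
  # high-risk set shrinks as N grows
  sizes <- vapply(1:3, function(N) {
    sum(suppressWarnings(combined_model(rec, sites, N = N))$risk$high_risk)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # missing sites are flagged and counted over what is available
  rec_gap <- rec[!(rec$patient == "PT01" & rec$site == "site01"), ]
  expect_warning(cmg <- combined_model(rec_gap, sites, N = 2), "missing sites")
  expect_true(cmg$risk$incomplete[cmg$risk$patient == "PT01"])
})

test_that("stage crosstab margins and association behave", {
  rec <- suppressWarnings(simulate_prognosis_cohort(prognosis_config(seed = 13)))
  cm <- suppressWarnings(combined_model(rec, unique(rec$site), N = 2))
  stages <- unique(rec[, c("patient", "stage")])
  xt <- stage_crosstab(cm, stages)
  expect_equal(sum(xt$table), 59)
  expect_equal(unname(rowSums(xt$table)["high_risk"]),
               sum(cm$risk$high_risk))
  # extreme association: all high-risk patients late-stage
  fake <- stages
  fake$stage <- ifelse(cm$risk$high_risk[match(fake$patient,
                                               cm$risk$patient)], "III", "I")
  xt2 <- stage_crosstab(cm, fake)
  expect_lt(xt2$p, 1e-6)
})

test_that("log-rank P is uniform under a null hazard", {
  ps <- vapply(1:200, function(r) {
    rec <- suppressWarnings(simulate_prognosis_cohort(
      prognosis_config(planted_hr = 1, censor_rate = 0.3, seed = 5000 + r)))
    suppressWarnings(combined_model(rec, unique(rec$site), N = 2))$logrank_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
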