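test_that("default calibrations carry the published cells and validate", {
  jc <- default_calibration("juvenile", "control")
  expect_equal(jc$weight$mean[1], 227.4)
  expect_equal(jc$weight$sd[1], 15.8)
  pe <- default_calibration("presenile", "exposed")
  expect_equal(pe$mwm$latency_mean[1], 30.4)
  expect_equal(pe$mwm$latency_sd[1], 9.1)
  expect_equal(pe$cage_ids, c(1L, 3L))
  for (ag in c("juvenile", "adult", "presenile"))
    for (arm in c("control", "exposed"))
      expect_s3_class(default_calibration(ag, arm), "cohort_spec")
  expect_error(default_calibration("senile", "control"))
  expect_error(default_calibration("juvenile", "sham"))
})

test_that("generation is deterministic in the seed", {
  sp <- default_calibration("adult", "exposed")
  a <- generate_cohort(sp, 123)
  b <- generate_cohort(sp, 123)
  expect_identical(a, b)
  c <- generate_cohort(sp, 124)
  expect_false(identical(a$animals, c$animals))
})

test_that("animal tags follow the cage-individual scheme", {
  pres <- generate_cohort(default_calibration("presenile", "exposed"), 5)
  expect_setequal(pres$animals$animal_id,
                  c(sprintf("1-%d", 1:5), sprintf("3-%d", 1:5)))
  juv <- generate_cohort(default_calibration("juvenile", "exposed"), 5)
  expect_setequal(juv$animals$animal_id, sprintf("1-%d", 1:10))
  expect_true(all(grepl("^[0-9]+-[0-9]+$", juv$animals$animal_id)))
})

test_that("zero-dispersion cohorts reproduce the calibrated means exactly", {
  sp <- zero_dispersion_spec("juvenile", "control")
  coh <- generate_cohort(sp, 99)
  for (j in 1:6)
    expect_equal(unique(coh$animals[[paste0("weight_", c("baseline", paste0("week", 1:5))[j])]]),
                 sp$weight$mean[j])
  for (j in 1:5) {
    tp <- c("baseline", paste0("week", 1:4))[j]
    expect_equal(unique(coh$animals[[paste0("rectal_", tp)]]), sp$rectal$mean[j])
    expect_equal(unique(coh$animals[[paste0("skin_", tp)]]), sp$skin$mean[j])
  }
  # organ-coefficient closure: mass / terminal * 100 returns the drawn cell
  organs <- c("brain", "heart", "liver", "testis_left", "testis_right")
  for (j in seq_along(organs)) {
    coef <- organ_weight_coefficient(
      coh$animals[[paste0("organ_", organs[j], "_g")]],
      coh$animals$terminal_weight_g)
    expect_equal(coef, rep(sp$organ$mean[j], 10))
  }
  # degenerate latency noise: every successful swim hits the cell mean
  d1 <- coh$trials[coh$trials$day == 1 & coh$trials$success, ]
  expect_true(all(d1$latency_s == sp$mwm$latency_mean[1]))
})

test_that("trial records satisfy the censoring and passive logic", {
  for (seed in 1:5) {
    tr <- generate_cohort(default_calibration("presenile", "control"), seed)$trials
    expect_true(all(tr$latency_s[tr$success] < 60))
    expect_true(all(tr$latency_s[!tr$success] == 60))
    expect_true(all(!tr$success[tr$passive]))
    expect_true(all(tr$latency_s > 0 & tr$latency_s <= 60))
    expect_setequal(unique(tr$day), c(1, 2, 3, 4, 7))
    expect_equal(nrow(tr), 10 * 4 * 5)
  }
})

test_that("truncated-normal moment matching agrees with quadrature", {
  par <- match_truncated_normal_moments(28.9, 15.4, 0, 60)
  mo <- tn_moments_quadrature(par[["location"]], par[["scale"]], 0, 60)
  expect_equal(unname(mo["mean"]), 28.9, tolerance = 1e-6)
  expect_equal(unname(mo["sd"]), 15.4, tolerance = 1e-6)

  # negligible truncation: parameters collapse onto the targets
  par2 <- match_truncated_normal_moments(30, 2, 0, 60)
  expect_equal(par2[["location"]], 30, tolerance = 1e-6)
  expect_equal(par2[["scale"]], 2, tolerance = 1e-6)

  # a bounded variable cannot have sd >= half the range
  expect_error(match_truncated_normal_moments(30, 40, 0, 60), "infeasible")
  expect_error(match_truncated_normal_moments(70, 5, 0, 60), "outside")
})

test_that("the generator recovers its calibration across replicate cohorts", {
  sp <- default_calibration("juvenile", "control")
  reps <- simulate_cohorts(sp, 200, seed = 31415)

  check_cell <- function(per_cohort, target) {
    se <- sd(per_cohort) / sqrt(length(per_cohort))
    expect_lt(abs(mean(per_cohort) - target), 3 * se + 1e-12)
  }
  check_cell(vapply(reps, function(r) mean(r$animals$weight_baseline),
                    numeric(1)), sp$weight$mean[1])
  check_cell(vapply(reps, function(r) mean(r$animals$weight_week5),
                    numeric(1)), sp$weight$mean[6])
  check_cell(vapply(reps, function(r) mean(r$animals$rectal_week1),
                    numeric(1)), sp$rectal$mean[2])
  check_cell(vapply(reps, function(r)
    mean(organ_weight_coefficient(r$animals$organ_brain_g,
                                  r$animals$terminal_weight_g)),
    numeric(1)), sp$organ$mean[1])
  lat1 <- vapply(reps, function(r) {
    tr <- r$trials
    mean(tr$latency_s[tr$day == 1 & tr$success])
  }, numeric(1))
  check_cell(lat1, sp$mwm$latency_mean[1])
  succ1 <- vapply(reps, function(r) {
    tr <- r$trials[r$trials$day == 1, ]
    100 * mean(tr$success)
  }, numeric(1))
  check_cell(succ1, sp$mwm$success_pct[1])
})
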