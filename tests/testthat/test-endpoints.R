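test_that("weekly weight gain matches the printed arithmetic and telescopes", {
  jc <- generate_cohort(zero_dispersion_spec("juvenile", "control"), 1)
  je <- generate_cohort(zero_dispersion_spec("juvenile", "exposed"), 1)
  gains <- weekly_weight_gain(rbind(jc$animals, je$animals))

  g1 <- gains[gains$arm == "control" & gains$interval == "week1-baseline", ]
  expect_equal(g1$mean_gain, 273.8 - 227.4)
  g5 <- gains[gains$arm == "exposed" & gains$interval == "week5-week4", ]
  expect_equal(g5$mean_gain, 344.3 - 327.0)

  # constant trajectories give zero gains
  flat <- jc$animals
  for (tp in paste0("weight_", c("week1", "week2", "week3", "week4", "week5")))
    flat[[tp]] <- flat$weight_baseline
  expect_true(all(weekly_weight_gain(flat)$mean_gain == 0))

  # telescoping on a stochastic cohort
  coh <- generate_cohort(default_calibration("adult", "control"), 42)$animals
  g <- weekly_weight_gain(coh)
  expect_equal(sum(g$mean_gain),
               mean(coh$weight_week5) - mean(coh$weight_baseline))

  expect_error(weekly_weight_gain(coh[, -5]), "timepoint")
})

test_that("organ weight coefficients are percentages of body weight", {
  expect_equal(round(organ_weight_coefficient(1.8, 340), 2), 0.53)
  expect_identical(organ_weight_coefficient(3.4, 340), 1)
  expect_equal(organ_weight_coefficient(1.8, 340),
               organ_weight_coefficient(1.8 / 1000, 340 / 1000))
  expect_error(organ_weight_coefficient(350, 340), "smaller")
  expect_error(organ_weight_coefficient(-1, 340), "> 0")
})

test_that("core-to-skin differential reproduces printed contrasts", {
  coh <- generate_cohort(zero_dispersion_spec("juvenile", "control"), 1)
  rect <- temperature_table(coh$animals, "rectal")
  skin <- temperature_table(coh$animals, "skin")
  d <- temperature_differential(rect, skin)
  expect_equal(d$differential_c[d$timepoint == "week4"], 37.7 - 36.2)
  expect_equal(d$differential_c[d$timepoint == "week1"], 37.5 - 35.3)
  expect_true(all(temperature_differential(rect, rect)$differential_c == 0))
  other <- rect
  other$timepoint <- paste0(other$timepoint, "_x")
  expect_error(temperature_differential(rect, other), "keys")
})

test_that("daily maze summaries follow the successful-swims convention", {
  mk <- function(lat, success, day = 1) data.frame(
    animal_id = sprintf("1-%d", seq_along(lat)), age_group = "juvenile",
    arm = "control", day = day, trial = 1L, latency_s = lat,
    success = success, passive = FALSE, stringsAsFactors = FALSE)

  all_success <- mk(rep(20, 40), rep(TRUE, 40))
  s <- mwm_daily_summary(all_success)
  expect_equal(s$mean_successful_latency_s, 20)
  expect_equal(s$percent_successful, 100)

  part <- mk(c(rep(15, 26), rep(60, 14)), c(rep(TRUE, 26), rep(FALSE, 14)))
  s2 <- mwm_daily_summary(part)
  expect_equal(s2$percent_successful, 65)
  expect_equal(s2$n_successful, 26)
  expect_equal(s2$n_attempted, 40)

  # censored failures never enter the latency average
  two <- mk(c(10, 60), c(TRUE, FALSE))
  s3 <- mwm_daily_summary(two)
  expect_equal(s3$mean_successful_latency_s, 10)
  expect_equal(s3$percent_successful, 50)

  none <- mk(rep(60, 4), rep(FALSE, 4))
  s4 <- mwm_daily_summary(none)
  expect_false(s4$latency_defined)
  expect_true(is.na(s4$mean_successful_latency_s))

  with_all <- mwm_daily_summary(two, all_trials_average = TRUE)
  expect_equal(with_all$mean_all_latency_s, 35)

  expect_error(mwm_daily_summary(two[0, ]), "no trials")
})

test_that("counts and percentages are exactly reproducible from the trials", {
  tr <- generate_cohort(default_calibration("adult", "exposed"), 8)$trials
  s <- mwm_daily_summary(tr)
  for (i in seq_len(nrow(s))) {
    sub <- tr[tr$day == s$day[i], ]
    expect_identical(s$n_attempted[i], nrow(sub))
    expect_identical(s$n_successful[i], sum(sub$success))
    expect_identical(s$percent_successful[i],
                     100 * sum(sub$success) / nrow(sub))
  }
})

test_that("passive swimmer lists are unique, sorted subsets of failures", {
  tr <- generate_cohort(default_calibration("presenile", "control"), 17)$trials
  ps <- passive_swimmers(tr)
  expect_named(ps, c("1", "2", "3", "4", "7"))
  for (d in names(ps)) {
    expect_false(any(duplicated(ps[[d]])))
    failed <- unique(tr$animal_id[tr$day == as.integer(d) & !tr$success])
    expect_true(all(ps[[d]] %in% failed))
  }

  quiet <- tr
  quiet$passive <- FALSE
  expect_true(all(lengths(passive_swimmers(quiet)) == 0))

  one <- tr[tr$animal_id == tr$animal_id[1] & tr$day == 1, ]
  one$success <- FALSE; one$latency_s <- 60; one$passive <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(passive_swimmers(one)[["1"]], one$animal_id[1])
})

test_that("passive episodes concentrate on the first training day", {
  sp <- default_calibration("presenile", "control")
  longer <- vapply(1:200, function(s) {
    ps <- passive_swimmers(generate_cohort(sp, 7000 + s)$trials)
    length(ps[["1"]]) > length(ps[["4"]])
  }, logical(1))
  expect_gte(mean(longer), 0.95)
})
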