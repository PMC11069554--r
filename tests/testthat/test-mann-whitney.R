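test_that("exact test reproduces hand-enumerated cases", {
  t1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(t1$u_statistic, 0)
  expect_equal(t1$p_value, 2 / 6)
  expect_equal(t1$method, "exact")

  # identical multisets: perfect symmetry, ties force the approximation
  x <- c(3, 1, 4, 1, 5)
  t2 <- mann_whitney_u(x, x)
  expect_equal(t2$u_statistic, length(x)^2 / 2)
  expect_equal(t2$p_value, 1)
  expect_equal(t2$method, "normal_approximation")
  expect_true(t2$tie_corrected)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact null counts sum to the binomial coefficient and are symmetric", {
  for (nn in list(c(3, 5), c(7, 7), c(10, 10))) {
    co <- mw_exact_counts(nn[1], nn[2])
    expect_equal(sum(co), choose(nn[1] + nn[2], nn[1]))
    expect_equal(co, rev(co))  # null distribution of U is symmetric
  }
})

test_that("exact p equals brute-force permutation enumeration", {
  set.seed(2023)
  for (n1 in c(2, 4, 6)) for (n2 in c(3, 5)) {
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    got <- mann_whitney_u(x, y, method = "exact")
    expect_equal(got$p_value, mw_permutation_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact p matches the reference implementation on tie-free samples", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), sd = 2)
    got <- mann_whitney_u(x, y, method = "exact")
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("U and p obey the rank-test symmetries", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), 0.5)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$u_statistic + b$u_statistic, length(x) * length(y))
    expect_equal(a$p_value, b$p_value)
    shift <- mann_whitney_u(x + 17.3, y + 17.3)
    expect_equal(shift$p_value, a$p_value)
    expect_equal(shift$u_statistic, a$u_statistic)
    neg <- mann_whitney_u(-x, -y)
    expect_equal(neg$u_statistic, length(x) * length(y) - a$u_statistic)
  }
})

test_that("normal approximation tracks the reference with and without continuity", {
  set.seed(13)
  x <- rnorm(20); y <- rnorm(25, 0.4)
  got_cc <- mann_whitney_u(x, y, method = "approx", continuity = TRUE)
  ref_cc <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got_cc$p_value, ref_cc$p.value, tolerance = 1e-10)
  got <- mann_whitney_u(x, y, method = "approx", continuity = FALSE)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # tie-corrected variance path
  xt <- c(1, 2, 2, 3, 5, 5, 5); yt <- c(2, 3, 3, 4, 5, 6)
  got_t <- mann_whitney_u(xt, yt, continuity = TRUE)
  ref_t <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE, correct = TRUE))
  expect_equal(got_t$p_value, ref_t$p.value, tolerance = 1e-10)
  expect_true(got_t$tie_corrected)
})

test_that("comparison tables flag nothing when arms are identical", {
  coh <- generate_cohort(default_calibration("juvenile", "control"), 3)
  mirrored_animals <- coh$animals
  mirrored_animals$arm <- "exposed"
  mirrored_trials <- coh$trials
  mirrored_trials$arm <- "exposed"
  cmp <- compare_groups(rbind(coh$animals, mirrored_animals),
                        rbind(coh$trials, mirrored_trials))
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))
})

test_that("comparison tables hold the nominal rate under a shared calibration", {
  # both arms drawn from the same calibration: every flagged row is a
  # false positive, so the flagged fraction must stay at or below the
  # nominal level (the exact test is conservative at n = 10)
  sp_c <- default_calibration("juvenile", "control")
  sp_e <- sp_c
  sp_e$arm <- "exposed"
  class(sp_e) <- "cohort_spec"
  flagged <- unlist(lapply(1:200, function(k) {
    a <- generate_cohort(sp_c, child_seed(909, 2 * k))
    b <- generate_cohort(sp_e, child_seed(909, 2 * k + 1))
    compare_groups(rbind(a$animals, b$animals),
                   rbind(a$trials, b$trials))$significant
  }))
  rate <- mean(flagged)
  se <- sqrt(rate * (1 - rate) / length(flagged))
  expect_lte(rate, 0.05 + 2 * se)
  expect_gte(rate, 0.005)
})

test_that("comparison rows carry the publication cell format", {
  jc <- generate_cohort(default_calibration("juvenile", "control"), 21)
  je <- generate_cohort(default_calibration("juvenile", "exposed"), 22)
  cmp <- compare_groups(rbind(jc$animals, je$animals),
                        rbind(jc$trials, je$trials))
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]+ ± -?[0-9]+\\.[0-9]+, p = [01]\\.[0-9]{3}$",
                        cmp$label)))
  expect_true(all(c("body_weight_g", "organ_coefficient_pct",
                    "rectal_temperature_c", "skin_temperature_c",
                    "mwm_latency_s") %in% cmp$endpoint))
  expect_equal(cmp$significant, cmp$p_value < 0.05)
  expect_true(all(cmp$u_statistic >= 0 &
                    cmp$u_statistic <= cmp$control_n * cmp$exposed_n))

  expect_error(compare_groups(jc$animals, jc$trials), "matched")
  expect_error(compare_groups(rbind(jc$animals, je$animals), alpha = 0),
               "alpha")
})
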