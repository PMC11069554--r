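# Shared fixtures: the study's antenna and cage scenarios, plus
# zero-dispersion cohort specs (degenerate noise makes every animal equal
# to the calibrated group means, so endpoint pipelines can be checked
# exactly).

study_antenna <- function() antenna_spec(0.0891, 7, 2.4)

exposure1_scenario <- function() {
  # presenile cages: near edge at 0.12 m, 0.375 m occupiable depth
  exposure_scenario(r_near = 0.12, cage_extent = 0.375,
                    mean_mass_kg = 0.49155, mean_length_m = 0.25,
                    label = "exposure1")
}

exposure2_scenario <- function() {
  # juvenile/adult cages: near edge at 0.20 m
  exposure_scenario(r_near = 0.20, cage_extent = 0.375,
                    mean_mass_kg = 0.2484, mean_length_m = 0.19,
                    label = "exposure2")
}

zero_dispersion_spec <- function(age_group, arm) {
  sp <- default_calibration(age_group, arm)
  sp$weight$sd[] <- 0
  sp$rectal$sd[] <- 0
  sp$skin$sd[] <- 0
  sp$organ$sd[] <- 0
  sp$mwm$latency_sd[] <- 0
  cohort_spec(sp$age_group, sp$arm, sp$n_animals, sp$cage_ids,
              sp$weight, sp$rectal, sp$skin, sp$organ, sp$mwm, sp$passive)
}

# independent brute-force two-sided Mann-Whitney p-value: enumerate every
# split of the pooled ranks into the two groups
mw_permutation_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# truncated-normal moments by adaptive quadrature (independent of the
# closed-form expressions used in the package)
tn_moments_quadrature <- function(mu, sigma, lower, upper) {
  z <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
  dens <- function(t) stats::dnorm(t, mu, sigma) / z
  m1 <- stats::integrate(function(t) t * dens(t), lower, upper,
                         rel.tol = 1e-12)$value
  m2 <- stats::integrate(function(t) (t - m1)^2 * dens(t), lower, upper,
                         rel.tol = 1e-12)$value
  c(mean = m1, sd = sqrt(m2))
}
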