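#' Cohort specification
#'
#' Bundles everything the synthetic-cohort generator needs for one age
#' group and study arm: cohort size, cage layout and per-endpoint
#' calibration cells (mean and dispersion per timepoint). Dispersions are
#' interpreted as per-animal standard deviations throughout.
#'
#' @param age_group `"juvenile"`, `"adult"` or `"presenile"`.
#' @param arm `"control"` or `"exposed"`.
#' @param n_animals Number of animals (> 0).
#' @param cage_ids Integer cage numbers; animals are split evenly across
#'   them and tagged `"<cage>-<individual>"`.
#' @param weight List with `mean` and `sd`, 6 values each (baseline +
#'   weeks 1-5), grams.
#' @param rectal,skin Lists with `mean` and `sd`, 5 values each (baseline +
#'   weeks 1-4), degrees Celsius; means must lie in `[30, 42]`.
#' @param organ List with `mean` and `sd`, 5 values each (brain, heart,
#'   liver, left testicle, right testicle), percent of body weight.
#' @param mwm List with `latency_mean`, `latency_sd` (seconds, successful
#'   swims, per training day 1, 2, 3, 4, 7) and `success_pct` (percent).
#' @param passive List with `mean_propensity`, `propensity_shape` and
#'   `day_decay` controlling the passive-swimming model (see
#'   [generate_cohort()]).
#' @return An object of class `cohort_spec`.
#' @seealso [default_calibration()] for specs calibrated to the published
#'   study tables.
#' @export
cohort_spec <- function(age_group, arm, n_animals, cage_ids,
                        weight, rectal, skin, organ, mwm,
                        passive = .passive_defaults) {
  age_group <- match.arg(age_group, c("juvenile", "adult", "presenile"))
  arm <- match.arg(arm, c("control", "exposed"))
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals <= 0L)
    stop("'n_animals' must be a positive integer", call. = FALSE)
  cage_ids <- as.integer(cage_ids)
  if (length(cage_ids) < 1L || any(is.na(cage_ids)) || any(cage_ids <= 0L))
    stop("'cage_ids' must be positive integers", call. = FALSE)

  check_cells <- function(x, name, len, lo = -Inf, hi = Inf) {
    if (length(x$mean) != len || length(x$sd) != len)
      stop(sprintf("'%s' needs %d mean and %d sd values", name, len, len),
           call. = FALSE)
    if (any(!is.finite(x$mean)) || any(x$mean < lo) || any(x$mean > hi))
      stop(sprintf("'%s' means outside [%s, %s]", name, lo, hi), call. = FALSE)
    if (any(!is.finite(x$sd)) || any(x$sd < 0))
      stop(sprintf("'%s' dispersions must be >= 0", name), call. = FALSE)
  }
  check_cells(weight, "weight", 6L, lo = 0)
  check_cells(rectal, "rectal", 5L, lo = 30, hi = 42)
  check_cells(skin, "skin", 5L, lo = 30, hi = 42)
  check_cells(organ, "organ", 5L, lo = 0)
  if (length(mwm$latency_mean) != 5L || length(mwm$latency_sd) != 5L ||
      length(mwm$success_pct) != 5L)
    stop("'mwm' needs latency_mean, latency_sd and success_pct of length 5",
         call. = FALSE)
  if (any(mwm$latency_mean <= 0) || any(mwm$latency_mean > 60))
    stop("'mwm' latency means must lie in (0, 60]", call. = FALSE)
  if (any(mwm$success_pct < 0) || any(mwm$success_pct > 100))
    stop("'mwm' success percentages must lie in [0, 100]", call. = FALSE)
  if (passive$mean_propensity < 0 || passive$mean_propensity > 1)
    stop("'passive$mean_propensity' must lie in [0, 1]", call. = FALSE)

  structure(
    list(age_group = age_group, arm = arm, n_animals = n_animals,
         cage_ids = cage_ids, weight = weight, rectal = rectal,
         skin = skin, organ = organ, mwm = mwm, passive = passive),
    class = "cohort_spec"
  )
}

# ---- truncated normal machinery ------------------------------------------

tn_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                    ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

rtruncnorm <- function(n, mu, sigma, lower, upper) {
  if (sigma == 0) return(rep(mu, n))
  u <- runif(n, pnorm(lower, mu, sigma), pnorm(upper, mu, sigma))
  qnorm(u, mu, sigma)
}

.tn_cache <- new.env(parent = emptyenv())

#' Moment-match a truncated normal distribution
#'
#' Finds location and scale of a normal distribution such that, after
#' truncation to `(lower, upper)`, its mean and standard deviation equal
#' the targets. Needed so that censored maze latencies, generated on
#' `(0, 60)` seconds, still average to the calibration cells. The solution
#' is found numerically and verified to reproduce the target moments to
#' within `1e-6`.
#'
#' @param target_mean Desired post-truncation mean, `lower < target_mean <
#'   upper`.
#' @param target_sd Desired post-truncation standard deviation (> 0). A
#'   variable bounded in an interval of width `w` cannot have a standard
#'   deviation of `w/2` or more; such requests are rejected, as are
#'   targets the truncated-normal family cannot attain (its dispersion is
#'   bounded by the uniform limit).
#' @param lower,upper Truncation bounds.
#' @param label Optional cell label used in error messages.
#' @return Named numeric vector with `location` and `scale`.
#' @export
match_truncated_normal_moments <- function(target_mean, target_sd,
                                           lower = 0, upper = 60,
                                           label = NULL) {
  who <- if (is.null(label)) {
    sprintf("cell (mean=%g, sd=%g) on (%g, %g)", target_mean, target_sd,
            lower, upper)
  } else label
  if (!(lower < target_mean && target_mean < upper))
    stop(sprintf("infeasible moment matching for %s: mean outside interval", who),
         call. = FALSE)
  if (target_sd <= 0)
    stop(sprintf("infeasible moment matching for %s: sd must be > 0", who),
         call. = FALSE)
  if (target_sd >= (upper - lower) / 2)
    stop(sprintf(
      "infeasible moment matching for %s: sd %g exceeds the maximum (%g) of a variable bounded on (%g, %g)",
      who, target_sd, (upper - lower) / 2, lower, upper), call. = FALSE)

  key <- paste(target_mean, target_sd, lower, upper, sep = "|")
  hit <- .tn_cache[[key]]
  if (!is.null(hit)) return(hit)

  obj <- function(p) {
    mo <- tn_moments(p[1], exp(p[2]), lower, upper)
    sum(((mo - c(target_mean, target_sd)) / target_sd)^2)
  }
  starts <- list(c(target_mean, log(target_sd)),
                 c((lower + upper) / 2, log(2 * target_sd)),
                 c(target_mean, log((upper - lower))))
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value < 1e-16) break
  }
  fit <- c(location = best$par[1], scale = exp(best$par[2]))
  mo <- tn_moments(fit[["location"]], fit[["scale"]], lower, upper)
  if (max(abs(mo - c(target_mean, target_sd))) > 1e-6)
    stop(sprintf("moment matching did not converge for %s (residual %.2g)",
                 who, max(abs(mo - c(target_mean, target_sd)))),
         call. = FALSE)
  .tn_cache[[key]] <- fit
  fit
}

# ---- cohort generation ---------------------------------------------------

#' Generate one synthetic cohort
#'
#' Draws a complete longitudinal dataset for one cohort with the
#' statistical structure of the calibration spec:
#' \itemize{
#'   \item body weights as correlated trajectories: baseline from a
#'     positive-truncated normal, then weekly increments whose means equal
#'     the consecutive differences of the calibrated means (so group means
#'     are matched at every timepoint and trajectories are autocorrelated;
#'     increments may be negative);
#'   \item rectal and skin temperatures from normals truncated to
#'     `[30, 42]` degrees C;
#'   \item terminal organ masses as coefficient draws (percent of body
#'     weight) times the terminal weight;
#'   \item Morris water maze trials (4 per day on days 1, 2, 3, 4, 7):
#'     per-trial success is Bernoulli with the calibrated day probability;
#'     successful latencies come from a truncated normal on (0, 60) s
#'     moment-matched to the calibrated cell; failures are censored at
#'     exactly 60 s; a failed trial is flagged passive with probability
#'     (per-animal propensity) x (day decay), so passive episodes
#'     concentrate on day 1 and fade.
#' }
#' Output is deterministic for a fixed `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list with two data frames: `animals` (one row per animal:
#'   id, cage, weights, temperatures, organ masses, terminal weight) and
#'   `trials` (one row per maze trial: day, trial index, latency,
#'   success, passive).
#' @examples
#' coh <- generate_cohort(default_calibration("juvenile", "control"), seed = 1)
#' head(coh$animals[, 1:6]); head(coh$trials)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_animals

  per_cage <- ceiling(n / length(spec$cage_ids))
  cage <- rep(spec$cage_ids, each = per_cage)[seq_len(n)]
  indiv <- unlist(lapply(split(seq_len(n), cage), seq_along), use.names = FALSE)
  indiv <- indiv[order(order(cage))]  # individual index within cage, original order
  animal_id <- sprintf("%d-%d", cage, indiv)

  # weights: baseline + increment trajectories
  wm <- spec$weight$mean; ws <- spec$weight$sd
  w <- matrix(NA_real_, n, 6)
  w[, 1] <- rtruncnorm(n, wm[1], ws[1], 0, Inf)
  for (t in 2:6) {
    inc_sd <- if (ws[t] == 0 && ws[t - 1] == 0) 0 else
      sqrt(max(ws[t]^2 - ws[t - 1]^2, (0.25 * ws[t])^2))
    w[, t] <- w[, t - 1] + rnorm(n, wm[t] - wm[t - 1], inc_sd)
  }
  colnames(w) <- paste0("weight_", .weight_timepoints)

  draw_temp <- function(cells, prefix) {
    m <- vapply(seq_along(cells$mean), function(j)
      rtruncnorm(n, cells$mean[j], cells$sd[j], 30, 42), numeric(n))
    colnames(m) <- paste0(prefix, "_", .temp_timepoints)
    m
  }
  rectal <- draw_temp(spec$rectal, "rectal")
  skin <- draw_temp(spec$skin, "skin")

  terminal <- w[, 6]
  coefs <- vapply(seq_along(.organ_names), function(j)
    rtruncnorm(n, spec$organ$mean[j], spec$organ$sd[j], 0, Inf), numeric(n))
  organs <- coefs * terminal / 100
  colnames(organs) <- paste0("organ_", .organ_names, "_g")

  animals <- data.frame(
    animal_id = animal_id, age_group = spec$age_group, arm = spec$arm,
    cage = cage, w, rectal, skin, organs, terminal_weight_g = terminal,
    stringsAsFactors = FALSE
  )

  # maze trials
  propensity <- rbeta(n, spec$passive$propensity_shape * spec$passive$mean_propensity,
                      spec$passive$propensity_shape * (1 - spec$passive$mean_propensity))
  trials <- vector("list", length(.mwm_days))
  for (j in seq_along(.mwm_days)) {
    day <- .mwm_days[j]
    p_success <- spec$mwm$success_pct[j] / 100
    lat_mean <- spec$mwm$latency_mean[j]
    lat_sd <- spec$mwm$latency_sd[j]
    n_tr <- n * 4L
    success <- runif(n_tr) < p_success
    latency <- rep(60, n_tr)
    if (any(success)) {
      if (lat_sd == 0) {
        latency[success] <- lat_mean
      } else {
        par <- match_truncated_normal_moments(
          lat_mean, lat_sd, 0, 60,
          label = sprintf("%s/%s maze day %d", spec$age_group, spec$arm, day))
        latency[success] <- rtruncnorm(sum(success), par[["location"]],
                                       par[["scale"]], 0, 60)
      }
    }
    decay <- spec$passive$day_decay[[as.character(day)]]
    p_pass <- rep(pmin(1, propensity * decay), each = 4L)
    passive <- !success & runif(n_tr) < p_pass
    trials[[j]] <- data.frame(
      animal_id = rep(animal_id, each = 4L),
      age_group = spec$age_group, arm = spec$arm,
      day = day, trial = rep(1:4, times = n),
      latency_s = latency, success = success, passive = passive,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL

  list(animals = animals, trials = trials)
}

#' Generate replicate cohorts
#'
#' Convenience wrapper that generates `n_replicates` independent cohorts
#' from the same spec, with per-replicate seeds derived deterministically
#' from the master seed (see [child_seed()]).
#'
#' @param spec A [cohort_spec()].
#' @param n_replicates Number of cohorts.
#' @param seed Master seed.
#' @return A list of [generate_cohort()] results.
#' @export
simulate_cohorts <- function(spec, n_replicates, seed) {
  lapply(seq_len(n_replicates), function(k)
    generate_cohort(spec, child_seed(seed, k)))
}
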