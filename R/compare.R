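# Exposed-versus-control comparison tables: one Mann-Whitney contrast per
# endpoint x age group x timepoint, mirroring the presentation of the
# study's result tables (mean +/- dispersion with a p-value per cell).

.endpoint_digits <- c(body_weight_g = 1, rectal_temperature_c = 1,
                      skin_temperature_c = 1, organ_coefficient_pct = 2,
                      mwm_latency_s = 1)

#' Exposed-versus-control comparison table
#'
#' Runs a Mann-Whitney U test for every endpoint x age group x timepoint
#' contrast between the exposed and control arms: body weight at each of
#' the six weighings, each organ weight coefficient, rectal and skin
#' temperature at each of the five measurements, and the per-animal mean
#' successful maze latency on each training day (animals without a
#' successful swim that day do not contribute a latency).
#'
#' @param animals Animals data frame covering both arms of each age group.
#' @param trials Matching trials data frame.
#' @param alpha Significance level in (0, 1); a row is significant when
#'   `p < alpha` (on the Holm-adjusted p-value if `holm = TRUE`).
#' @param method,continuity Passed to [mann_whitney_u()].
#' @param holm Apply a Holm multiple-testing correction across all rows
#'   (off by default: the study reports raw per-contrast p-values).
#' @return Data frame of class `comparison_table`: endpoint, age group,
#'   timepoint, control and exposed summaries (mean, dispersion, n), the
#'   U statistic, p-value, test method, significance flag, and a
#'   formatted `label` in the `"mean ± dispersion, p = ..."` cell style.
#' @export
compare_groups <- function(animals, trials = NULL, alpha = 0.05,
                           method = "auto", continuity = TRUE,
                           holm = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)

  rows <- list()
  add_contrast <- function(endpoint, age_group, timepoint, ctrl, expo) {
    if (length(ctrl) < 1 || length(expo) < 1)
      stop(sprintf("unmatched arms for %s / %s / %s", endpoint, age_group,
                   timepoint), call. = FALSE)
    tst <- mann_whitney_u(expo, ctrl, method = method,
                          continuity = continuity)
    rows[[length(rows) + 1L]] <<- data.frame(
      endpoint = endpoint, age_group = age_group, timepoint = timepoint,
      control_mean = mean(ctrl), control_dispersion = sd(ctrl),
      control_n = length(ctrl),
      exposed_mean = mean(expo), exposed_dispersion = sd(expo),
      exposed_n = length(expo),
      u_statistic = tst$u_statistic, p_value = tst$p_value,
      test_method = tst$method,
      stringsAsFactors = FALSE
    )
  }

  pull <- function(age_group, arm, col) {
    v <- animals[animals$age_group == age_group & animals$arm == arm, col]
    if (!length(v))
      stop(sprintf("unmatched arms: no %s animals in age group %s", arm,
                   age_group), call. = FALSE)
    v
  }

  for (ag in unique(animals$age_group)) {
    arms <- unique(animals$arm[animals$age_group == ag])
    if (!all(c("control", "exposed") %in% arms))
      stop(sprintf("age group %s lacks a matched exposed/control pair", ag),
           call. = FALSE)
    for (tp in .weight_timepoints)
      add_contrast("body_weight_g", ag, tp,
                   pull(ag, "control", paste0("weight_", tp)),
                   pull(ag, "exposed", paste0("weight_", tp)))
    for (site in c("rectal", "skin"))
      for (tp in .temp_timepoints)
        add_contrast(paste0(site, "_temperature_c"), ag, tp,
                     pull(ag, "control", paste0(site, "_", tp)),
                     pull(ag, "exposed", paste0(site, "_", tp)))
    for (org in .organ_names) {
      col <- paste0("organ_", org, "_g")
      add_contrast("organ_coefficient_pct", ag, org,
                   organ_weight_coefficient(
                     pull(ag, "control", col),
                     pull(ag, "control", "terminal_weight_g")),
                   organ_weight_coefficient(
                     pull(ag, "exposed", col),
                     pull(ag, "exposed", "terminal_weight_g")))
    }
    if (!is.null(trials)) {
      sub <- trials[trials$age_group == ag, ]
      for (d in sort(unique(sub$day))) {
        per_animal <- function(arm) {
          s <- sub[sub$arm == arm & sub$day == d & sub$success, ]
          if (!nrow(s)) return(numeric(0))
          tapply(s$latency_s, s$animal_id, mean)
        }
        ctrl <- per_animal("control"); expo <- per_animal("exposed")
        if (length(ctrl) && length(expo))
          add_contrast("mwm_latency_s", ag, paste0("day", d), ctrl, expo)
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- if (holm) p.adjust(out$p_value, method = "holm") else
    out$p_value
  out$significant <- out$p_adjusted < alpha
  dg <- .endpoint_digits[out$endpoint]
  dg[is.na(dg)] <- 2
  out$label <- sprintf("%s ± %s, p = %.3f",
                       mapply(formatC, out$exposed_mean, digits = dg,
                              MoreArgs = list(format = "f")),
                       mapply(formatC, out$exposed_dispersion, digits = dg,
                              MoreArgs = list(format = "f")),
                       out$p_value)
  class(out) <- c("comparison_table", "data.frame")
  out
}
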