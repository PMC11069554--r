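# Endpoint computation: every reported summary of the exposure experiment,
# recomputed from per-animal records. Endpoint tables are long data frames
# with one row per age group x arm x timepoint.

.group_cols <- c("age_group", "arm")

endpoint_summarise <- function(animals, cols, timepoints, endpoint) {
  missing_cols <- setdiff(cols, names(animals))
  if (length(missing_cols))
    stop(sprintf("missing timepoint column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyNA(animals[cols]))
    stop(sprintf("missing values in %s measurements", endpoint), call. = FALSE)
  groups <- unique(animals[.group_cols])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- animals[animals$age_group == groups$age_group[g] &
                     animals$arm == groups$arm[g], cols, drop = FALSE]
    data.frame(
      endpoint = endpoint,
      age_group = groups$age_group[g], arm = groups$arm[g],
      timepoint = timepoints,
      mean = vapply(sub, mean, numeric(1)),
      dispersion = vapply(sub, sd, numeric(1)),
      n = nrow(sub),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Body-weight endpoint table
#'
#' Per-group mean, dispersion (SD across animals) and n for each of the
#' six weighing timepoints.
#'
#' @param animals Animals data frame from [generate_cohort()] (cohorts may
#'   be row-bound first).
#' @return Long endpoint table (`endpoint`, `age_group`, `arm`,
#'   `timepoint`, `mean`, `dispersion`, `n`).
#' @export
weight_table <- function(animals) {
  endpoint_summarise(animals, paste0("weight_", .weight_timepoints),
                     .weight_timepoints, "body_weight_g")
}

#' Weekly body-weight gain
#'
#' Week-on-week gain per group: the difference of consecutive timepoint
#' means, with the dispersion of the per-animal gains alongside. The gains
#' telescope: they sum to final mean minus baseline mean.
#'
#' @param animals Animals data frame.
#' @return Long table with one row per group and consecutive-timepoint
#'   interval (`interval`, `mean_gain`, `dispersion`, `n`).
#' @export
weekly_weight_gain <- function(animals) {
  cols <- paste0("weight_", .weight_timepoints)
  if (!all(cols %in% names(animals)) || anyNA(animals[cols]))
    stop("weight trajectory incomplete: all six timepoints are required",
         call. = FALSE)
  groups <- unique(animals[.group_cols])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- animals[animals$age_group == groups$age_group[g] &
                     animals$arm == groups$arm[g], cols, drop = FALSE]
    gains <- as.matrix(sub[, -1]) - as.matrix(sub[, -length(cols)])
    data.frame(
      age_group = groups$age_group[g], arm = groups$arm[g],
      interval = paste(.weight_timepoints[-1], .weight_timepoints[-6],
                       sep = "-"),
      mean_gain = colMeans(gains),
      dispersion = apply(gains, 2, sd),
      n = nrow(sub),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Organ weight coefficient
#'
#' Organ mass as a percentage of terminal body weight; invariant to a
#' common rescaling of the mass unit.
#'
#' @param organ_mass_g Organ mass (vectorised, > 0).
#' @param terminal_weight_g Body weight at necropsy (> 0).
#' @return `100 * organ_mass_g / terminal_weight_g`.
#' @examples
#' organ_weight_coefficient(1.8, 340)  # ~0.53 %
#' @export
organ_weight_coefficient <- function(organ_mass_g, terminal_weight_g) {
  if (any(organ_mass_g <= 0) || any(terminal_weight_g <= 0))
    stop("masses must be > 0", call. = FALSE)
  if (any(organ_mass_g >= terminal_weight_g))
    stop("organ mass must be smaller than body weight", call. = FALSE)
  100 * organ_mass_g / terminal_weight_g
}

#' Organ weight-coefficient endpoint table
#'
#' Coefficients (percent of terminal body weight) for brain, heart,
#' liver and both testicles, summarised per group.
#'
#' @param animals Animals data frame.
#' @return Long endpoint table with `timepoint` holding the organ name.
#' @export
organ_coefficient_table <- function(animals) {
  for (org in .organ_names) {
    animals[[paste0("coef_", org)]] <- organ_weight_coefficient(
      animals[[paste0("organ_", org, "_g")]], animals$terminal_weight_g)
  }
  endpoint_summarise(animals, paste0("coef_", .organ_names),
                     .organ_names, "organ_coefficient_pct")
}

#' Temperature endpoint table
#'
#' @param animals Animals data frame.
#' @param site `"rectal"` or `"skin"`.
#' @return Long endpoint table of temperatures, degrees C.
#' @export
temperature_table <- function(animals, site = c("rectal", "skin")) {
  site <- match.arg(site)
  endpoint_summarise(animals, paste0(site, "_", .temp_timepoints),
                     .temp_timepoints,
                     paste0(site, "_temperature_c"))
}

#' Core-to-skin temperature differential
#'
#' Elementwise difference of group-mean rectal and skin temperatures per
#' group and timepoint. In healthy animals the skin surface runs roughly
#' 0.5-2 degrees C below core temperature.
#'
#' @param rectal_table,skin_table Endpoint tables from
#'   [temperature_table()]; group/timepoint keys must match exactly.
#' @return Long table with `differential_c` per group and timepoint.
#' @export
temperature_differential <- function(rectal_table, skin_table) {
  key <- c(.group_cols, "timepoint")
  if (nrow(rectal_table) != nrow(skin_table))
    stop("rectal and skin tables have different numbers of rows", call. = FALSE)
  m <- merge(rectal_table, skin_table, by = key,
             suffixes = c("_rectal", "_skin"))
  if (nrow(m) != nrow(rectal_table))
    stop("rectal and skin tables do not share the same group/timepoint keys",
         call. = FALSE)
  out <- data.frame(
    m[key],
    differential_c = m$mean_rectal - m$mean_skin,
    n = m$n_rectal,
    stringsAsFactors = FALSE
  )
  out[order(out$age_group, out$arm, out$timepoint), , drop = FALSE]
}

#' Daily Morris water maze summary
#'
#' Per group and training day: the mean and SD of successful-swim
#' latencies (censored 60 s failures are excluded from the latency
#' average), the percentage of successful swims, and the underlying
#' counts. Days with no successful swim report `NA` latency with
#' `latency_defined = FALSE`.
#'
#' @param trials Trials data frame from [generate_cohort()].
#' @param all_trials_average If `TRUE`, an additional column
#'   `mean_all_latency_s` averages over every trial including censored
#'   ones (off by default; the headline metric follows the
#'   successful-swims convention).
#' @return One row per age group x arm x day.
#' @export
mwm_daily_summary <- function(trials, all_trials_average = FALSE) {
  if (is.null(trials) || nrow(trials) == 0)
    stop("no trials supplied", call. = FALSE)
  groups <- unique(trials[c(.group_cols, "day")])
  groups <- groups[order(groups$age_group, groups$arm, groups$day), ]
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- trials[trials$age_group == groups$age_group[g] &
                    trials$arm == groups$arm[g] &
                    trials$day == groups$day[g], ]
    succ <- sub$latency_s[sub$success]
    row <- data.frame(
      age_group = groups$age_group[g], arm = groups$arm[g],
      day = groups$day[g],
      mean_successful_latency_s = if (length(succ)) mean(succ) else NA_real_,
      dispersion_s = if (length(succ) > 1) sd(succ) else NA_real_,
      percent_successful = 100 * length(succ) / nrow(sub),
      n_successful = length(succ),
      n_attempted = nrow(sub),
      latency_defined = length(succ) > 0,
      stringsAsFactors = FALSE
    )
    if (all_trials_average) row$mean_all_latency_s <- mean(sub$latency_s)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Animals with passive-swimming episodes, per day
#'
#' Lists, for each training day, the sorted unique tags of animals that
#' drifted passively in at least one trial that day. Passive episodes are
#' by construction a subset of failed (censored) trials.
#'
#' @param trials Trials data frame.
#' @return Named list, one sorted character vector of animal tags per day.
#' @export
passive_swimmers <- function(trials) {
  days <- sort(unique(trials$day))
  out <- lapply(days, function(d) {
    ids <- unique(trials$animal_id[trials$day == d & trials$passive])
    sort_animal_ids(ids)
  })
  names(out) <- as.character(days)
  out
}

# sort "cage-individual" tags numerically by cage then individual
sort_animal_ids <- function(ids) {
  if (!length(ids)) return(character(0))
  parts <- do.call(rbind, strsplit(ids, "-", fixed = TRUE))
  ids[order(as.integer(parts[, 1]), as.integer(parts[, 2]))]
}
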