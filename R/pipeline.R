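# Orchestration: a run configuration (YAML), deterministic child seeds, and
# an end-to-end driver that plans dosimetry, simulates the cohorts, computes
# endpoints and comparison tables, and writes a manifest with checksums.

#' Deterministic child seed
#'
#' Derives the seed for the `index`-th stochastic component from the master
#' seed via one step of a Lehmer congruential map modulo the Mersenne prime
#' 2^31 - 1. Adding a component leaves the seeds of the others untouched,
#' and results stay below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer component index.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, index) {
  m <- 2147483647
  h <- ((as.numeric(master_seed) %% m) * 48271 + as.numeric(index) * 16807) %% m
  as.integer(h %% (m - 1) + 1)
}

# 32-bit FNV-1a over the bytes of a character scalar; multiplication is done
# in 16-bit halves so everything stays exact in doubles.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor on the 32-bit value, done on hi/lo 16-bit halves
    hi <- h %/% 65536; lo <- h %% 65536
    bl <- bitwXor(as.integer(lo), b)
    h <- hi * 65536 + bl
    # multiply mod 2^32
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((lo * prime) + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(paste(deparse(config), collapse = ""))
}

#' Read and validate a run configuration
#'
#' The configuration is a YAML file with blocks `seed`, `dosimetry`
#' (antenna, limits, scenarios), `cohorts` (either `defaults:
#' <group>/<arm>` references or inline specs) and `analysis` (alpha, test
#' method, continuity, holm). See
#' `system.file("extdata", "default_run.yaml", package = "rfdosim")` for
#' the documented schema.
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Default run configuration
#'
#' The built-in configuration reproducing the study design: both exposure
#' scenarios (presenile cages at 0.12 m; juvenile/adult cages at 0.20 m)
#' and all six cohorts at their published calibrations.
#'
#' @param seed Master seed.
#' @return A validated list of class `run_config`.
#' @export
default_run_config <- function(seed = 20240504) {
  path <- system.file("extdata", "default_run.yaml", package = "rfdosim")
  cfg <- yaml::read_yaml(path)
  cfg$seed <- seed
  validate_run_config(cfg)
}

#' Validate a run-configuration list
#'
#' Checks every block of a run configuration and fails with a message
#' naming each offending key. Called by [read_run_config()] and
#' [default_run_config()]; exported so programmatically built
#' configurations can be validated too.
#'
#' @param cfg A plain list with the configuration blocks.
#' @return The configuration, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  bad <- character(0)
  need <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  a <- cfg$dosimetry$antenna
  need(is.numeric(a$power_w) && a$power_w > 0, "dosimetry.antenna.power_w")
  need(is.numeric(a$gain_db), "dosimetry.antenna.gain_db")
  need(is.numeric(a$frequency_ghz) && a$frequency_ghz > 0,
       "dosimetry.antenna.frequency_ghz")
  lim <- cfg$dosimetry$limits
  need(is.numeric(lim$sar_wkg) && lim$sar_wkg > 0, "dosimetry.limits.sar_wkg")
  need(is.numeric(lim$density_wm2) && lim$density_wm2 > 0,
       "dosimetry.limits.density_wm2")
  need(length(cfg$dosimetry$scenarios) >= 1, "dosimetry.scenarios")
  for (i in seq_along(cfg$dosimetry$scenarios)) {
    sc <- cfg$dosimetry$scenarios[[i]]
    key <- sprintf("dosimetry.scenarios[%d]", i)
    need(is.numeric(sc$r_near_m) && sc$r_near_m > 0, paste0(key, ".r_near_m"))
    need(is.numeric(sc$cage_extent_m) && sc$cage_extent_m >= 0,
         paste0(key, ".cage_extent_m"))
    need(is.numeric(sc$mean_mass_kg) && sc$mean_mass_kg > 0,
         paste0(key, ".mean_mass_kg"))
    need(is.numeric(sc$mean_length_m) && sc$mean_length_m > 0,
         paste0(key, ".mean_length_m"))
  }
  need(length(cfg$cohorts) >= 1, "cohorts")
  for (i in seq_along(cfg$cohorts)) {
    co <- cfg$cohorts[[i]]
    if (!is.null(co$defaults)) {
      parts <- strsplit(co$defaults, "/", fixed = TRUE)[[1]]
      ok <- length(parts) == 2 &&
        parts[1] %in% c("juvenile", "adult", "presenile") &&
        parts[2] %in% c("control", "exposed")
      need(ok, sprintf("cohorts[%d].defaults", i))
    } else {
      need(FALSE, sprintf("cohorts[%d] (only 'defaults: <group>/<arm>' entries are supported)", i))
    }
  }
  an <- cfg$analysis
  need(is.numeric(an$alpha) && an$alpha > 0 && an$alpha < 1, "analysis.alpha")
  if (length(bad))
    stop("invalid run configuration; offending keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full experiment pipeline
#'
#' End-to-end replica of the study workflow: (1) dosimetry planning and
#' ICNIRP compliance for every configured exposure scenario; (2) seeded
#' simulation of every configured cohort (child seeds derived from the
#' master seed, so cohorts are independent of each other); (3) endpoint
#' tables; (4) exposed-versus-control comparison tables. All outputs are
#' written under `output_dir` together with `manifest.json` carrying the
#' configuration hash, master seed and an FNV-1a checksum per file, and a
#' structured `run.log`. Deterministic for a fixed configuration and seed.
#'
#' @param config A `run_config` from [read_run_config()] or
#'   [default_run_config()].
#' @param output_dir Output directory (created if needed); defaults to the
#'   configuration's `output_dir` or `"results"`.
#' @return Invisibly, a list with the dosimetry reports, the pooled
#'   `animals`/`trials` data, all endpoint tables, the comparison table
#'   and the manifest.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  output_dir <- output_dir %||% config$output_dir %||% "results"
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(unclass(config))
  log_lines <- character(0)
  say <- function(stage, detail) {
    line <- sprintf("stage=%s seed=%s config=%s %s", stage, config$seed,
                    chash, detail)
    log_lines <<- c(log_lines, line)
  }

  # dosimetry
  ant <- antenna_spec(config$dosimetry$antenna$power_w,
                      config$dosimetry$antenna$gain_db,
                      config$dosimetry$antenna$frequency_ghz)
  lims <- compliance_limits(config$dosimetry$limits$sar_wkg,
                            config$dosimetry$limits$density_wm2)
  dosimetry <- lapply(config$dosimetry$scenarios, function(sc) {
    scen <- suppressWarnings(exposure_scenario(
      sc$r_near_m, sc$cage_extent_m, sc$mean_mass_kg, sc$mean_length_m,
      antenna = ant, label = sc$label))
    summ <- sar_range(ant, scen)
    chk <- icnirp_check(summ, lims)
    list(label = sc$label,
         s_min = summ$s_min, s_avg = summ$s_avg, s_max = summ$s_max,
         sar_min = summ$sar_min, sar_avg = summ$sar_avg,
         sar_max = summ$sar_max,
         mean_length_m_assumed = sc$mean_length_m,
         far_field_warning = summ$far_field_warning,
         compliant = chk$compliant, sar_margin = chk$sar_margin,
         density_margin = chk$density_margin)
  })
  jsonlite::write_json(dosimetry, file.path(output_dir, "dosimetry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("plan-dosimetry", sprintf("scenarios=%d", length(dosimetry)))

  # simulate
  cohorts <- lapply(seq_along(config$cohorts), function(k) {
    parts <- strsplit(config$cohorts[[k]]$defaults, "/", fixed = TRUE)[[1]]
    spec <- default_calibration(parts[1], parts[2])
    generate_cohort(spec, child_seed(config$seed, k))
  })
  animals <- do.call(rbind, lapply(cohorts, `[[`, "animals"))
  trials <- do.call(rbind, lapply(cohorts, `[[`, "trials"))
  write_csv_exact(animals, file.path(output_dir, "animals.csv"))
  write_csv_exact(trials, file.path(output_dir, "trials.csv"))
  say("simulate", sprintf("cohorts=%d animals=%d trials=%d",
                          length(cohorts), nrow(animals), nrow(trials)))

  # endpoints + comparisons
  res <- analyze_experiment(animals, trials, config, output_dir)
  say("analyze", sprintf("endpoint_tables=%d", length(res$endpoints)))
  say("report", sprintf("comparison_rows=%d", nrow(res$comparison)))

  files <- c("dosimetry.json", "animals.csv", "trials.csv",
             names(res$written))
  checksums <- vapply(files, function(f)
    fnv1a(readLines(file.path(output_dir, f), warn = FALSE)), character(1))
  manifest <- list(config_hash = chash, seed = config$seed,
                   files = as.list(checksums))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(output_dir, "run.log"))

  invisible(list(dosimetry = dosimetry, animals = animals, trials = trials,
                 endpoints = res$endpoints, comparison = res$comparison,
                 manifest = manifest))
}

#' Analyze stored or in-memory cohort data
#'
#' The analysis stage on its own: endpoint tables and the comparison
#' table, written as CSV (plus the passive-swimmer lists as JSON). Running
#' it on the CSVs written by a previous [run_experiment()] reproduces the
#' same tables, enabling analyze-only partial reruns.
#'
#' @param animals Animals data frame, or path to an `animals.csv`.
#' @param trials Trials data frame, or path to a `trials.csv`.
#' @param config A `run_config` supplying the analysis block.
#' @param output_dir Directory for the written tables (`NULL` to skip
#'   writing).
#' @return List with `endpoints` (named list of tables), `comparison`, and
#'   `written` (named vector of written file names).
#' @export
analyze_experiment <- function(animals, trials, config = default_run_config(),
                               output_dir = NULL) {
  if (is.character(animals)) animals <- read.csv(animals, stringsAsFactors = FALSE)
  if (is.character(trials)) trials <- read.csv(trials, stringsAsFactors = FALSE)
  an <- config$analysis
  endpoints <- list(
    body_weight = weight_table(animals),
    weekly_gain = weekly_weight_gain(animals),
    organ_coefficients = organ_coefficient_table(animals),
    rectal_temperature = temperature_table(animals, "rectal"),
    skin_temperature = temperature_table(animals, "skin"),
    mwm_daily = mwm_daily_summary(trials)
  )
  endpoints$temperature_differential <- temperature_differential(
    endpoints$rectal_temperature, endpoints$skin_temperature)
  comparison <- compare_groups(animals, trials, alpha = an$alpha,
                               method = an$method %||% "auto",
                               continuity = isTRUE(an$continuity),
                               holm = isTRUE(an$holm))
  passive <- passive_swimmers(trials)

  written <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(endpoints)) {
      f <- paste0("endpoint_", nm, ".csv")
      write_csv_exact(endpoints[[nm]], file.path(output_dir, f))
      written[f] <- f
    }
    write_csv_exact(as.data.frame(comparison),
                    file.path(output_dir, "comparison.csv"))
    written["comparison.csv"] <- "comparison.csv"
    jsonlite::write_json(passive, file.path(output_dir, "passive_swimmers.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    written["passive_swimmers.json"] <- "passive_swimmers.json"
  }
  list(endpoints = endpoints, comparison = comparison, passive = passive,
       written = written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer that round-trips doubles exactly (17 significant digits), so an
# analyze-only rerun from stored CSVs reproduces byte-identical tables
write_csv_exact <- function(df, path) {
  df <- as.data.frame(df)
  char_cols <- which(vapply(df, is.character, logical(1)))
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], format = "g",
                                               digits = 17)
  write.csv(df, path, row.names = FALSE, quote = char_cols)
}
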