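#' Antenna specification
#'
#' Describes the radiating source of a far-field exposure setup: the power
#' actually delivered at the antenna input, the antenna gain over an
#' isotropic radiator, and the carrier frequency.
#'
#' @param power_input_w Power at the antenna input, watts. Must be > 0.
#' @param gain_db Antenna gain, decibels. Must be finite.
#' @param frequency_ghz Carrier frequency, gigahertz. Must be > 0.
#'
#' @return An object of class `antenna_spec`.
#' @examples
#' antenna_spec(power_input_w = 0.0891, gain_db = 7, frequency_ghz = 2.4)
#' @export
antenna_spec <- function(power_input_w, gain_db, frequency_ghz) {
  stopifnot(is.numeric(power_input_w), length(power_input_w) == 1L,
            is.numeric(gain_db), length(gain_db) == 1L,
            is.numeric(frequency_ghz), length(frequency_ghz) == 1L)
  if (!is.finite(power_input_w) || power_input_w <= 0)
    stop("'power_input_w' must be a positive finite number", call. = FALSE)
  if (!is.finite(gain_db))
    stop("'gain_db' must be finite", call. = FALSE)
  if (!is.finite(frequency_ghz) || frequency_ghz <= 0)
    stop("'frequency_ghz' must be a positive finite number", call. = FALSE)
  structure(
    list(power_input_w = power_input_w, gain_db = gain_db,
         frequency_ghz = frequency_ghz),
    class = "antenna_spec"
  )
}

#' Exposure scenario: cage geometry and cohort physique
#'
#' One cage placement in front of the antenna, together with the averaged
#' physique of the animals housed there. `r_near` is the distance from the
#' antenna to the near edge of the occupiable volume; `cage_extent` is the
#' occupiable depth along the beam axis, so animals range over
#' `[r_near, r_near + cage_extent]`.
#'
#' If `r_near` is closer than the far-field distance of the antenna the
#' scenario is still constructed, but carries a `far_field_warning` flag:
#' the inverse-square model is only advisory inside the near field.
#'
#' @param r_near Distance from antenna to cage near edge, metres (> 0).
#' @param cage_extent Occupiable depth along the beam axis, metres (>= 0).
#' @param mean_mass_kg Cohort-averaged body mass, kilograms (> 0).
#' @param mean_length_m Cohort-averaged animal length, metres (> 0).
#' @param antenna Optional [antenna_spec()]; when given, the far-field
#'   distance check is evaluated against it.
#' @param label Optional scenario label used in reports.
#'
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(r_near, cage_extent, mean_mass_kg,
                              mean_length_m, antenna = NULL, label = NULL) {
  if (!is.finite(r_near) || r_near <= 0)
    stop("'r_near' must be > 0", call. = FALSE)
  if (!is.finite(cage_extent) || cage_extent < 0)
    stop("'cage_extent' must be >= 0", call. = FALSE)
  if (!is.finite(mean_mass_kg) || mean_mass_kg <= 0)
    stop("'mean_mass_kg' must be > 0", call. = FALSE)
  if (!is.finite(mean_length_m) || mean_length_m <= 0)
    stop("'mean_length_m' must be > 0", call. = FALSE)
  ff_warn <- FALSE
  if (!is.null(antenna)) {
    ff <- far_field_distance(antenna)
    ff_warn <- r_near < ff
    if (ff_warn)
      warning(sprintf(
        "r_near (%.3f m) is inside the far-field distance (%.3f m); the inverse-square model is advisory here",
        r_near, ff), call. = FALSE)
  }
  structure(
    list(r_near = r_near, cage_extent = cage_extent,
         mean_mass_kg = mean_mass_kg, mean_length_m = mean_length_m,
         far_field_warning = ff_warn, label = label),
    class = "exposure_scenario"
  )
}

#' Dosimetry constants
#'
#' The dimensionless coefficient of the whole-body SAR estimate (already
#' divided by the carrier frequency in GHz at evaluation time) and the
#' speed of light. The default coefficient is 5.954e-2, which reproduces
#' the reference whole-body SAR summaries for a 2.4 GHz rodent exposure;
#' it can be overridden for other absorption models.
#'
#' @param eq_coefficient Dimensionless SAR coefficient (> 0).
#' @param speed_of_light Metres per second.
#' @return An object of class `dosimetry_constants`.
#' @export
dosimetry_constants <- function(eq_coefficient = 5.954e-2,
                                speed_of_light = 299792458) {
  if (!is.finite(eq_coefficient) || eq_coefficient <= 0)
    stop("'eq_coefficient' must be > 0", call. = FALSE)
  structure(
    list(eq_coefficient = eq_coefficient, speed_of_light = speed_of_light),
    class = "dosimetry_constants"
  )
}

#' ICNIRP whole-body exposure limits
#'
#' Default values are the ICNIRP general-public whole-body averaged SAR
#' limit (0.08 W/kg) and the whole-body incident power density reference
#' level (10 W/m^2) applicable in the considered frequency band.
#'
#' @param sar_whole_body_limit W/kg, > 0.
#' @param power_density_reference W/m^2, > 0.
#' @return An object of class `compliance_limits`.
#' @export
compliance_limits <- function(sar_whole_body_limit = 0.08,
                              power_density_reference = 10) {
  if (!is.finite(sar_whole_body_limit) || sar_whole_body_limit <= 0)
    stop("'sar_whole_body_limit' must be > 0", call. = FALSE)
  if (!is.finite(power_density_reference) || power_density_reference <= 0)
    stop("'power_density_reference' must be > 0", call. = FALSE)
  structure(
    list(sar_whole_body_limit = sar_whole_body_limit,
         power_density_reference = power_density_reference),
    class = "compliance_limits"
  )
}

#' Decibels to linear power factor
#'
#' @param gain_db Gain in decibels (finite, vectorised).
#' @return `10^(gain_db/10)`.
#' @examples
#' db_to_linear(0)   # 1
#' db_to_linear(10)  # 10
#' @export
db_to_linear <- function(gain_db) {
  if (!is.numeric(gain_db) || any(!is.finite(gain_db)))
    stop("'gain_db' must be finite numeric", call. = FALSE)
  10^(gain_db / 10)
}

#' Incident power density at a distance
#'
#' Far-field power flux through unit area at distance `r` from the antenna,
#' \eqn{S(r) = P_A \, 10^{G/10} / (4 \pi r^2)} (inverse-square law).
#'
#' @param antenna An [antenna_spec()].
#' @param r Distance from the antenna, metres (> 0, vectorised).
#' @return Incident power density, W/m^2.
#' @examples
#' ant <- antenna_spec(0.0891, 7, 2.4)
#' incident_power_density(ant, 0.12)  # ~2.47 W/m^2
#' @export
incident_power_density <- function(antenna, r) {
  stopifnot(inherits(antenna, "antenna_spec"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be > 0", call. = FALSE)
  antenna$power_input_w * db_to_linear(antenna$gain_db) / (4 * pi * r^2)
}

#' Far-field distance of the antenna
#'
#' For a combined electric/magnetic dipole with a shared phase centre the
#' far field forms at roughly one free-space wavelength, so the wavelength
#' `c / f` is returned as the far-field distance.
#'
#' @param antenna An [antenna_spec()].
#' @param constants A [dosimetry_constants()] supplying the speed of light.
#' @return Distance in metres.
#' @examples
#' far_field_distance(antenna_spec(0.0891, 7, 2.4))  # ~0.125 m
#' @export
far_field_distance <- function(antenna, constants = dosimetry_constants()) {
  stopifnot(inherits(antenna, "antenna_spec"))
  constants$speed_of_light / (antenna$frequency_ghz * 1e9)
}

#' Line-averaged incident power density over a depth interval
#'
#' Averages the inverse-square profile along the beam axis over
#' `[r0, r1]`:
#' \deqn{\langle S \rangle = \frac{1}{r_1 - r_0} \int_{r_0}^{r_1} \frac{P_A G}{4\pi r^2} dr
#'       = \frac{P_A G}{4\pi}\frac{1}{r_0 r_1}.}
#' The degenerate interval `r0 == r1` returns the pointwise density.
#'
#' @param antenna An [antenna_spec()].
#' @param r0,r1 Interval endpoints in metres, `0 < r0 <= r1`.
#' @return Averaged incident power density, W/m^2.
#' @export
averaged_incident_power_density <- function(antenna, r0, r1) {
  stopifnot(inherits(antenna, "antenna_spec"))
  if (!is.finite(r0) || r0 <= 0) stop("'r0' must be > 0", call. = FALSE)
  if (!is.finite(r1) || r1 < r0) stop("'r1' must be >= r0", call. = FALSE)
  antenna$power_input_w * db_to_linear(antenna$gain_db) / (4 * pi) / (r0 * r1)
}

#' Whole-body averaged SAR from incident power density
#'
#' Closed-form estimate of the whole-body averaged specific absorption
#' rate of a rodent in a far-field plane wave:
#' \deqn{SAR_{wb} = \frac{k}{f_{GHz}} \frac{\langle S \rangle \langle L \rangle}{\langle m \rangle}}
#' with `k` the dimensionless coefficient from [dosimetry_constants()],
#' `S` the (averaged) incident power density in W/m^2, `L` the averaged
#' animal length in metres and `m` the averaged body mass in kilograms.
#' The estimate is linear in `S` and `L` and inversely proportional to
#' `m` and the frequency.
#'
#' @param frequency_ghz Carrier frequency, GHz (> 0).
#' @param s_inc Incident power density, W/m^2 (>= 0, vectorised).
#' @param mean_length_m Averaged animal length, metres (> 0).
#' @param mean_mass_kg Averaged body mass, kilograms (> 0).
#' @param constants A [dosimetry_constants()].
#' @return Whole-body averaged SAR, W/kg.
#' @examples
#' whole_body_sar(2.4, s_inc = 0.605, mean_length_m = 0.25,
#'                mean_mass_kg = 0.49155)  # ~0.0076 W/kg
#' @export
whole_body_sar <- function(frequency_ghz, s_inc, mean_length_m, mean_mass_kg,
                           constants = dosimetry_constants()) {
  stopifnot(inherits(constants, "dosimetry_constants"))
  if (!is.finite(frequency_ghz) || frequency_ghz <= 0)
    stop("'frequency_ghz' must be > 0", call. = FALSE)
  if (any(!is.finite(s_inc)) || any(s_inc < 0))
    stop("'s_inc' must be >= 0", call. = FALSE)
  if (!is.finite(mean_length_m) || mean_length_m <= 0)
    stop("'mean_length_m' must be > 0", call. = FALSE)
  if (!is.finite(mean_mass_kg) || mean_mass_kg <= 0)
    stop("'mean_mass_kg' must be > 0", call. = FALSE)
  constants$eq_coefficient / frequency_ghz * s_inc * mean_length_m / mean_mass_kg
}

#' Min/average/max exposure summary for one cage scenario
#'
#' Evaluates the incident power density at the cage near edge (maximum),
#' the far edge (minimum) and the line average over the occupiable depth,
#' then converts each to whole-body SAR. Because the SAR estimate is
#' linear in the density, the three SAR values share one SAR/density
#' ratio.
#'
#' @param antenna An [antenna_spec()].
#' @param scenario An [exposure_scenario()].
#' @param constants A [dosimetry_constants()].
#' @return An object of class `sar_summary`: a list with `s_min`, `s_avg`,
#'   `s_max` (W/m^2), `sar_min`, `sar_avg`, `sar_max` (W/kg), the scenario
#'   and antenna, and the advisory `far_field_warning` flag.
#' @export
sar_range <- function(antenna, scenario, constants = dosimetry_constants()) {
  stopifnot(inherits(antenna, "antenna_spec"),
            inherits(scenario, "exposure_scenario"))
  r0 <- scenario$r_near
  r1 <- scenario$r_near + scenario$cage_extent
  s_max <- incident_power_density(antenna, r0)
  s_min <- incident_power_density(antenna, r1)
  s_avg <- averaged_incident_power_density(antenna, r0, r1)
  sar <- function(s) whole_body_sar(antenna$frequency_ghz, s,
                                    scenario$mean_length_m,
                                    scenario$mean_mass_kg, constants)
  structure(
    list(s_min = s_min, s_avg = s_avg, s_max = s_max,
         sar_min = sar(s_min), sar_avg = sar(s_avg), sar_max = sar(s_max),
         antenna = antenna, scenario = scenario,
         far_field_warning = scenario$far_field_warning),
    class = "sar_summary"
  )
}

#' @export
print.sar_summary <- function(x, ...) {
  lab <- if (is.null(x$scenario$label)) "" else paste0(" [", x$scenario$label, "]")
  cat(sprintf("Exposure summary%s\n", lab))
  cat(sprintf("  S_inc (W/m^2): min %.2f  avg %.2f  max %.2f\n",
              x$s_min, x$s_avg, x$s_max))
  cat(sprintf("  SAR_wb (W/kg): min %.2g  avg %.2g  max %.2g\n",
              x$sar_min, x$sar_avg, x$sar_max))
  cat(sprintf("  mean mass %.4g kg (length %.2f m assumed, flagged as assumption)\n",
              x$scenario$mean_mass_kg, x$scenario$mean_length_m))
  if (isTRUE(x$far_field_warning))
    cat("  warning: cage near edge inside the far-field distance\n")
  invisible(x)
}

#' ICNIRP compliance check for an exposure summary
#'
#' The scenario is compliant when the cage-averaged whole-body SAR does
#' not exceed the whole-body SAR limit and the averaged incident power
#' density does not exceed the reference level (boundary equality counts
#' as compliant). The report also carries margin ratios `limit/observed`:
#' the SAR margin against the averaged SAR and the density margin against
#' the maximum density in the cage (the worst-case position).
#'
#' @param summary A `sar_summary` from [sar_range()].
#' @param limits A [compliance_limits()].
#' @return A list of class `icnirp_report` with `compliant`, `sar_margin`,
#'   `density_margin` and the inputs.
#' @export
icnirp_check <- function(summary, limits = compliance_limits()) {
  stopifnot(inherits(summary, "sar_summary"),
            inherits(limits, "compliance_limits"))
  compliant <- summary$sar_avg <= limits$sar_whole_body_limit &&
    summary$s_avg <= limits$power_density_reference
  structure(
    list(compliant = compliant,
         sar_margin = limits$sar_whole_body_limit / summary$sar_avg,
         density_margin = limits$power_density_reference / summary$s_max,
         summary = summary, limits = limits),
    class = "icnirp_report"
  )
}

#' @export
print.icnirp_report <- function(x, ...) {
  cat(sprintf("ICNIRP compliance: %s\n",
              if (x$compliant) "COMPLIANT" else "NON-COMPLIANT"))
  cat(sprintf("  whole-body SAR margin (limit/avg): %.3g\n", x$sar_margin))
  cat(sprintf("  power-density margin (reference/max): %.3g\n", x$density_margin))
  invisible(x)
}
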