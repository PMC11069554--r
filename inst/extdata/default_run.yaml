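# Default run configuration: the study's two exposure scenarios and all
# six cohorts at their published calibrations.
#
# Schema:
#   seed: integer master seed (per-cohort seeds are derived from it)
#   output_dir: where run_experiment() writes its report bundle
#   dosimetry:
#     antenna: {power_w, gain_db, frequency_ghz}
#     limits:  {sar_wkg, density_wm2}      # ICNIRP whole-body limits
#     scenarios: list of {label, r_near_m, cage_extent_m, mean_mass_kg,
#                         mean_length_m}   # mean_length_m is an assumption,
#                                          # flagged as such in reports
#   cohorts: list of {defaults: <age_group>/<arm>}
#   analysis: {alpha, method: auto|exact|approx, continuity, holm}
seed: 20240504
output_dir: results
dosimetry:
  antenna:
    power_w: 0.0891
    gain_db: 7.0
    frequency_ghz: 2.4
  limits:
    sar_wkg: 0.08
    density_wm2: 10.0
  scenarios:
    - label: exposure1_presenile
      r_near_m: 0.12
      cage_extent_m: 0.375
      mean_mass_kg: 0.49155    # mean of the two presenile baseline means
      mean_length_m: 0.25
    - label: exposure2_juvenile_adult
      r_near_m: 0.20
      cage_extent_m: 0.375
      mean_mass_kg: 0.2484     # mean of the four juvenile/adult baseline means
      mean_length_m: 0.19
cohorts:
  - defaults: juvenile/control
  - defaults: juvenile/exposed
  - defaults: adult/control
  - defaults: adult/exposed
  - defaults: presenile/control
  - defaults: presenile/exposed
analysis:
  alpha: 0.05
  method: auto
  continuity: true
  holm: false
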