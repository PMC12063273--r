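# Default synthetic-gait generator parameters.
#
# Provenance tags per value:
#   [STUDY]      printed estimate from the study being emulated
#   [CALIBRATED] derived in closed form from printed estimates
#   [DEFAULT]    not reported by the study; package default (see the methods
#                vignette for the rationale)
#
# Units: speeds m/s, masses kg, propulsion peak N/kg, propulsion impulse
# N/kg*s. Leg coding: non-paretic = reference (0), paretic = 1. The per-leg
# generative model for each metric is
#   value = intercept + slope*speed + leg*(leg_effect + interaction*speed)
#           + b0 + b1*speed + leg*(b2 + b3*speed) + condition residual
# with (b1, b3) optionally correlated.

stroke:
  n_participants: 15        # [STUDY] cohort size after exclusions
  cws_mean: 0.71            # [STUDY] comfortable walking speed, mean
  cws_sd: 0.18              # [STUDY] comfortable walking speed, SD
  cws_min: 0.5              # [STUDY] cohort inclusion: independent gait above 0.5 m/s
  cws_max: 1.1              # [DEFAULT] truncation for schedule realism
  max_speed_margin: 0.4     # [DEFAULT] max speed = CWS + margin; yields ~8 conditions
  mass_median_kg: 80        # [STUDY] median body mass
  mass_sdlog: 0.135         # [CALIBRATED] log-normal sigma from IQR [75, 90]
  paretic_left_ratio: 0.5   # [DEFAULT]
  cross_metric_corr: 0.8    # [DEFAULT] shared-impairment correlation of the
                            #   peak and impulse latent sources (marginals
                            #   per metric are unchanged)
  peak:
    intercept: 0.226        # [CALIBRATED] non-paretic intercept placing
                            #   peak symmetry ~ 0.40 at the mean CWS
    slope: 1.6              # [STUDY] non-paretic speed slope (0.16 per 0.1 m/s)
    leg_effect: -0.17       # [STUDY] paretic reduction
    interaction: -0.4       # [CALIBRATED] paretic slope 1.2 [STUDY] minus 1.6
    sd_intercept: 0.08      # [DEFAULT]
    sd_slope: 0.43          # [STUDY] random speed-slope SD (0.043 per 0.1 m/s)
    sd_leg: 0.17            # [STUDY] random leg-effect SD
    sd_interaction: 0.57    # [STUDY] random speed-by-leg SD
    corr_slope_interaction: -0.68  # [CALIBRATED] reproduces the paretic
                            #   slope SD 0.42 [STUDY] given the two SDs above
    corr_leg_interaction: 0.0      # [DEFAULT]
    sd_condition: 0.04      # [DEFAULT] condition-level residual SD
    floor: 0.02             # [DEFAULT] truncation floor
  impulse:
    intercept: 0.25         # [CALIBRATED] non-paretic intercept placing
                            #   cohort-mean impulse symmetry ~ 0.40 at CWS
    slope: 0.12             # [STUDY] speed slope (0.012 per 0.1 m/s)
    leg_effect: -0.12       # [STUDY] paretic reduction
    interaction: 0.026      # [STUDY] speed-by-leg effect (not significant)
    sd_intercept: 0.02      # [DEFAULT]
    sd_slope: 0.070         # [STUDY] random speed-slope SD
    sd_leg: 0.094           # [STUDY] random leg-effect SD
    sd_interaction: 0.071   # [STUDY] random speed-by-leg SD
    corr_slope_interaction: 0.0  # [DEFAULT]
    corr_leg_interaction: -0.72  # [CALIBRATED] couples a larger paretic
                            #   deficit to a steeper paretic impulse gain,
                            #   reproducing the printed symmetry-model
                            #   speed and interaction effects
    sd_condition: 0.008     # [DEFAULT]
    floor: 0.005            # [DEFAULT]

control:
  n_participants: 16        # [STUDY]
  cws_mean: 1.25            # [DEFAULT] young healthy adults
  cws_sd: 0.12              # [DEFAULT]
  cws_min: 1.0              # [DEFAULT]
  cws_max: 1.5              # [DEFAULT]
  mass_median_kg: 68        # [STUDY] median body mass
  mass_sdlog: 0.256         # [CALIBRATED] log-normal sigma from IQR [63, 89]
  peak:                     # legs exchangeable: no fixed leg effect;
                            # independent per-leg deviations instead
    intercept: 0.15         # [DEFAULT]
    slope: 1.73             # [STUDY]
    sd_intercept: 0.10      # [DEFAULT]
    sd_slope: 0.15          # [STUDY]
    sd_leg_intercept: 0.05  # [CALIBRATED] chosen with sd_leg_slope to give
    sd_leg_slope: 0.17      #   emergent symmetry slope SD ~ 0.033 [STUDY]
    sd_condition: 0.04      # [DEFAULT]
    floor: 0.02             # [DEFAULT]
  impulse:
    intercept: 0.24         # [DEFAULT]
    slope: 0.0083           # [STUDY]
    sd_intercept: 0.02      # [DEFAULT]
    sd_slope: 0.0026        # [STUDY]
    sd_leg_intercept: 0.008 # [CALIBRATED] chosen with sd_leg_slope to give
    sd_leg_slope: 0.013     #   emergent symmetry slope SD ~ 0.019 [STUDY]
    sd_condition: 0.008     # [DEFAULT]
    floor: 0.005            # [DEFAULT]

noise:
  step_cv: 0.10             # [DEFAULT] between-step coefficient of variation

crossover_rate: 0.02        # [DEFAULT] fraction of steps flagged crossover

cadence:
  intercept: 60             # [DEFAULT] steps/min at zero speed
  slope: 40                 # [DEFAULT] steps/min per m/s

waveform:
  duty_factor: 0.62         # [DEFAULT] stance fraction of the stride
  braking_peak_ratio: 0.9   # [DEFAULT] braking amplitude / propulsion peak
  braking_onset: 0.05       # [DEFAULT] fraction of stance
  braking_duration: 0.30    # [DEFAULT] fraction of stance
  propulsion_end_margin: 0.04  # [DEFAULT] fraction of stance before TC
  foot_length_m: 0.25       # [DEFAULT] heel-to-toe marker offset
  belt_offset_m: 0.10       # [DEFAULT] foot ML distance from the midline
  crossover_ml_m: 0.02      # [DEFAULT] ML overlap across the midline
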