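name: calibration
sample_rate_hz: 80.0
wear_sites:
- hip
- nondom_wrist
- dom_wrist
epoch_s: 5.0
activities:
- label: lying_still
  duration_s: 660.0
  met_mean: 1.0
  met_sd: 0.15
  movement_freq_hz: 0.5
  enmo_target_mg:
    hip: 3.4
    nondom_wrist: 6.4
    dom_wrist: 5.5
  enmo_sd_mg:
    hip: 5.3
    nondom_wrist: 6.4
    dom_wrist: 5.5
- label: standing_still
  duration_s: 190.0
  met_mean: 1.4
  met_sd: 0.2
  movement_freq_hz: 0.6
  enmo_target_mg:
    hip: 6.7
    nondom_wrist: 12.5
    dom_wrist: 13.5
  enmo_sd_mg:
    hip: 6.1
    nondom_wrist: 13.7
    dom_wrist: 17.4
- label: sitting_still
  duration_s: 185.0
  met_mean: 1.1
  met_sd: 0.15
  movement_freq_hz: 0.5
  enmo_target_mg:
    hip: 6.0
    nondom_wrist: 8.6
    dom_wrist: 8.3
  enmo_sd_mg:
    hip: 6.0
    nondom_wrist: 8.0
    dom_wrist: 6.6
- label: washing_dishes
  duration_s: 205.0
  met_mean: 1.9
  met_sd: 0.3
  movement_freq_hz: 1.0
  enmo_target_mg:
    hip: 8.2
    nondom_wrist: 71.9
    dom_wrist: 101.1
  enmo_sd_mg:
    hip: 5.6
    nondom_wrist: 43.9
    dom_wrist: 44.7
- label: kneading_dough
  duration_s: 190.0
  met_mean: 2.0
  met_sd: 0.3
  movement_freq_hz: 1.2
  enmo_target_mg:
    hip: 10.8
    nondom_wrist: 65.3
    dom_wrist: 69.1
  enmo_sd_mg:
    hip: 6.7
    nondom_wrist: 24.2
    dom_wrist: 24.8
- label: dressing
  duration_s: 210.0
  met_mean: 2.2
  met_sd: 0.3
  movement_freq_hz: 0.8
  enmo_target_mg:
    hip: 17.1
    nondom_wrist: 120.2
    dom_wrist: 119.3
  enmo_sd_mg:
    hip: 6.9
    nondom_wrist: 39.1
    dom_wrist: 37.4
- label: folding_towels
  duration_s: 185.0
  met_mean: 1.8
  met_sd: 0.25
  movement_freq_hz: 0.8
  enmo_target_mg:
    hip: 8.4
    nondom_wrist: 85.5
    dom_wrist: 86.9
  enmo_sd_mg:
    hip: 5.9
    nondom_wrist: 20.5
    dom_wrist: 19.3
- label: vacuuming
  duration_s: 200.0
  met_mean: 2.8
  met_sd: 0.35
  movement_freq_hz: 1.0
  enmo_target_mg:
    hip: 25.7
    nondom_wrist: 46.2
    dom_wrist: 65.2
  enmo_sd_mg:
    hip: 11.3
    nondom_wrist: 22.4
    dom_wrist: 22.4
- label: shopping
  duration_s: 230.0
  met_mean: 2.3
  met_sd: 0.3
  movement_freq_hz: 0.8
  enmo_target_mg:
    hip: 11.6
    nondom_wrist: 49.9
    dom_wrist: 59.7
  enmo_sd_mg:
    hip: 5.1
    nondom_wrist: 22.4
    dom_wrist: 18.0
- label: writing
  duration_s: 230.0
  met_mean: 1.2
  met_sd: 0.15
  movement_freq_hz: 0.7
  enmo_target_mg:
    hip: 4.8
    nondom_wrist: 12.5
    dom_wrist: 15.2
  enmo_sd_mg:
    hip: 4.5
    nondom_wrist: 5.0
    dom_wrist: 5.4
- label: dealing_cards
  duration_s: 190.0
  met_mean: 1.4
  met_sd: 0.2
  movement_freq_hz: 1.0
  enmo_target_mg:
    hip: 7.8
    nondom_wrist: 31.0
    dom_wrist: 47.1
  enmo_sd_mg:
    hip: 6.2
    nondom_wrist: 22.0
    dom_wrist: 24.4
- label: treadmill_walk
  duration_s: 355.0
  met_mean: 3.0
  met_sd: 0.35
  movement_freq_hz: 1.0
  enmo_target_mg:
    hip: 48.4
    nondom_wrist: 31.5
    dom_wrist: 33.3
  enmo_sd_mg:
    hip: 10.6
    nondom_wrist: 25.4
    dom_wrist: 37.9
- label: usual_walk
  duration_s: 80.0
  met_mean: 3.3
  met_sd: 0.35
  movement_freq_hz: 1.6
  enmo_target_mg:
    hip: 94.3
    nondom_wrist: 117.0
    dom_wrist: 130.3
  enmo_sd_mg:
    hip: 39.6
    nondom_wrist: 57.8
    dom_wrist: 83.7
- label: brisk_walk
  duration_s: 335.0
  met_mean: 4.0
  met_sd: 0.5
  movement_freq_hz: 1.9
  enmo_target_mg:
    hip: 137.2
    nondom_wrist: 187.7
    dom_wrist: 205.8
  enmo_sd_mg:
    hip: 51.8
    nondom_wrist: 139.8
    dom_wrist: 161.5
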