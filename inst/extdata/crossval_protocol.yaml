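name: crossval
sample_rate_hz: 60.0
wear_sites:
- hip
- nondom_wrist
epoch_s: 5.0
activities:
- label: reading
  duration_s: 300.0
  met_mean: 1.2
  met_sd: 0.15
  movement_freq_hz: 0.5
  enmo_target_mg:
    hip: 3.5
    nondom_wrist: 12.0
  enmo_sd_mg:
    hip: 3.0
    nondom_wrist: 5.0
- label: watching_tv
  duration_s: 300.0
  met_mean: 1.0
  met_sd: 0.12
  movement_freq_hz: 0.4
  enmo_target_mg:
    hip: 3.2
    nondom_wrist: 8.0
  enmo_sd_mg:
    hip: 2.5
    nondom_wrist: 4.0
- label: handcrafting
  duration_s: 300.0
  met_mean: 1.4
  met_sd: 0.15
  movement_freq_hz: 0.8
  enmo_target_mg:
    hip: 4.5
    nondom_wrist: 14.0
  enmo_sd_mg:
    hip: 3.0
    nondom_wrist: 6.0
- label: standing_still
  duration_s: 300.0
  met_mean: 1.3
  met_sd: 0.15
  movement_freq_hz: 0.6
  enmo_target_mg:
    hip: 4.0
    nondom_wrist: 10.0
  enmo_sd_mg:
    hip: 3.0
    nondom_wrist: 5.0
- label: making_bed
  duration_s: 300.0
  met_mean: 2.4
  met_sd: 0.3
  movement_freq_hz: 0.9
  enmo_target_mg:
    hip: 12.0
    nondom_wrist: 42.0
  enmo_sd_mg:
    hip: 5.0
    nondom_wrist: 15.0
- label: usual_walk
  duration_s: 300.0
  met_mean: 3.3
  met_sd: 0.35
  movement_freq_hz: 1.6
  enmo_target_mg:
    hip: 90.0
    nondom_wrist: 110.0
  enmo_sd_mg:
    hip: 30.0
    nondom_wrist: 40.0
- label: sweeping
  duration_s: 300.0
  met_mean: 2.5
  met_sd: 0.3
  movement_freq_hz: 1.0
  enmo_target_mg:
    hip: 26.0
    nondom_wrist: 45.0
  enmo_sd_mg:
    hip: 10.0
    nondom_wrist: 15.0
- label: climbing_stairs
  duration_s: 300.0
  met_mean: 4.0
  met_sd: 0.45
  movement_freq_hz: 1.5
  enmo_target_mg:
    hip: 110.0
    nondom_wrist: 120.0
  enmo_sd_mg:
    hip: 35.0
    nondom_wrist: 40.0
- label: brisk_walk
  duration_s: 360.0
  met_mean: 3.8
  met_sd: 0.45
  movement_freq_hz: 1.9
  enmo_target_mg:
    hip: 135.0
    nondom_wrist: 180.0
  enmo_sd_mg:
    hip: 45.0
    nondom_wrist: 60.0
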