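deployment:
  site_code: SIM
  latitude: 52.4
  longitude: -131.7
  seafloor_depth: 740.0
  recorder_model: synthetic
  start_date: "2018-08-15"
  end_date: "2018-10-10"
  record_s: 300.0
  off_s: 3300.0
sim:
  sample_rate: 256.0
  noise_psd_db: 60.0
  seed: 11
  hours_step: 1
calls:
  class: fin_chorus
  f_lo: 20.0
  f_hi: 40.0
  duration: 1.0
  f_start: 34.0
  f_end: 23.0
  start_doy: 240
  end_doy: 270
  hourly_rate: 2.0
  night_multiplier: 1.0
  rise_db: 10.0
  call_interval_s: 4.0
detector:
  frame_s: 1.0
  snr_threshold: 8.0
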