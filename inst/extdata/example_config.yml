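# Example simulation configuration: dynamic management at the
# high-elevation site, baseline climate, 2012-2018.
site: graswang
altitude: 864
latitude: 47.57
management: dynamic
start_year: 2012
end_year: 2018
spinup_years: 2
seed: 1
rules:
  first_cut_latest_doy: 150
  max_days_between_cuts: 55
  manure_window_days: 7
  heavy_rain_threshold: 5
  earliest_manure_doy: 32
composition:
  c_load: 437
  n_load: 48
  ph: 7.6
scenario:
  label: baseline
  co2:
    2011: 400
    2100: 400
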