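# Demonstration run: a small synthetic boreal grid spanning 1961-2009.
synthetic:
  grid_rows: 6
  grid_cols: 6
  cell_area_km2: 10
  years: [1950, 2009]
  wsi_base: 145
  wsi_trend: -0.8
  wsi_sd: 8
  gs_base: 160
  gs_trend: 0.2
  gs_sd: 5
  detection_prob: 1
  seed: 1
run:
  decades: [1970, 1980, 1990, 2000]
  threshold: 0.73
  n_validation_sites: 30
  forecast_decades: [2010, 2020, 2030, 2040, 2050]
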