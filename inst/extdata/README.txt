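Reference statistics from a published seven-territory urban red fox
camera-trap survey, used as worked-example inputs and arithmetic checks.

territory_seasonal_consistency.csv
  Dietz-R Mantel seasonal-consistency results per territory, grouped by the
  time difference between the compared seasonal surveys (1 = consecutive,
  2 = one season apart, 3 = two apart). For time differences 1 and 2 each row
  is a Fisher-omnibus chi-square over two season-pair tests (df = 4); for
  time difference 3 a single test's p-value is given. "All" rows are the
  across-territory combinations.

lir_model_parameters.csv
  Fitted parameters (with bootstrap SEs and 95% CIs) of the
  emigration + reimmigration + mortality model for the pooled lagged
  identification rate of the same survey: N animals in the study area, mean
  days in and out of the area, and daily mortality rate.
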