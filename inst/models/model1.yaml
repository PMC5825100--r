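name: model1
description: >
  Sparsest network: the eight direct paths into EPP plus a minimal set of
  previously reported inter-predictor regressions (body size driving
  longevity, provisioning and clutch spread; longevity and altitude
  shaping range size; geography shaping song).
variables: [epp, body_size, longevity, male_feeding, testes_residual,
            range_size, altitude_range, clutch_range, song_complexity]
regressions:
  epp: [body_size, longevity, male_feeding, testes_residual, range_size,
        altitude_range, clutch_range, song_complexity]
  longevity: [body_size]
  range_size: [longevity, altitude_range]
  male_feeding: [body_size, longevity]
  clutch_range: [body_size, longevity]
  song_complexity: [altitude_range, range_size]
exogenous_covariances: free
endogenous: [epp, longevity, range_size, male_feeding, clutch_range,
             song_complexity]
expected_df: 16
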