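name: model2
description: >
  Model 1 densified: testes size feeds provisioning and range size, and
  song complexity responds to clutch spread and provisioning as well as
  geography.
variables: [epp, body_size, longevity, male_feeding, testes_residual,
            range_size, altitude_range, clutch_range, song_complexity]
regressions:
  epp: [body_size, longevity, male_feeding, testes_residual, range_size,
        altitude_range, clutch_range, song_complexity]
  longevity: [body_size]
  range_size: [longevity, altitude_range, testes_residual]
  male_feeding: [body_size, longevity, testes_residual]
  clutch_range: [body_size, longevity, range_size]
  song_complexity: [altitude_range, range_size, clutch_range, male_feeding]
exogenous_covariances: free
endogenous: [epp, longevity, range_size, male_feeding, clutch_range,
             song_complexity]
expected_df: 11
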