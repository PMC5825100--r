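name: model4
description: >
  The only model treating altitudinal range as endogenous (a consequence
  of range size and longevity rather than a driver); testes size and
  body size are the exogenous inputs.
variables: [epp, body_size, longevity, male_feeding, testes_residual,
            range_size, altitude_range, clutch_range, song_complexity]
regressions:
  epp: [body_size, longevity, male_feeding, testes_residual, range_size,
        altitude_range, clutch_range, song_complexity]
  longevity: [body_size]
  range_size: [longevity]
  altitude_range: [range_size, longevity]
  male_feeding: [body_size, longevity]
  clutch_range: [body_size, range_size, longevity]
  song_complexity: [range_size, clutch_range, male_feeding]
exogenous_covariances: free
endogenous: [epp, longevity, range_size, altitude_range, male_feeding,
             clutch_range, song_complexity]
expected_df: 15
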