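name: model5
description: >
  Intermediate network centred on body size and longevity as upstream
  drivers (body size feeds provisioning directly); testes size stays
  fully exogenous.
variables: [epp, body_size, longevity, male_feeding, testes_residual,
            range_size, altitude_range, clutch_range, song_complexity]
regressions:
  epp: [body_size, longevity, male_feeding, testes_residual, range_size,
        altitude_range, clutch_range, song_complexity]
  longevity: [body_size]
  male_feeding: [body_size, longevity]
  range_size: [longevity, altitude_range]
  clutch_range: [body_size, range_size, longevity]
  song_complexity: [range_size, altitude_range]
exogenous_covariances: free
endogenous: [epp, longevity, male_feeding, range_size, clutch_range,
             song_complexity]
expected_df: 15
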