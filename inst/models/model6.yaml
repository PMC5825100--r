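name: model6
description: >
  The best-supported contrast-scale network: body size drives longevity,
  longevity drives testes size, range size and provisioning, and clutch
  spread and song complexity sit downstream of both geography and
  provisioning.
variables: [epp, body_size, longevity, male_feeding, testes_residual,
            range_size, altitude_range, clutch_range, song_complexity]
regressions:
  epp: [body_size, longevity, male_feeding, testes_residual, range_size,
        altitude_range, clutch_range, song_complexity]
  longevity: [body_size]
  testes_residual: [longevity]
  range_size: [longevity, altitude_range]
  male_feeding: [body_size, longevity, testes_residual]
  clutch_range: [body_size, range_size, longevity, male_feeding]
  song_complexity: [range_size, altitude_range, clutch_range, male_feeding]
exogenous_covariances: free
endogenous: [epp, longevity, testes_residual, range_size, male_feeding,
             clutch_range, song_complexity]
expected_df: 12
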