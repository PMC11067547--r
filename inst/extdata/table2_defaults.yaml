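n_patients_amd: 49.0
n_eyes_amd: 54.0
n_controls: 27.0
n_visits_max: 4.0
visit_count_probs:
- 0.27777777777777779
- 0.07407407407407407
- 0.12962962962962962
- 0.51851851851851849
visit_interval_months:
  mean: 12.0
  sd: 2.0
age_amd:
  mean: 70.70000000000000284
  sd: 9.09999999999999964
age_controls:
  mean: 63.39999999999999858
  sd: 8.90000000000000036
age_range:
- 45.0
- 85.0
pseudophakic_fraction_amd: 0.25925925925925924
pseudophakic_fraction_controls: 0.1111111111111111
right_eye_fraction: 0.5
fixed_effects_cross_sectional:
  mesopic:
    intercept: 5.05999999999999961
    age: -0.09
    pseudophakic: -0.29999999999999999
    subRPE_drusen: -0.22
    SDD: -0.38
    PED: -1.30000000000000004
    vitelliform: -0.96999999999999997
    HRF: -0.89000000000000001
    refractile: 0.63
    iRORA: -0.66000000000000003
    cRORA: -1.35000000000000009
  scotopic:
    intercept: 1.52000000000000002
    age: -0.04
    pseudophakic: 0.03
    subRPE_drusen: -0.17999999999999999
    SDD: -0.37
    PED: -1.22999999999999998
    vitelliform: -0.66000000000000003
    HRF: -0.87
    refractile: 0.37
    iRORA: -0.85999999999999999
    cRORA: 0.46999999999999997
fixed_effects_intervisit:
  mesopic:
    intercept: 2.64999999999999991
    age: -0.04
    years_between_visits: -0.48999999999999999
    pseudophakic: 0.71999999999999997
    subRPE_drusen: 0.12
    SDD: 0.03
    PED: 0.73999999999999999
    vitelliform: 0.52000000000000002
    HRF: -0.07000000000000001
    refractile: -0.13
    iRORA: 0.93999999999999995
    cRORA: -0.23999999999999999
    z_RNFL: -0.07000000000000001
    z_GCL: -0.03
    z_IPL: -0.01
    z_INL: 0.06
    z_OPL: 0.02
    z_ONL: 0.07000000000000001
    z_IS: -0.001
    z_OS: 0.002
    z_RPEDC: -0.046
  scotopic:
    intercept: 10.71000000000000085
    age: -0.14999999999999999
    years_between_visits: 0.13
    pseudophakic: 0.20999999999999999
    subRPE_drusen: -0.29999999999999999
    SDD: -0.06
    PED: 0.40000000000000002
    vitelliform: 1.16999999999999993
    HRF: 0.65000000000000002
    refractile: -3.5
    iRORA: 0.94999999999999996
    cRORA: -2.14999999999999991
    z_RNFL: -0.01
    z_GCL: 0.04
    z_IPL: -0.02
    z_INL: 0.02
    z_OPL: 0.02
    z_ONL: 0.003
    z_IS: -0.0001
    z_OS: -0.01
    z_RPEDC: -0.0002
random_effect_sds:
  patient: 1.5
  visit: 0.5
  grid: 0.80000000000000004
  residual: 1.5
random_effect_sds_intervisit:
  patient: 0.5
  visit: 0.29999999999999999
  grid: 0.29999999999999999
  residual: 1.0
lesion_params:
  biomarker:
  - subRPE_drusen
  - SDD
  - PED
  - HRF
  - vitelliform
  - refractile
  - iRORA
  - cRORA
  prevalence:
  - 0.94999999999999996
  - 0.5
  - 0.45000000000000001
  - 0.59999999999999998
  - 0.25
  - 0.25
  - 0.40000000000000002
  - 0.34999999999999998
  count_min:
  - 8.0
  - 10.0
  - 1.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  count_max:
  - 30.0
  - 35.0
  - 2.0
  - 12.0
  - 2.0
  - 3.0
  - 4.0
  - 2.0
  diameter_min_um:
  - 130.0
  - 80.0
  - 1000.0
  - 60.0
  - 200.0
  - 120.0
  - 100.0
  - 250.0
  diameter_max_um:
  - 500.0
  - 220.0
  - 2200.0
  - 200.0
  - 500.0
  - 350.0
  - 240.0
  - 900.0
  height_min_um:
  - 25.0
  - 15.0
  - 200.0
  - .na.real
  - .na.real
  - .na.real
  - .na.real
  - .na.real
  height_max_um:
  - 110.0
  - 50.0
  - 480.0
  - .na.real
  - .na.real
  - .na.real
  - .na.real
  - .na.real
  growth_um_per_year:
  - 25.0
  - 10.0
  - 60.0
  - 5.0
  - 20.0
  - 10.0
  - 15.0
  - 150.0
  onset:
  - baseline
  - baseline
  - baseline
  - baseline
  - baseline
  - followup
  - baseline
  - followup
sensitivity_range:
  floor: 0.0
  ceiling: 20.0
normative_mesopic:
  level: 14.0
  foveal_dip: 0.0
  dip_radius_deg: 1.0
  quadratic: 0.10000000000000001
normative_scotopic:
  level: 12.0
  foveal_dip: 1.5
  dip_radius_deg: 1.19999999999999996
  quadratic: 0.04
map_size_px: 256.0
field_of_view_deg: 30.0
um_per_deg: 288.0
layer_profiles:
  layer:
  - RNFL
  - GCL
  - IPL
  - INL
  - OPL
  - ONL
  - IS
  - OS
  - RPEDC
  a:
  - 5.0
  - 10.0
  - 20.0
  - 12.0
  - 18.0
  - 50.0
  - 25.0
  - 30.0
  - 25.0
  b:
  - 25.0
  - 25.0
  - 15.0
  - 18.0
  - 8.0
  - 40.0
  - 8.0
  - 15.0
  - 8.0
  c:
  - 12.0
  - 4.0
  - 3.0
  - 3.0
  - 2.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  d:
  - 8.0
  - 3.0
  - 3.0
  - 2.0
  - 2.0
  - 2.5
  - 3.0
  - 2.0
  - 3.0
  between_eye_sd_um:
  - 1.5
  - 2.5
  - 2.0
  - 2.0
  - 2.0
  - 5.0
  - 1.5
  - 2.5
  - 1.97999999999999998
pixel_noise_sd_um: 1.5
n_vessels: 8.0
landmark_noise_sd_deg: 0.05
lesion_field_deg: 6.0
generative_model: cross_sectional
reader_flip_prob: 0.0
grid:
  centers_x:
  - 1.0
  - 0.86602540378443871
  - 0.50000000000000011
  - 6.12323399573676604e-17
  - -4.99999999999999778e-01
  - -8.66025403784438708e-01
  - -1.0e+00
  - -8.66025403784438819e-01
  - -5.00000000000000444e-01
  - -1.83697019872102969e-16
  - 5.00000000000000111e-01
  - 8.66025403784438375e-01
  - 3.0e+00
  - 2.85316954888546048e+00
  - 2.42705098312484235e+00
  - 1.76335575687741941e+00
  - 9.27050983124842354e-01
  - 1.83697019872102969e-16
  - -9.27050983124842021e-01
  - -1.76335575687741919e+00
  - -2.42705098312484191e+00
  - -2.85316954888546048e+00
  - -3.0e+00
  - -2.85316954888546137e+00
  - -2.4270509831248428e+00
  - -1.76335575687741963e+00
  - -9.27050983124842687e-01
  - -5.51091059616308956e-16
  - 9.27050983124841688e-01
  - 1.76335575687741875e+00
  - 2.42705098312484191e+00
  - 2.85316954888546048e+00
  - 5.0e+00
  - 4.82962913144534145e+00
  - 4.33012701892219365e+00
  - 3.53553390593273775e+00
  - 2.50000000000000044e+00
  - 1.2940952255126037e+00
  - 3.06161699786838314e-16
  - -1.29409522551260325e+00
  - -2.49999999999999911e+00
  - -3.53553390593273731e+00
  - -4.33012701892219365e+00
  - -4.82962913144534056e+00
  - -5.0e+00
  - -4.82962913144534145e+00
  - -4.33012701892219454e+00
  - -3.53553390593273953e+00
  - -2.50000000000000222e+00
  - -1.29409522551260325e+00
  - -9.18485099360514794e-16
  - 1.29409522551260148e+00
  - 2.50000000000000044e+00
  - 3.53553390593273686e+00
  - 4.33012701892219187e+00
  - 4.82962913144534056e+00
  centers_y:
  - 0.0
  - 0.49999999999999994
  - 0.8660254037844386
  - 1.0
  - 0.86602540378443871
  - 0.49999999999999994
  - 1.22464679914735321e-16
  - -4.99999999999999722e-01
  - -8.66025403784438375e-01
  - -1.0e+00
  - -8.66025403784438597e-01
  - -5.00000000000000444e-01
  - 0.0e+00
  - 9.27050983124842132e-01
  - 1.76335575687741941e+00
  - 2.42705098312484235e+00
  - 2.85316954888546048e+00
  - 3.0e+00
  - 2.85316954888546093e+00
  - 2.42705098312484235e+00
  - 1.76335575687741963e+00
  - 9.27050983124842576e-01
  - 3.67394039744205938e-16
  - -9.27050983124840688e-01
  - -1.76335575687741919e+00
  - -2.42705098312484191e+00
  - -2.85316954888546048e+00
  - -3.0e+00
  - -2.85316954888546093e+00
  - -2.4270509831248428e+00
  - -1.76335575687742008e+00
  - -9.27050983124842798e-01
  - 0.0e+00
  - 1.2940952255126037e+00
  - 2.49999999999999956e+00
  - 3.53553390593273731e+00
  - 4.33012701892219276e+00
  - 4.82962913144534145e+00
  - 5.0e+00
  - 4.82962913144534145e+00
  - 4.33012701892219365e+00
  - 3.53553390593273775e+00
  - 2.49999999999999956e+00
  - 1.29409522551260503e+00
  - 6.12323399573676628e-16
  - -1.29409522551260392e+00
  - -2.49999999999999867e+00
  - -3.53553390593273553e+00
  - -4.33012701892219187e+00
  - -4.82962913144534145e+00
  - -5.0e+00
  - -4.82962913144534234e+00
  - -4.33012701892219276e+00
  - -3.53553390593273864e+00
  - -2.50000000000000222e+00
  - -1.29409522551260792e+00
  mesopic_diameter_deg: 0.42999999999999999
  scotopic_diameter_deg: 1.69999999999999996
  extraction_diameter_deg: 1.69999999999999996
seed: 1
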