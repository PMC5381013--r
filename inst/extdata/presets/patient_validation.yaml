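# Validation-like clinical cohort: same population as the derivation
# preset plus a 13 ms residual (non-blood-mediated) sex gap, so blood
# correction shrinks but does not eliminate the sex difference.
n: 200
seed: 1
male_fraction: 0.5
hct_mean_male: 42.0
hct_mean_female: 38.0
hct_sd_male: 4.0
hct_sd_female: 4.0
hct_bounds: [25.0, 57.0]
r1_intercept: 0.00024
r1_slope: 1.0e-5
r1_noise_sd: 1.0e-5
r1star_offset_mean: -3.0e-5
r1star_offset_sd: 3.0e-5
lv_rv_t1_offset: 20.0
tissue_t1_mean: 1008.0
tissue_t1_sd: 33.0
mbv_mean: 0.06
mbv_sd: 0.015
gamma_r1: -15000.0
gamma_r1star: -340000.0
residual_sex_gap: 13.0
noise_sd: 15.0
age_mean: 50.0
age_sd: 18.0
wall_mean_male: 11.0
wall_mean_female: 9.0
wall_sd: 2.0
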