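# Healthy-volunteer cohort: reduced between-subject blood variability
# (tighter hematocrit, blood-R1 noise and R1* offset spread), slightly
# more homogeneous tissue T1.  Correction applied to such a cohort is
# expected to yield no significant SD reduction.
n: 77
seed: 1
male_fraction: 0.49
hct_mean_male: 42.0
hct_mean_female: 38.0
hct_sd_male: 2.0
hct_sd_female: 2.0
hct_bounds: [25.0, 57.0]
r1_intercept: 0.00024
r1_slope: 1.0e-5
r1_noise_sd: 5.0e-6
r1star_offset_mean: -3.0e-5
r1star_offset_sd: 1.0e-5
lv_rv_t1_offset: 20.0
tissue_t1_mean: 1005.0
tissue_t1_sd: 31.5
mbv_mean: 0.06
mbv_sd: 0.015
gamma_r1: -15000.0
gamma_r1star: -340000.0
residual_sex_gap: 0.0
noise_sd: 15.0
age_mean: 49.0
age_sd: 14.0
wall_mean_male: 10.0
wall_mean_female: 9.0
wall_sd: 1.5
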