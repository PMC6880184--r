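# shared fixtures: reference parameter objects and a noise-free study config

ref_pk <- function() reference_pk_params()
ref_pd <- function() reference_emax_params()
ref_phys <- function() reference_physiology()

# all between-subject and residual variability switched off
zero_noise_config <- function() {
  base <- study_config()
  study_config(bsv = rapply(base$bsv, function(v) 0 * v, how = "replace"),
               residual = list(plasma = 0, sua = 0, urine = 0))
}

# noise-free single-dose profile at the SAD schedule (post-dose times only
# carry signal; time 0 is pre-dose)
ref_profile <- function(dose = 5) {
  reg <- dose_regimen(dose = dose)
  tt <- sad_blood_times()
  plasma_profile("ref", tt, pk_concentration(ref_pk(), reg, tt), reg)
}
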