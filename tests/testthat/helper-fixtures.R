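# Shared fixtures, all built in code.

tiny_config <- function(seed = 1, ...) {
  generator_config(n_practices = 6, patients_per_practice = 25, seed = seed, ...)
}

small_config <- function(seed = 1, ...) {
  generator_config(n_practices = 20, patients_per_practice = 40, seed = seed, ...)
}

# ~2,000 eligible episodes under the default (true marginal OR 1.25) design
calibration_config <- function(seed = 1, ...) {
  generator_config(n_practices = 42, patients_per_practice = 60, seed = seed, ...)
}

# ~20,000 eligible episodes
recovery_config <- function(seed = 1, ...) {
  generator_config(n_practices = 250, patients_per_practice = 92, seed = seed, ...)
}

# One-directional confounding (mode-model coefficients aligned in sign with
# the outcome model), no practice random effect and no mixed episodes, so the
# crude remote-vs-face-to-face contrast is heavily biased while parametric
# working models in the structural terms are exactly correct.
strong_confounding_config <- function(seed = 5, beta_a = 0.27) {
  generator_config(
    mode_model_coefs = c(
      intercept = 0.2, child = -0.5, age_std = 0.5, sex_male = -0.1,
      imd_c = 0.1, lrti = 1.5, sinusitis = 0.8, otitis_externa = 0.4,
      otitis_media = 1.5, covid = -1.5, urban = 0.5, registrar = -0.5
    ),
    outcome_model_coefs = c(
      intercept = -0.25, A = beta_a, child = -0.25, age_std = 0.3,
      sex_male = -0.05, imd_c = 0.1, lrti = 2.0, sinusitis = 0.6,
      otitis_externa = 0.5, otitis_media = 1.3, covid = -1.6,
      urban = -0.3, registrar = -0.5
    ),
    practice_random_effect_sd = 0, mixed_episode_fraction = 0, seed = seed
  )
}

# design matrix of the structural terms for a structural population draw
structural_design_matrix <- function(pop) {
  cbind(
    child = pop$child, age_std = (pop$age - 40) / 20, sex_male = pop$sex_male,
    imd_c = pop$imd - 3, lrti = pop$lrti, sinusitis = pop$sinusitis,
    otitis_externa = pop$otitis_externa, otitis_media = pop$otitis_media,
    covid = pop$covid, urban = pop$urban,
    registrar = as.integer(pop$clinician_role == "gp_registrar")
  )
}

# hand-written consultation rows for cohort unit tests
mk_cons <- function(patient_id, day, mode_marker, codes = "URTI",
                    role = "general_medical_practitioner") {
  tibble::tibble(
    patient_id = patient_id,
    date = as.Date("2021-06-01") + day,
    clinician_role = role, mode_marker = mode_marker, diagnosis_codes = codes
  )
}

with_ids <- function(cons) {
  dplyr::mutate(cons, consultation_id = sprintf("c%03d", dplyr::row_number()),
                .before = 1)
}

classified <- function(cons) {
  dplyr::mutate(cons, mode = classify_mode(cons$mode_marker))
}

# arm-level count fixture reproducing a two-arm stratified study layout
counts_fixture <- function(n_f2f, y_f2f, n_remote, y_remote, stratum) {
  tibble::tibble(
    A = rep(c(0L, 1L), c(n_f2f, n_remote)),
    Y = c(rep(c(1L, 0L), c(y_f2f, n_f2f - y_f2f)),
          rep(c(1L, 0L), c(y_remote, n_remote - y_remote))),
    stratum = stratum
  )
}
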