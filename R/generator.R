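# Synthetic primary-care EHR generator.
#
# The generator emulates the event-table structure of a UK primary-care
# research database: patients nested in practices, repeated GP consultations
# for acute respiratory infections (ARI) with remote / face-to-face / unknown
# mode markers, confounded mode assignment, antibiotic prescriptions linkable
# by ID or date, and a regional infection-prevalence time series. Its ground
# truth (the marginal ATE and odds ratio implied by its coefficients) is
# recoverable exactly by Monte-Carlo integration over the covariate law.

ARI_SUBTYPES <- c("urti", "lrti", "sinusitis", "otitis_externa", "otitis_media", "covid")

GP_ROLES <- c(
  "general_medical_practitioner", "salaried_gp", "gp_registrar",
  "locum_gp", "sessional_gp", "associate_practitioner_gp"
)
GP_ROLE_PROBS <- c(0.70, 0.14, 0.082, 0.040, 0.047, 0.011)

REGIONS <- c(
  "East Midlands", "East of England", "London", "North East", "North West",
  "South East", "South West", "West Midlands", "Yorkshire and the Humber"
)
REGION_PROBS <- c(0.025, 0.048, 0.198, 0.022, 0.238, 0.168, 0.094, 0.157, 0.050)

REMOTE_MARKERS <- c("telephone", "video", "sms", "internet")
F2F_MARKERS <- c("surgery", "home_visit")

# Columns of the structural design matrix shared by the mode and outcome
# models. Coefficient vectors are matched by name against these (plus "A"
# for the treatment coefficient in the outcome model).
STRUCTURAL_TERMS <- c(
  "intercept", "child", "age_std", "sex_male", "imd_c",
  "lrti", "sinusitis", "otitis_externa", "otitis_media", "covid",
  "urban", "registrar"
)

#' Default structural-model coefficients
#'
#' The generator's default logistic coefficients for the consultation-mode
#' model `P(remote | W)` and the prescribing outcome model `P(Y=1 | A, W)`,
#' on the logit scale. The outcome model's treatment coefficient default
#' (`beta_a = 0.27`) is calibrated so the implied true marginal odds ratio
#' is 1.25 (see [calibrate_treatment_coef()]).
#'
#' @param beta_a Treatment coefficient on the logit scale.
#' @return Named numeric coefficient vector.
#' @export
default_mode_coefs <- function() {
  c(
    intercept = 0.70, child = -0.75, age_std = 0.00, sex_male = -0.05,
    imd_c = 0.03, lrti = -0.30, sinusitis = 0.50, otitis_externa = -0.40,
    otitis_media = -1.00, covid = 0.30, urban = 0.35, registrar = -0.55
  )
}

#' @rdname default_mode_coefs
#' @export
default_outcome_coefs <- function(beta_a = 0.27) {
  c(
    intercept = -0.25, A = beta_a, child = -0.25, age_std = 0.08,
    sex_male = -0.05, imd_c = 0.04, lrti = 2.00, sinusitis = 0.60,
    otitis_externa = 0.50, otitis_media = 1.30, covid = -1.60,
    urban = -0.05, registrar = -0.15
  )
}

#' Configuration for the synthetic EHR generator
#'
#' Collects and validates every knob of the synthetic study: cohort size,
#' study window, the logistic structural models for consultation mode and
#' antibiotic prescribing, practice-level random effects, and the record-level
#' noise processes (repeat consultations, unknown mode markers, mixed-mode
#' episodes).
#'
#' The mode model gives `P(remote | W)` and the outcome model
#' `P(prescribed | A, W)` on the logit scale; both are linear in a fixed set
#' of named structural terms (`intercept`, `child`, `age_std` = (age-40)/20,
#' `sex_male`, `imd_c` = IMD quintile - 3, infection-subtype indicators with
#' URTI as reference, `urban`, `registrar`), and the outcome model
#' additionally takes the treatment coefficient `A`.
#'
#' @param n_practices Number of GP practices.
#' @param patients_per_practice Patients sampled per practice.
#' @param study_window Length-2 `Date` vector, analysis window (start < end).
#' @param mode_model_coefs Named numeric vector of mode-model coefficients.
#' @param outcome_model_coefs Named numeric vector of outcome-model
#'   coefficients, including the treatment coefficient `A`.
#' @param practice_random_effect_sd SD (logit scale) of the practice-level
#'   random intercepts; independent effects are drawn for the mode and the
#'   outcome model.
#' @param repeat_consultation_rate Expected number of extra same-episode
#'   consultation records per index consultation.
#' @param unknown_mode_fraction Fraction of face-to-face consultation records
#'   whose mode marker is replaced by `"unknown"`.
#' @param mixed_episode_fraction Fraction of episodes containing both a
#'   remote and a face-to-face record; mixed episodes are generated under
#'   exposure 0, matching the analysis-arm coding.
#' @param episodes_per_patient Poisson mean of index ARI consultations per
#'   patient inside the study window.
#' @param second_subtype_prob Probability a consultation carries a second
#'   ARI diagnosis code.
#' @param child_fraction Fraction of patients aged under 16.
#' @param background_consult_rate Non-ARI consultations per patient-year
#'   (feeds lookback covariates).
#' @param background_abx_rate Unrelated antibiotic prescriptions per
#'   patient-year.
#' @param imd_missing_fraction,sex_missing_fraction Fractions of patients
#'   with unrecorded IMD / sex (exercise the eligibility filters).
#' @param seed Root seed; all randomness is derived from it through named
#'   per-stage streams.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_practices = 5, patients_per_practice = 20, seed = 7)
#' @export
generator_config <- function(n_practices = 40,
                             patients_per_practice = 60,
                             study_window = as.Date(c("2021-04-01", "2022-03-22")),
                             mode_model_coefs = default_mode_coefs(),
                             outcome_model_coefs = default_outcome_coefs(),
                             practice_random_effect_sd = 0.25,
                             repeat_consultation_rate = 0.45,
                             unknown_mode_fraction = 0.10,
                             mixed_episode_fraction = 0.05,
                             episodes_per_patient = 0.9,
                             second_subtype_prob = 0.025,
                             child_fraction = 0.30,
                             background_consult_rate = 4,
                             background_abx_rate = 0.5,
                             imd_missing_fraction = 0.002,
                             sex_missing_fraction = 0.001,
                             seed = 1L) {
  cfg <- list(
    n_practices = n_practices, patients_per_practice = patients_per_practice,
    study_window = as.Date(study_window),
    mode_model_coefs = mode_model_coefs,
    outcome_model_coefs = outcome_model_coefs,
    practice_random_effect_sd = practice_random_effect_sd,
    repeat_consultation_rate = repeat_consultation_rate,
    unknown_mode_fraction = unknown_mode_fraction,
    mixed_episode_fraction = mixed_episode_fraction,
    episodes_per_patient = episodes_per_patient,
    second_subtype_prob = second_subtype_prob,
    child_fraction = child_fraction,
    background_consult_rate = background_consult_rate,
    background_abx_rate = background_abx_rate,
    imd_missing_fraction = imd_missing_fraction,
    sex_missing_fraction = sex_missing_fraction,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  err <- function(msg) abort(msg, class = "teletmle_config_error")
  if (!is.numeric(cfg$n_practices) || cfg$n_practices < 1) err("n_practices must be a positive integer")
  if (!is.numeric(cfg$patients_per_practice) || cfg$patients_per_practice < 1) {
    err("patients_per_practice must be a positive integer")
  }
  if (length(cfg$study_window) != 2 || anyNA(cfg$study_window)) err("study_window must be two dates")
  if (!(cfg$study_window[1] < cfg$study_window[2])) err("study_window start must precede end")
  for (p in c("unknown_mode_fraction", "mixed_episode_fraction", "child_fraction",
              "second_subtype_prob", "imd_missing_fraction", "sex_missing_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) err(paste0(p, " must lie in [0, 1]"))
  }
  for (p in c("practice_random_effect_sd", "repeat_consultation_rate",
              "episodes_per_patient", "background_consult_rate", "background_abx_rate")) {
    if (cfg[[p]] < 0) err(paste0(p, " must be nonnegative"))
  }
  check_coefs <- function(coefs, allow_a) {
    extra <- setdiff(names(coefs), c(STRUCTURAL_TERMS, if (allow_a) "A"))
    if (is.null(names(coefs)) || any(!nzchar(names(coefs))) || length(extra)) {
      err(paste0("unknown structural coefficient name(s): ",
                 paste(if (length(extra)) extra else "<unnamed>", collapse = ", ")))
    }
  }
  check_coefs(cfg$mode_model_coefs, allow_a = FALSE)
  check_coefs(cfg$outcome_model_coefs, allow_a = TRUE)
  if (!"A" %in% names(cfg$outcome_model_coefs)) err("outcome_model_coefs must name a treatment coefficient 'A'")
  invisible(cfg)
}

subtype_probs <- function(child) {
  adult <- c(urti = 0.500, lrti = 0.143, sinusitis = 0.118, otitis_externa = 0.060,
             otitis_media = 0.028, covid = 0.151)
  kid <- c(urti = 0.700, lrti = 0.058, sinusitis = 0.020, otitis_externa = 0.032,
           otitis_media = 0.101, covid = 0.089)
  if (child) kid else adult
}

draw_age <- function(child) {
  # children median ~4y (skewed young), adults median ~49y
  ifelse(child == 1, 16 * rbeta(length(child), 1.5, 3.5),
         16 + 84 * rbeta(length(child), 1.8, 2.8))
}

# Draw n episode-level structural covariate vectors from the generator's
# covariate law. Used identically by generate_study() and the Monte-Carlo
# truth oracle, so the oracle integrates over exactly the law the data follow.
draw_structural_covariates <- function(n, cfg, stratum = c("all", "adult", "child")) {
  stratum <- match.arg(stratum)
  child <- switch(stratum,
    all = rbinom(n, 1, cfg$child_fraction),
    adult = rep(0L, n),
    child = rep(1L, n)
  )
  age <- draw_age(child)
  sex_male <- rbinom(n, 1, ifelse(child == 1, 0.52, 0.37))
  imd <- sample(1:5, n, replace = TRUE)
  role <- sample(GP_ROLES, n, replace = TRUE, prob = GP_ROLE_PROBS)
  urban <- rbinom(n, 1, 0.85)
  u_mode <- rnorm(n, 0, cfg$practice_random_effect_sd)
  u_out <- rnorm(n, 0, cfg$practice_random_effect_sd)

  sub1 <- character(n)
  for (s in 0:1) {
    idx <- child == s
    if (any(idx)) {
      sub1[idx] <- sample(ARI_SUBTYPES, sum(idx), replace = TRUE,
                          prob = subtype_probs(s == 1)[ARI_SUBTYPES])
    }
  }
  has2 <- rbinom(n, 1, cfg$second_subtype_prob) == 1
  sub2 <- rep(NA_character_, n)
  if (any(has2)) {
    sub2[has2] <- vapply(sub1[has2], function(s1) sample(setdiff(ARI_SUBTYPES, s1), 1), character(1))
  }
  out <- tibble::tibble(
    child = child, age = age, sex_male = sex_male, imd = imd,
    clinician_role = role, urban = urban,
    subtype_1 = sub1, subtype_2 = sub2,
    u_mode = u_mode, u_out = u_out
  )
  for (s in ARI_SUBTYPES) {
    out[[s]] <- as.integer(out$subtype_1 == s | (!is.na(out$subtype_2) & out$subtype_2 == s))
  }
  out
}

structural_lp <- function(df, coefs, a = NULL) {
  x <- cbind(
    intercept = 1, child = df$child, age_std = (df$age - 40) / 20,
    sex_male = df$sex_male, imd_c = df$imd - 3,
    lrti = df$lrti, sinusitis = df$sinusitis,
    otitis_externa = df$otitis_externa, otitis_media = df$otitis_media,
    covid = df$covid, urban = df$urban,
    registrar = as.integer(df$clinician_role == "gp_registrar")
  )
  terms <- setdiff(names(coefs), "A")
  lp <- drop(x[, terms, drop = FALSE] %*% coefs[terms])
  if (!is.null(a)) lp <- lp + coefs[["A"]] * a
  lp
}

#' Draw an analysis-ready episode-level population from the structural law
#'
#' Bypasses the event-table machinery and draws episodes directly from the
#' generator's structural model: covariates, the true propensity of a remote
#' episode, exposure, potential-outcome probabilities, and the realised
#' outcome. Useful for estimator-focused simulations (bias, double
#' robustness) where the cohort-construction plumbing is not under study.
#'
#' @param config A [generator_config()].
#' @param n Number of episodes to draw.
#' @param stratum `"all"`, `"adult"` or `"child"`.
#' @return A tibble with covariates, `g_true` (true P(A=1|W) including the
#'   mixed-episode recoding), `p1`/`p0` (potential-outcome probabilities),
#'   exposure `A` and outcome `Y`.
#' @export
draw_structural_population <- function(config, n, stratum = "all") {
  stopifnot(inherits(config, "generator_config"), n >= 1)
  w <- draw_structural_covariates(n, config, stratum = stratum)
  p_mode <- expit(structural_lp(w, config$mode_model_coefs) + w$u_mode)
  mixed <- rbinom(n, 1, config$mixed_episode_fraction)
  a <- rbinom(n, 1, p_mode) * (1 - mixed)
  lp0 <- structural_lp(w, config$outcome_model_coefs, a = 0) + w$u_out
  beta_a <- config$outcome_model_coefs[["A"]]
  p0 <- expit(lp0)
  p1 <- expit(lp0 + beta_a)
  y <- rbinom(n, 1, ifelse(a == 1, p1, p0))
  dplyr::mutate(w,
    g_true = p_mode * (1 - config$mixed_episode_fraction),
    mixed = mixed, p1 = p1, p0 = p0, A = a, Y = y
  )
}

#' True marginal effects implied by a generator configuration
#'
#' Monte-Carlo oracle for the generator's causal ground truth: draws `n_mc`
#' covariate vectors from the covariate law (including the practice random
#' effect), evaluates both potential-outcome probabilities by setting the
#' exposure to 1 and 0 in the outcome model, and returns the marginal ATE,
#' the marginal odds ratio formed from the two mean potential-outcome
#' probabilities, and the Monte-Carlo standard error of the ATE.
#'
#' @param config A [generator_config()].
#' @param n_mc Number of Monte-Carlo draws (>= 1; >= 1e4 recommended).
#' @param stratum Population to integrate over: `"all"`, `"adult"`, `"child"`.
#' @return A `truth_params` tibble with columns `true_ate`, `true_or`,
#'   `mc_se`, `n_mc`, `stratum`.
#' @examples
#' cfg <- generator_config(seed = 1)
#' true_marginal_effects(cfg, n_mc = 1e4)
#' @export
true_marginal_effects <- function(config, n_mc = 1e5, stratum = "all") {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n_mc) || n_mc < 1) abort("n_mc must be a positive integer", class = "teletmle_config_error")
  with_stream_seed(config$seed, "mc", {
    w <- draw_structural_covariates(n_mc, config, stratum = stratum)
    lp0 <- structural_lp(w, config$outcome_model_coefs, a = 0) + w$u_out
    p0 <- expit(lp0)
    p1 <- expit(lp0 + config$outcome_model_coefs[["A"]])
    diff <- p1 - p0
    m1 <- mean(p1); m0 <- mean(p0)
    structure(
      tibble::tibble(
        true_ate = m1 - m0,
        true_or = marginal_or(m1, m0),
        mc_se = sd(diff) / sqrt(n_mc),
        n_mc = as.integer(n_mc),
        stratum = stratum
      ),
      class = c("truth_params", "tbl_df", "tbl", "data.frame")
    )
  })
}

#' Calibrate the treatment coefficient to a target marginal odds ratio
#'
#' Root-finds the outcome-model treatment coefficient so the generator's true
#' marginal odds ratio equals `target_or`, using common random numbers across
#' candidate values.
#'
#' @param config A [generator_config()].
#' @param target_or Target true marginal odds ratio (> 0).
#' @param n_mc Monte-Carlo draws used inside the root finder.
#' @param interval Search interval for the coefficient.
#' @return The calibrated coefficient (scalar).
#' @export
calibrate_treatment_coef <- function(config, target_or, n_mc = 2e5, interval = c(-3, 3)) {
  stopifnot(inherits(config, "generator_config"), target_or > 0)
  w <- with_stream_seed(config$seed, "mc", draw_structural_covariates(n_mc, config))
  lp0 <- structural_lp(w, config$outcome_model_coefs, a = 0) + w$u_out
  f <- function(b) {
    m1 <- mean(expit(lp0 + b)); m0 <- mean(expit(lp0))
    log(marginal_or(m1, m0)) - log(target_or)
  }
  stats::uniroot(f, interval, tol = 1e-8)$root
}

#' Generate a synthetic study as raw event tables
#'
#' Produces the five event tables (practices, patients, consultations,
#' prescriptions, regional prevalence) of a synthetic observational study of
#' remote versus face-to-face GP consultations for acute respiratory
#' infections. Consultation mode follows the configured logistic mode model
#' on the generated covariates plus a practice random effect; the antibiotic
#' prescribing outcome follows the configured outcome model. A configured
#' fraction of face-to-face records carry `"unknown"` mode markers, a
#' configured fraction of episodes mix both modes, and repeat records within
#' 7 days of the index consultation are injected at the configured rate.
#' A 365-day pre-window history of background (non-ARI) consultations and
#' unrelated prescriptions is always generated so lookback covariates are
#' computable at every index date.
#'
#' Identical configurations (including the seed) yield identical tables.
#'
#' @param config A [generator_config()].
#' @return An object of class `event_tables`: a named list of tibbles
#'   (`practices`, `patients`, `consultations`, `prescriptions`,
#'   `prevalence`) with the generating `config` and the latent episode frame
#'   attached as attributes.
#' @examples
#' tabs <- generate_study(generator_config(n_practices = 4, patients_per_practice = 10))
#' names(tabs)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  cfg <- config
  win <- cfg$study_window
  hist_start <- win[1] - 365

  practices <- with_stream_seed(cfg$seed, "practices", {
    n <- cfg$n_practices
    tibble::tibble(
      practice_id = sprintf("pr%04d", seq_len(n)),
      region = sample(REGIONS, n, replace = TRUE, prob = REGION_PROBS / sum(REGION_PROBS)),
      urban_flag = rbinom(n, 1, 0.85),
      list_size = round(exp(rnorm(n, log(12500), 0.45))),
      u_mode = rnorm(n, 0, cfg$practice_random_effect_sd),
      u_out = rnorm(n, 0, cfg$practice_random_effect_sd)
    )
  })

  patients <- with_stream_seed(cfg$seed, "patients", {
    n <- cfg$n_practices * cfg$patients_per_practice
    child <- rbinom(n, 1, cfg$child_fraction)
    age <- draw_age(child)
    sex <- ifelse(rbinom(n, 1, ifelse(child == 1, 0.52, 0.37)) == 1, "male", "female")
    sex[runif(n) < cfg$sex_missing_fraction] <- "unknown"
    imd <- sample(1:5, n, replace = TRUE)
    imd[runif(n) < cfg$imd_missing_fraction] <- NA_integer_
    eth <- sample(c("white", "mixed", "asian", "black", "other", "missing"),
                  n, replace = TRUE, prob = c(0.72, 0.02, 0.07, 0.03, 0.015, 0.145))
    tibble::tibble(
      patient_id = sprintf("pt%06d", seq_len(n)),
      practice_id = rep(practices$practice_id, each = cfg$patients_per_practice),
      birth_date = win[1] - round(age * 365.25),
      sex = sex, imd_quintile = imd, ethnicity = eth,
      asthma = rbinom(n, 1, ifelse(child == 1, 0.04, 0.17)),
      copd = as.integer(child == 0) * rbinom(n, 1, 0.05),
      depression = as.integer(child == 0) * rbinom(n, 1, 0.25),
      skin_condition = rbinom(n, 1, ifelse(child == 1, 0.31, 0.45)),
      obesity = rbinom(n, 1, ifelse(child == 1, 0.004, 0.13)),
      reg_start = hist_start - sample(0:365, n, replace = TRUE),
      reg_end = win[2] + 30
    )
  })
  pat_child <- as.integer((as.numeric(win[1] - patients$birth_date) / 365.25) < 16)

  # Latent episode frame: one row per index ARI consultation, carrying the
  # structural covariates, the drawn exposure and outcome. Index dates of one
  # patient are thinned to be >= 8 days apart so each row is one episode.
  latent <- with_stream_seed(cfg$seed, "episodes", {
    n_pat <- nrow(patients)
    k <- rpois(n_pat, cfg$episodes_per_patient)
    idx <- rep(seq_len(n_pat), k)
    n_ep <- length(idx)
    if (n_ep == 0) abort("configuration produced zero episodes", class = "teletmle_config_error")
    dates <- win[1] + sample(0:as.numeric(win[2] - win[1]), n_ep, replace = TRUE)
    ep <- tibble::tibble(pat_row = idx, index_date = dates) |>
      dplyr::arrange(.data$pat_row, .data$index_date) |>
      dplyr::group_by(.data$pat_row) |>
      dplyr::filter(keep_spaced(.data$index_date, 8)) |>
      dplyr::ungroup()
    n_ep <- nrow(ep)
    p <- patients[ep$pat_row, ]
    age_at <- as.numeric(win[1] - p$birth_date) / 365.25
    child <- pat_child[ep$pat_row]
    role <- sample(GP_ROLES, n_ep, replace = TRUE, prob = GP_ROLE_PROBS)
    sub1 <- character(n_ep)
    for (s in 0:1) {
      i <- child == s
      if (any(i)) sub1[i] <- sample(ARI_SUBTYPES, sum(i), replace = TRUE, prob = subtype_probs(s == 1))
    }
    has2 <- rbinom(n_ep, 1, cfg$second_subtype_prob) == 1
    sub2 <- rep(NA_character_, n_ep)
    if (any(has2)) {
      sub2[has2] <- vapply(sub1[has2], function(s1) sample(setdiff(ARI_SUBTYPES, s1), 1), character(1))
    }
    w <- tibble::tibble(
      child = child, age = age_at,
      sex_male = as.integer(p$sex == "male"),
      imd = dplyr::coalesce(p$imd_quintile, 3L),
      clinician_role = role,
      urban = practices$urban_flag[match(p$practice_id, practices$practice_id)],
      subtype_1 = sub1, subtype_2 = sub2
    )
    for (s in ARI_SUBTYPES) {
      w[[s]] <- as.integer(w$subtype_1 == s | (!is.na(w$subtype_2) & w$subtype_2 == s))
    }
    pr <- match(p$practice_id, practices$practice_id)
    p_mode <- expit(structural_lp(w, cfg$mode_model_coefs) + practices$u_mode[pr])
    mode_pure <- rbinom(n_ep, 1, p_mode)
    mixed <- rbinom(n_ep, 1, cfg$mixed_episode_fraction)
    a <- mode_pure * (1 - mixed)
    p_y <- expit(structural_lp(w, cfg$outcome_model_coefs, a = a) + practices$u_out[pr])
    y <- rbinom(n_ep, 1, p_y)
    dplyr::bind_cols(
      tibble::tibble(
        episode_key = seq_len(n_ep),
        patient_id = p$patient_id, practice_id = p$practice_id,
        index_date = ep$index_date,
        arm = a, mixed = mixed, p_mode = p_mode, p_y = p_y, y = y
      ),
      w
    )
  })

  consultations <- with_stream_seed(cfg$seed, "consultations", {
    n_ep <- nrow(latent)
    n_extra <- rpois(n_ep, cfg$repeat_consultation_rate)
    n_extra[latent$mixed == 1 & n_extra == 0] <- 1L
    codes <- ifelse(is.na(latent$subtype_2), toupper(latent$subtype_1),
                    paste(toupper(latent$subtype_1), toupper(latent$subtype_2), sep = ";"))
    base_mode <- ifelse(latent$arm == 1, "remote", "face_to_face")
    # mixed episodes were generated under exposure 0; their index record is
    # face-to-face and one injected extra record is remote
    idx_rec <- tibble::tibble(
      episode_key = latent$episode_key, patient_id = latent$patient_id,
      date = latent$index_date, clinician_role = latent$clinician_role,
      mode = base_mode, diagnosis_codes = codes
    )
    extra <- latent[rep(seq_len(n_ep), n_extra), ]
    if (nrow(extra)) {
      off <- sample(0:6, nrow(extra), replace = TRUE,
                    prob = c(0.75, 0.05, 0.05, 0.04, 0.04, 0.04, 0.03))
      first_of_ep <- !duplicated(extra$episode_key)
      mode_x <- ifelse(extra$arm == 1, "remote", "face_to_face")
      flip <- extra$mixed == 1 & first_of_ep
      mode_x[flip] <- "remote"
      off[flip] <- pmax(off[flip], 1L)  # mixed contact on a later day
      extra_rec <- tibble::tibble(
        episode_key = extra$episode_key, patient_id = extra$patient_id,
        date = extra$index_date + off, clinician_role = extra$clinician_role,
        mode = mode_x, diagnosis_codes = toupper(extra$subtype_1)
      )
    } else {
      extra_rec <- idx_rec[0, ]
    }
    # background non-ARI consultations over [window start - 365, window end]
    span_years <- as.numeric(win[2] - hist_start) / 365.25
    m <- rpois(nrow(patients), cfg$background_consult_rate * span_years)
    bg_idx <- rep(seq_len(nrow(patients)), m)
    bg <- tibble::tibble(
      episode_key = NA_integer_,
      patient_id = patients$patient_id[bg_idx],
      date = hist_start + sample(0:as.numeric(win[2] - hist_start), length(bg_idx), replace = TRUE),
      clinician_role = ifelse(runif(length(bg_idx)) < 0.7,
                              sample(GP_ROLES, length(bg_idx), replace = TRUE, prob = GP_ROLE_PROBS),
                              "practice_nurse"),
      mode = ifelse(runif(length(bg_idx)) < 0.4, "remote", "face_to_face"),
      diagnosis_codes = "OTHER"
    )
    all_rec <- dplyr::bind_rows(idx_rec, extra_rec, bg)
    marker <- character(nrow(all_rec))
    is_rem <- all_rec$mode == "remote"
    marker[is_rem] <- sample(REMOTE_MARKERS, sum(is_rem), replace = TRUE,
                             prob = c(0.78, 0.07, 0.05, 0.10))
    marker[!is_rem] <- sample(F2F_MARKERS, sum(!is_rem), replace = TRUE, prob = c(0.96, 0.04))
    marker[!is_rem & runif(nrow(all_rec)) < cfg$unknown_mode_fraction] <- "unknown"
    all_rec |>
      dplyr::mutate(mode_marker = marker) |>
      dplyr::arrange(.data$patient_id, .data$date) |>
      dplyr::mutate(consultation_id = sprintf("c%07d", dplyr::row_number())) |>
      dplyr::select("consultation_id", "patient_id", "date", "clinician_role",
                    "mode_marker", "diagnosis_codes", "episode_key")
  })

  prescriptions <- with_stream_seed(cfg$seed, "prescriptions", {
    rx_ep <- latent[latent$y == 1, ]
    id_linked <- runif(nrow(rx_ep)) < 0.2
    idx_cons <- consultations[!is.na(consultations$episode_key), ] |>
      dplyr::distinct(.data$episode_key, .keep_all = TRUE)
    link_id <- idx_cons$consultation_id[match(rx_ep$episode_key, idx_cons$episode_key)]
    ep_rx <- tibble::tibble(
      patient_id = rx_ep$patient_id,
      date = rx_ep$index_date + ifelse(id_linked, sample(1:7, nrow(rx_ep), replace = TRUE), 0L),
      antibiotic_flag = 1L,
      consultation_link_id = ifelse(id_linked, link_id, NA_character_)
    )
    # background antibiotic prescriptions, kept off ARI consultation dates so
    # they cannot leak into the outcome by the same-date linkage rule
    span_years <- as.numeric(win[2] - hist_start) / 365.25
    m <- rpois(nrow(patients), cfg$background_abx_rate * span_years)
    bg_idx <- rep(seq_len(nrow(patients)), m)
    bg_rx <- tibble::tibble(
      patient_id = patients$patient_id[bg_idx],
      date = hist_start + sample(0:as.numeric(win[2] - hist_start), length(bg_idx), replace = TRUE),
      antibiotic_flag = 1L,
      consultation_link_id = NA_character_
    ) |>
      dplyr::anti_join(
        consultations |>
          dplyr::filter(.data$diagnosis_codes != "OTHER") |>
          dplyr::distinct(.data$patient_id, .data$date),
        by = c("patient_id", "date")
      )
    # non-antibiotic prescriptions (flagged upstream, excluded by the linker)
    m2 <- rpois(nrow(patients), 1.0 * span_years)
    o_idx <- rep(seq_len(nrow(patients)), m2)
    other_rx <- tibble::tibble(
      patient_id = patients$patient_id[o_idx],
      date = hist_start + sample(0:as.numeric(win[2] - hist_start), length(o_idx), replace = TRUE),
      antibiotic_flag = 0L,
      consultation_link_id = NA_character_
    )
    dplyr::bind_rows(ep_rx, bg_rx, other_rx) |>
      dplyr::arrange(.data$patient_id, .data$date) |>
      dplyr::mutate(prescription_id = sprintf("rx%07d", dplyr::row_number())) |>
      dplyr::select("prescription_id", "patient_id", "date",
                    "antibiotic_flag", "consultation_link_id")
  })

  prevalence <- with_stream_seed(cfg$seed, "prevalence", {
    dates <- seq(hist_start, win[2] + 7, by = 7)
    phase <- runif(length(REGIONS), 0, 2 * pi)
    lev <- runif(length(REGIONS), 1.5, 2.2)
    tidyr::expand_grid(region = REGIONS, date = dates) |>
      dplyr::mutate(
        t = as.numeric(.data$date - .env$hist_start),
        infection_rate = round(pmax(
          0.15,
          lev[match(.data$region, REGIONS)] +
            1.3 * sin(2 * pi * .data$t / 365.25 + phase[match(.data$region, REGIONS)]) +
            rnorm(dplyr::n(), 0, 0.05)
        ), 3)
      ) |>
      dplyr::select("region", "date", "infection_rate")
  })

  structure(
    list(
      practices = dplyr::select(practices, -"u_mode", -"u_out"),
      patients = patients,
      consultations = dplyr::select(consultations, -"episode_key"),
      prescriptions = prescriptions,
      prevalence = prevalence
    ),
    class = "event_tables",
    config = cfg,
    latent_episodes = latent
  )
}

# keep dates greedily so consecutive kept dates are >= gap days apart
keep_spaced <- function(dates, gap) {
  n <- length(dates)
  keep <- logical(n)
  last <- -Inf
  d <- as.numeric(dates)
  for (i in seq_len(n)) {
    if (d[i] - last >= gap) {
      keep[i] <- TRUE
      last <- d[i]
    }
  }
  keep
}

#' Write / read event tables as CSV with a JSON sidecar
#'
#' Tables are written as plain CSV with ISO-8601 dates; a `manifest.json`
#' sidecar records the generator configuration and, if supplied, the
#' Monte-Carlo ground truth.
#'
#' @param tables An `event_tables` object.
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth_params` tibble to store alongside.
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(tables, dir, truth = NULL) {
  stopifnot(inherits(tables, "event_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  cfg <- attr(tables, "config")
  side <- list(
    config = lapply(unclass(cfg), function(x) if (inherits(x, "Date")) format(x) else x),
    truth = if (!is.null(truth)) as.list(truth)
  )
  jsonlite::write_json(side, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_event_tables
#' @export
read_event_tables <- function(dir) {
  date_cols <- list(
    patients = c("birth_date", "reg_start", "reg_end"),
    consultations = "date", prescriptions = "date", prevalence = "date"
  )
  tabs <- lapply(
    setNames(nm = c("practices", "patients", "consultations", "prescriptions", "prevalence")),
    function(nm) {
      df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")), stringsAsFactors = FALSE)
      for (dc in intersect(date_cols[[nm]], names(df))) df[[dc]] <- as.Date(df[[dc]])
      tibble::as_tibble(df)
    }
  )
  structure(tabs, class = "event_tables")
}
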