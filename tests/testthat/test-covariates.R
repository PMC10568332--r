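# Covariate engineering: lookback windows, practice rates, prevalence
# linkage, encoding.

lookback_fixture <- function() {
  ep <- tibble::tibble(
    episode_id = "e1", patient_id = "p1", index_date = as.Date("2021-06-01")
  )
  cons <- tibble::tibble(
    consultation_id = sprintf("c%02d", 1:5),
    patient_id = "p1",
    date = as.Date("2021-06-01") - c(0, 5, 20, 100, 400),
    clinician_role = "general_medical_practitioner",
    mode_marker = c("surgery", "telephone", "surgery", "telephone", "surgery"),
    diagnosis_codes = c("URTI", "URTI", "OTHER", "COVID", "URTI")
  )
  rx <- tibble::tibble(
    prescription_id = c("r1", "r2", "r3"),
    patient_id = "p1",
    date = as.Date("2021-06-01") - c(0, 6, 40),
    antibiotic_flag = c(1L, 1L, 1L),
    consultation_link_id = NA_character_
  )
  list(ep = ep, cons = cons, rx = rx)
}

test_that("lookback windows are half-open [index - w, index): same-day events never count", {
  f <- lookback_fixture()
  lb <- lookback_counts(f$ep, f$cons, f$rx)
  # the index-day consultation (lag 0) and the 400-day-old one are excluded
  expect_equal(lb$cons_all_7d, 1L)     # remote consult 5 days before
  expect_equal(lb$cons_remote_7d, 1L)
  expect_equal(lb$cons_all_30d, 2L)
  expect_equal(lb$cons_all_365d, 3L)
  expect_equal(lb$ari_all_30d, 1L)     # the OTHER-coded one is not ARI
  expect_equal(lb$ari_remote_365d, 2L)
  expect_equal(lb$covid_365d, 1L)      # COVID consult 100 days back
  expect_equal(lb$covid_30d, 0L)
  # same-day prescription excluded; 6-day and 40-day ones counted
  expect_equal(lb$abx_7d, 1L)
  expect_equal(lb$abx_30d, 1L)
  expect_equal(lb$abx_365d, 2L)
})

test_that("lookback counts nest across windows and are shift invariant", {
  tabs <- generate_study(small_config(seed = 13))
  coh <- build_cohort(tabs)
  ep <- coh$episodes
  lb <- lookback_counts(ep, tabs$consultations, tabs$prescriptions)
  for (f in c("cons_all", "cons_f2f", "cons_remote", "ari_all", "abx")) {
    expect_true(all(lb[[paste0(f, "_7d")]] <= lb[[paste0(f, "_30d")]]))
    expect_true(all(lb[[paste0(f, "_30d")]] <= lb[[paste0(f, "_365d")]]))
  }
  shift <- 37L
  lb2 <- lookback_counts(
    dplyr::mutate(ep, index_date = index_date + shift),
    dplyr::mutate(tabs$consultations, date = date + shift),
    dplyr::mutate(tabs$prescriptions, date = date + shift)
  )
  expect_equal(lb2, lb)
})

test_that("insufficient pre-index history raises a validation error", {
  f <- lookback_fixture()
  reg <- tibble::tibble(patient_id = "p1", reg_start = as.Date("2021-01-01"))
  expect_error(lookback_counts(f$ep, f$cons, f$rx, registrations = reg),
               class = "teletmle_validation_error")
})

test_that("practice rates follow direct arithmetic and scale inversely with list size", {
  idx <- as.Date("2021-06-01")
  ep <- tibble::tibble(episode_id = "e1", practice_id = "pr1", index_date = idx)
  # 10 patients registered over the full prior year -> 3650 patient-days
  pats <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10), practice_id = "pr1",
    reg_start = idx - 1000, reg_end = idx + 100
  )
  cons <- tibble::tibble(patient_id = "p01", date = idx - c(10, 50, 400),
                         antibiotic_flag = NA)
  rx <- tibble::tibble(patient_id = "p02", date = idx - c(30, 200),
                       antibiotic_flag = 1L)
  out <- practice_rates(ep, cons, rx, pats)
  expect_equal(out$practice_abx_rate_10k, 10000 * 2 / 3650)
  expect_equal(out$practice_cons_rate_10k, 10000 * 2 / 3650)
  # doubling the registered population halves the rates
  pats2 <- dplyr::bind_rows(pats, dplyr::mutate(pats, patient_id = paste0(patient_id, "b")))
  out2 <- practice_rates(ep, cons, rx, pats2)
  expect_equal(out2$practice_abx_rate_10k, out$practice_abx_rate_10k / 2)
  # zero patient-days errors
  pats3 <- dplyr::mutate(pats, reg_start = idx + 1)
  expect_error(practice_rates(ep, cons, rx, pats3), class = "teletmle_validation_error")
})

test_that("practice rates match a brute-force day-by-day tally on a ragged fixture", {
  set.seed(99)
  idx <- as.Date("2021-06-01") + c(0, 31)
  ep <- tibble::tibble(episode_id = c("e1", "e2"), practice_id = "pr1", index_date = idx)
  pats <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:6), practice_id = "pr1",
    reg_start = as.Date("2020-01-01") + sample(0:400, 6),
    reg_end = as.Date("2021-03-01") + sample(0:200, 6)
  )
  cons <- tibble::tibble(patient_id = sample(pats$patient_id, 40, replace = TRUE),
                         date = as.Date("2020-05-01") + sample(0:400, 40, replace = TRUE))
  rx <- tibble::tibble(patient_id = sample(pats$patient_id, 25, replace = TRUE),
                       date = as.Date("2020-05-01") + sample(0:400, 25, replace = TRUE),
                       antibiotic_flag = rbinom(25, 1, 0.7))
  out <- practice_rates(ep, cons, rx, pats)
  for (i in 1:2) {
    days <- seq(idx[i] - 365, idx[i] - 1, by = "day")
    pdays <- sum(vapply(days, function(d) sum(pats$reg_start <= d & pats$reg_end >= d), numeric(1)))
    n_cons <- sum(cons$date %in% days)
    n_abx <- sum(rx$date[rx$antibiotic_flag == 1] %in% days)
    expect_equal(out$practice_cons_rate_10k[i], 10000 * n_cons / pdays)
    expect_equal(out$practice_abx_rate_10k[i], 10000 * n_abx / pdays)
  }
})

test_that("prevalence joins as a step function carried forward from the last series date", {
  ep <- tibble::tibble(
    episode_id = c("e1", "e2", "e3"), practice_id = "pr1",
    index_date = as.Date(c("2021-06-07", "2021-06-10", "2021-06-14"))
  )
  practices <- tibble::tibble(practice_id = "pr1", region = "London")
  prev <- tibble::tibble(
    region = "London",
    date = as.Date(c("2021-06-07", "2021-06-14")),
    infection_rate = c(1.64, 2.10)
  )
  out <- join_prevalence(ep, prev, practices)
  expect_equal(out$infection_rate, c(1.64, 1.64, 2.10))
  expect_error(
    join_prevalence(ep, dplyr::mutate(prev, region = "Wessex"), practices),
    class = "teletmle_validation_error"
  )
  early <- dplyr::mutate(ep, index_date = as.Date("2021-06-01"))
  expect_error(join_prevalence(early, prev, practices),
               class = "teletmle_validation_error")
})

test_that("the covariate matrix is complete, one row per episode, and encodes reversibly", {
  tabs <- generate_study(small_config(seed = 17))
  coh <- build_cohort(tabs)
  W <- build_covariates(coh, tabs)
  expect_equal(nrow(W), nrow(coh$episodes))
  expect_false(anyNA(W))
  schema <- attr(W, "schema")
  expect_true(all(c("column", "role", "reference_level") %in% names(schema)))
  enc <- encode_covariates(W)
  expect_false(anyNA(enc$x))
  expect_equal(nrow(enc$x), nrow(W))
  dec <- decode_covariates(enc)
  for (cl in names(dec)) {
    expect_equal(dec[[cl]], as.character(W[[cl]]), info = cl)
  }
  # child stratum drops adult-only comorbidity columns
  kids <- W[W$stratum == "child", ]
  attr(kids, "schema") <- schema
  enc_child <- encode_covariates(kids, stratum = "child")
  expect_false(any(c("copd", "depression") %in% colnames(enc_child$x)))
  expect_true("asthma" %in% colnames(enc_child$x))
})

test_that("column order is deterministic across rebuilds", {
  tabs <- generate_study(tiny_config(seed = 19))
  coh <- build_cohort(tabs)
  W1 <- build_covariates(coh, tabs)
  W2 <- build_covariates(coh, tabs)
  expect_identical(names(W1), names(W2))
  expect_identical(W1, W2)
})
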