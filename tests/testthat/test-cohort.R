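# Cohort construction rules: mode classification, GP/ARI filtering, 7-day
# episode grouping, prescription linkage, eligibility.

test_that("mode markers classify as remote or face-to-face, with unknown assumed face-to-face", {
  expect_equal(classify_mode("telephone"), "remote")
  expect_equal(classify_mode(c("video", "sms", "internet")), rep("remote", 3))
  expect_equal(classify_mode("surgery"), "face_to_face")
  expect_equal(classify_mode("home_visit"), "face_to_face")
  expect_equal(classify_mode("unknown"), "face_to_face")
  err <- expect_error(classify_mode(c("telephone", "carrier_pigeon")),
                      class = "teletmle_validation_error")
  expect_match(conditionMessage(err), "carrier_pigeon")
})

test_that("only GP consultations with an ARI code survive the filter", {
  cons <- with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone", "URTI"),
    mk_cons("p2", 0, "telephone", "URTI", role = "practice_nurse"),
    mk_cons("p3", 0, "surgery", "OTHER"),
    mk_cons("p4", 0, "surgery", "OTHER;LRTI")
  ))
  kept <- filter_gp_ari(cons)
  expect_setequal(kept$patient_id, c("p1", "p4"))
  expect_equal(kept$diagnosis_codes[kept$patient_id == "p4"], "OTHER;LRTI")
  expect_error(filter_gp_ari(cons, ari_code_set = character()),
               class = "teletmle_validation_error")
})

test_that("consultations within 7 days group into one episode keeping the first date", {
  cons <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone"), mk_cons("p1", 3, "video"), mk_cons("p1", 6, "sms")
  )))
  ep <- group_episodes(cons)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$index_date, as.Date("2021-06-01"))
  expect_equal(ep$mode, "remote")
  expect_equal(ep$A, 1L)
})

test_that("a consultation 8 days on opens a second episode; anchored grouping does not chain", {
  cons <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone"), mk_cons("p1", 8, "telephone")
  )))
  expect_equal(nrow(group_episodes(cons)), 2)
  # day 6 joins the day-0 episode; day 12 opens a new one even though it is
  # within 7 days of day 6
  chain <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "surgery"), mk_cons("p1", 6, "surgery"), mk_cons("p1", 12, "surgery")
  )))
  expect_equal(nrow(group_episodes(chain)), 2)
  expect_equal(nrow(group_episodes(chain, method = "rolling")), 1)
})

test_that("episodes mixing both modes are coded mixed and analysed in arm 0, with subtypes unioned", {
  cons <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone", "URTI"), mk_cons("p1", 2, "surgery", "LRTI")
  )))
  ep <- group_episodes(cons)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$mode, "mixed")
  expect_equal(ep$A, 0L)
  expect_equal(ep$infection_subtypes, "LRTI;URTI")
})

test_that("grouping partitions the consultations and is idempotent", {
  tabs <- generate_study(small_config(seed = 21))
  gp <- filter_gp_ari(tabs$consultations)
  gp <- dplyr::mutate(gp, mode = classify_mode(gp$mode_marker))
  ep <- group_episodes(gp)
  asg <- attr(ep, "assignments")
  expect_equal(nrow(asg), nrow(gp))
  expect_equal(dplyr::n_distinct(asg$consultation_id), nrow(gp))
  expect_lte(nrow(ep), nrow(gp))
  # regrouping the index records changes nothing
  idx <- dplyr::mutate(ep,
    consultation_id = ep$episode_id, date = ep$index_date,
    diagnosis_codes = ep$infection_subtypes,
    mode = ifelse(ep$mode == "mixed", "face_to_face", ep$mode))
  re <- group_episodes(idx)
  expect_equal(nrow(re), nrow(ep))
  expect_equal(re$index_date, ep$index_date)
  # episode windows of one patient never overlap
  spans <- ep |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(index_date)) >= 7), .groups = "drop")
  expect_true(all(spans$ok))
})

test_that("antibiotics link by consultation ID or same-date issue, and only those", {
  cons <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone"),
    mk_cons("p2", 0, "surgery"),
    mk_cons("p3", 0, "surgery")
  )))
  ep <- group_episodes(cons)
  rx <- tibble::tibble(
    prescription_id = c("r1", "r2", "r3", "r4"),
    patient_id = c("p1", "p2", "p3", "p3"),
    date = as.Date("2021-06-01") + c(10, 0, 3, 0),
    antibiotic_flag = c(1L, 1L, 1L, 0L),
    consultation_link_id = c("c001", NA, NA, NA)
  )
  out <- link_prescriptions(ep, rx)
  y <- setNames(out$Y, out$patient_id)
  expect_equal(y[["p1"]], 1L)  # ID link despite a different date
  expect_equal(y[["p2"]], 1L)  # same-date link without an ID
  expect_equal(y[["p3"]], 0L)  # 3 days later, no link path; non-antibiotic ignored
  bad <- dplyr::mutate(rx, patient_id = c("p1", "p2", "ghost", "p3"))
  expect_error(
    link_prescriptions(ep, bad, patients = tibble::tibble(patient_id = c("p1", "p2", "p3"))),
    class = "teletmle_validation_error"
  )
})

test_that("eligibility drops missing IMD or sex, restricts the window, and assigns strata at age 16", {
  cons <- classified(with_ids(dplyr::bind_rows(
    mk_cons("p1", 0, "telephone"), mk_cons("p2", 0, "telephone"),
    mk_cons("p3", 0, "telephone"), mk_cons("p4", 0, "telephone"),
    mk_cons("p5", 200, "telephone")
  )))
  ep <- link_prescriptions(group_episodes(cons), tibble::tibble(
    prescription_id = character(), patient_id = character(),
    date = as.Date(character()), antibiotic_flag = integer(),
    consultation_link_id = character()
  ))
  idx <- as.Date("2021-06-01")
  pats <- tibble::tibble(
    patient_id = paste0("p", 1:5),
    practice_id = "pr1",
    birth_date = c(idx - round(15.9 * 365.25), idx - round(16.0 * 365.25) - 1,
                   idx - 40 * 365, idx - 40 * 365, idx - 40 * 365),
    sex = c("female", "male", "unknown", "male", "male"),
    imd_quintile = c(2L, 3L, 1L, NA, 2L)
  )
  out <- apply_eligibility(ep, pats, window = as.Date(c("2021-04-01", "2021-12-01")))
  expect_setequal(out$patient_id, c("p1", "p2"))  # p3 sex, p4 IMD, p5 window
  expect_equal(out$stratum[out$patient_id == "p1"], "child")
  expect_equal(out$stratum[out$patient_id == "p2"], "adult")
  sens <- apply_eligibility(dplyr::mutate(ep, mode = "mixed"), pats, drop_mixed = TRUE)
  expect_equal(nrow(sens), 0)
})

test_that("the attrition flow is monotone nonincreasing and mixed episodes vanish under the sensitivity flag", {
  tabs <- generate_study(small_config(seed = 31))
  coh <- build_cohort(tabs)
  expect_true(all(diff(coh$attrition$n) <= 0))
  expect_true(all(coh$episodes$mode %in% c("remote", "face_to_face", "mixed")))
  expect_true(all(coh$episodes$A[coh$episodes$mode != "remote"] == 0))
  expect_true(all(coh$episodes$A[coh$episodes$mode == "remote"] == 1))
  sens <- build_cohort(tabs, drop_mixed = TRUE)
  expect_false(any(sens$episodes$mode == "mixed"))
  expect_lte(nrow(sens$episodes), nrow(coh$episodes))
})

test_that("the cohort reproduces the generator's latent episodes", {
  tabs <- generate_study(small_config(seed = 41))
  lat <- attr(tabs, "latent_episodes")
  coh <- build_cohort(tabs)
  ep <- coh$episodes
  key <- dplyr::inner_join(
    dplyr::select(ep, "patient_id", "index_date", "A", "Y"),
    dplyr::select(lat, "patient_id", "index_date", arm = "arm", y_true = "y"),
    by = c("patient_id", "index_date")
  )
  expect_gt(nrow(key) / nrow(ep), 0.99)
  expect_equal(key$A, key$arm)
  expect_equal(key$Y, key$y_true)
})
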