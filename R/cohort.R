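# Cohort construction: raw event tables -> analysis episodes.
#
# Rules implemented here: GP-only ARI consultations; remote/face-to-face
# classification with unknown modes assumed face-to-face; 7-day grouping of a
# patient's ARI consultations anchored at the first consultation date;
# antibiotic linkage by explicit consultation ID or same-date issue;
# eligibility filters (recorded sex, recorded IMD, index date in window);
# adult/child strata split at age 16.

MODE_VOCAB <- list(
  remote = c("telephone", "video", "sms", "internet"),
  face_to_face = c("surgery", "home_visit"),
  unknown = "unknown"
)

#' Classify consultation mode markers as remote or face-to-face
#'
#' Telephone, video, SMS and internet markers are remote; surgery and
#' home-visit markers are face-to-face; consultations whose mode is unclear
#' (`"unknown"`) are assumed to be face-to-face.
#'
#' @param mode_marker Character vector of raw mode markers.
#' @return Character vector with values `"remote"` or `"face_to_face"`.
#' @examples
#' classify_mode(c("telephone", "unknown", "home_visit"))
#' @export
classify_mode <- function(mode_marker) {
  bad <- setdiff(unique(mode_marker), unlist(MODE_VOCAB))
  if (length(bad)) {
    abort(paste0("unrecognized mode marker(s): ", paste(bad, collapse = ", ")),
          class = "teletmle_validation_error")
  }
  ifelse(mode_marker %in% MODE_VOCAB$remote, "remote", "face_to_face")
}

parse_codes <- function(x) strsplit(x, ";", fixed = TRUE)

#' Keep GP consultations carrying at least one ARI diagnosis code
#'
#' Only consultations carried out by a GP role and carrying at least one code
#' from `ari_code_set` are kept; all recorded diagnosis codes stay on the
#' record.
#'
#' @param consultations Consultation tibble with `clinician_role` and
#'   semicolon-separated `diagnosis_codes`.
#' @param ari_code_set Character vector of ARI codes.
#' @param gp_roles Character vector of clinician roles counted as GP.
#' @return The filtered consultation tibble.
#' @export
filter_gp_ari <- function(consultations, ari_code_set = toupper(ARI_SUBTYPES),
                          gp_roles = GP_ROLES) {
  if (length(ari_code_set) == 0) {
    abort("ari_code_set must not be empty", class = "teletmle_validation_error")
  }
  codes <- parse_codes(consultations$diagnosis_codes)
  has_ari <- vapply(codes, function(cc) any(cc %in% ari_code_set), logical(1))
  dplyr::filter(consultations, .data$clinician_role %in% gp_roles, has_ari)
}

# anchored: a consultation joins the open episode iff date - index < window
# rolling:  ... iff date - previous consultation date < window
episode_index_per_patient <- function(dates, window_days, method) {
  d <- as.numeric(dates)
  n <- length(d)
  g <- integer(n)
  gi <- 0L
  ref <- -Inf
  for (i in seq_len(n)) {
    if (d[i] - ref >= window_days) {
      gi <- gi + 1L
      ref <- d[i]
    } else if (method == "rolling") {
      ref <- d[i]
    }
    g[i] <- gi
  }
  g
}

#' Group ARI consultations into episodes
#'
#' Per patient, chronological greedy grouping: the first ungrouped
#' consultation opens an episode at its date, and every later consultation
#' strictly within `window_days` of the episode's index date joins it
#' (same-day records always share an episode). The episode keeps the date of
#' the first consultation; its mode is the common classified mode or
#' `"mixed"` when both occur; infection subtypes are unioned across grouped
#' records. The analysis arm codes pure-remote episodes as 1 and
#' face-to-face or mixed episodes as 0.
#'
#' @param consultations GP ARI consultation tibble; must carry a classified
#'   `mode` column (see [classify_mode()]).
#' @param window_days Episode window length in days (default 7: days 0-6
#'   join the episode).
#' @param method `"anchored"` (default; greedy from the index date) or
#'   `"rolling"` (chains from the most recent grouped consultation).
#' @return Episode tibble (`episode_id`, `patient_id`, `index_date`, `mode`,
#'   `A`, `n_consultations`, `infection_subtypes`, `clinician_role` of the
#'   index record), with the consultation-to-episode assignment attached as
#'   attribute `"assignments"`.
#' @export
group_episodes <- function(consultations, window_days = 7,
                           method = c("anchored", "rolling")) {
  method <- match.arg(method)
  if (!"mode" %in% names(consultations)) {
    abort("consultations must carry a classified 'mode' column", class = "teletmle_validation_error")
  }
  if (nrow(consultations) == 0) {
    ep <- tibble::tibble(
      episode_id = character(), patient_id = character(),
      index_date = as.Date(character()), mode = character(), A = integer(),
      n_consultations = integer(), infection_subtypes = character(),
      clinician_role = character()
    )
    attr(ep, "assignments") <- tibble::tibble(consultation_id = character(), episode_id = character())
    return(ep)
  }
  cons <- consultations |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(ep_local = episode_index_per_patient(.data$date, window_days, method)) |>
    dplyr::ungroup() |>
    dplyr::mutate(episode_id = paste0(.data$patient_id, "_e", .data$ep_local))
  episodes <- cons |>
    dplyr::group_by(.data$patient_id, .data$episode_id) |>
    dplyr::summarise(
      index_date = min(.data$date),
      mode = if (dplyr::n_distinct(.data$mode) > 1) "mixed" else .data$mode[1],
      n_consultations = dplyr::n(),
      infection_subtypes = paste(
        sort(unique(unlist(parse_codes(.data$diagnosis_codes)))), collapse = ";"),
      clinician_role = .data$clinician_role[which.min(.data$date)],
      .groups = "drop"
    ) |>
    dplyr::mutate(A = as.integer(.data$mode == "remote")) |>
    dplyr::arrange(.data$patient_id, .data$index_date) |>
    dplyr::select("episode_id", "patient_id", "index_date", "mode", "A",
                  "n_consultations", "infection_subtypes", "clinician_role")
  attr(episodes, "assignments") <-
    dplyr::select(cons, "consultation_id", "episode_id", "date", "patient_id")
  episodes
}

#' Link antibiotic prescriptions to episodes and set the outcome
#'
#' An episode's outcome is 1 if any antibiotic prescription links to one of
#' its grouped consultations by explicit consultation ID, or was issued on
#' the same date as any of its grouped consultations.
#'
#' @param episodes Episode tibble from [group_episodes()].
#' @param prescriptions Prescription tibble (`patient_id`, `date`,
#'   `antibiotic_flag`, optional `consultation_link_id`); only rows with
#'   `antibiotic_flag == 1` are used.
#' @param patients Optional patient table; if supplied, prescriptions naming
#'   a patient absent from it raise a validation error.
#' @param assignments Consultation-to-episode map; defaults to the
#'   `"assignments"` attribute of `episodes`.
#' @return `episodes` with an integer outcome column `Y`.
#' @export
link_prescriptions <- function(episodes, prescriptions, patients = NULL,
                               assignments = attr(episodes, "assignments")) {
  if (is.null(assignments)) {
    abort("episodes must carry a consultation assignment map", class = "teletmle_validation_error")
  }
  if (!is.null(patients)) {
    bad <- setdiff(unique(prescriptions$patient_id), patients$patient_id)
    if (length(bad)) {
      abort(paste0("prescriptions reference unknown patient(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "teletmle_validation_error")
    }
  }
  abx <- dplyr::filter(prescriptions, .data$antibiotic_flag == 1)
  by_id <- abx |>
    dplyr::filter(!is.na(.data$consultation_link_id)) |>
    dplyr::inner_join(assignments, by = c(consultation_link_id = "consultation_id"),
                      suffix = c("", ".cons")) |>
    dplyr::distinct(.data$episode_id)
  by_date <- abx |>
    dplyr::inner_join(assignments, by = c("patient_id", "date")) |>
    dplyr::distinct(.data$episode_id)
  hit <- unique(c(by_id$episode_id, by_date$episode_id))
  out <- dplyr::mutate(episodes, Y = as.integer(.data$episode_id %in% hit))
  attr(out, "assignments") <- assignments
  out
}

#' Apply patient- and window-level eligibility to episodes
#'
#' Drops episodes of patients with unrecorded sex or missing IMD, restricts
#' index dates to the analysis window, attaches practice ID, fractional age
#' at index, and the adult/child stratum (child = age at index under 16
#' completed years).
#'
#' @param episodes Episode tibble.
#' @param patients Patient table (`patient_id`, `practice_id`, `birth_date`,
#'   `sex`, `imd_quintile`).
#' @param window Length-2 `Date` vector; episodes with `index_date` outside
#'   it are dropped. `NULL` keeps all.
#' @param drop_mixed Drop mixed-mode episodes (sensitivity analysis) instead
#'   of analysing them in the face-to-face arm.
#' @return The filtered, annotated episode tibble.
#' @export
apply_eligibility <- function(episodes, patients, window = NULL, drop_mixed = FALSE) {
  assignments <- attr(episodes, "assignments")
  out <- episodes |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "practice_id", "birth_date",
                    "sex", "imd_quintile"),
      by = "patient_id"
    ) |>
    dplyr::filter(.data$sex %in% c("male", "female"), !is.na(.data$imd_quintile)) |>
    dplyr::mutate(
      age_at_index = as.numeric(.data$index_date - .data$birth_date) / 365.25,
      stratum = ifelse(floor(.data$age_at_index) < 16, "child", "adult")
    )
  if (!is.null(window)) {
    window <- as.Date(window)
    out <- dplyr::filter(out, .data$index_date >= window[1], .data$index_date <= window[2])
  }
  if (drop_mixed) out <- dplyr::filter(out, .data$mode != "mixed")
  out <- dplyr::select(out, -"birth_date")
  attr(out, "assignments") <- assignments
  out
}

#' Build the analysis cohort from raw event tables
#'
#' End-to-end cohort construction: classify consultation modes, keep GP ARI
#' consultations, group them into 7-day episodes, link antibiotic
#' prescriptions, and apply eligibility. An attrition flow (row counts at
#' each stage) is always recorded.
#'
#' @param tables An `event_tables` list (see [generate_study()] /
#'   [read_event_tables()]).
#' @param window Analysis window (`Date` length 2); defaults to the
#'   generating config's study window when present, else the consultation
#'   date range.
#' @param episode_window_days Episode grouping window (default 7).
#' @param drop_mixed Exclude mixed-mode episodes (sensitivity analysis).
#' @param grouping `"anchored"` or `"rolling"` (see [group_episodes()]).
#' @param ari_code_set ARI diagnosis codes defining an ARI consultation.
#' @return An object of class `cohort`: list with `episodes` (tibble) and
#'   `attrition` (stage/count tibble).
#' @examples
#' tabs <- generate_study(generator_config(n_practices = 4, patients_per_practice = 15))
#' coh <- build_cohort(tabs)
#' coh$attrition
#' @export
build_cohort <- function(tables, window = NULL, episode_window_days = 7,
                         drop_mixed = FALSE, grouping = "anchored",
                         ari_code_set = toupper(ARI_SUBTYPES)) {
  cfg <- attr(tables, "config")
  if (is.null(window)) {
    window <- if (!is.null(cfg)) cfg$study_window else range(tables$consultations$date)
  }
  cons <- tables$consultations
  gp_ari <- filter_gp_ari(cons, ari_code_set)
  gp_ari <- dplyr::mutate(gp_ari, mode = classify_mode(.data$mode_marker))
  n_same_day <- nrow(dplyr::distinct(gp_ari, .data$patient_id, .data$date))
  episodes <- group_episodes(gp_ari, window_days = episode_window_days, method = grouping)
  episodes <- link_prescriptions(episodes, tables$prescriptions, patients = tables$patients)
  eligible <- apply_eligibility(episodes, tables$patients, window = window,
                                drop_mixed = drop_mixed)
  attrition <- tibble::tibble(
    stage = c("consultations_raw", "gp_ari_consultations", "same_day_groups",
              "episodes_7day", "episodes_eligible"),
    n = c(nrow(cons), nrow(gp_ari), n_same_day, nrow(episodes), nrow(eligible))
  )
  structure(
    list(episodes = eligible, attrition = attrition,
         window = as.Date(window), drop_mixed = drop_mixed),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<teletmle cohort>\n")
  cat("  window:", format(x$window[1]), "to", format(x$window[2]), "\n")
  cat("  attrition:\n")
  for (i in seq_len(nrow(x$attrition))) {
    cat(sprintf("    %-24s %8d\n", x$attrition$stage[i], x$attrition$n[i]))
  }
  invisible(x)
}
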