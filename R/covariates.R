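# Covariate engineering: the per-episode design matrix W used by both the
# treatment (propensity) and outcome models. Patient, clinician, practice and
# temporal covariates; lookback windows are half-open [index - w, index), so
# the index consultation and same-day events never count themselves.

LOOKBACK_WINDOWS <- c(7L, 30L, 365L)

ADULT_COMORBIDITIES <- c("asthma", "copd", "depression", "skin_condition", "obesity")
CHILD_COMORBIDITIES <- c("asthma", "skin_condition", "obesity")

#' Lookback event counts per episode
#'
#' Counts, for every episode and every window `w`, the events with date in
#' `[index_date - w, index_date)` — strictly before the index date. The full
#' grid is emitted: consultations (all / face-to-face / remote), ARI
#' consultations (all / face-to-face / remote), antibiotic prescriptions, and
#' a binary recorded-COVID flag, each over 7 / 30 / 365 days.
#'
#' @param episodes Episode tibble (`episode_id`, `patient_id`, `index_date`).
#' @param consultations Full consultation table; a classified `mode` column
#'   is added from `mode_marker` when absent.
#' @param prescriptions Prescription table (`antibiotic_flag`).
#' @param windows Integer lookback windows in days.
#' @param ari_code_set Codes defining an ARI consultation.
#' @param registrations Optional tibble (`patient_id`, `reg_start`); when
#'   supplied, an episode whose registration does not cover the longest
#'   lookback raises a validation error.
#' @return Tibble keyed by `episode_id` with one count column per
#'   window-by-filter cell (e.g. `cons_remote_30d`, `abx_365d`,
#'   `covid_7d`).
#' @export
lookback_counts <- function(episodes, consultations, prescriptions,
                            windows = LOOKBACK_WINDOWS,
                            ari_code_set = toupper(ARI_SUBTYPES),
                            registrations = NULL) {
  stopifnot(all(windows > 0))
  wmax <- max(windows)
  if (!is.null(registrations)) {
    chk <- dplyr::inner_join(episodes, registrations, by = "patient_id")
    late <- chk$reg_start > chk$index_date - wmax
    if (any(late)) {
      abort(sprintf("%d episode(s) lack %d days of history before index", sum(late), wmax),
            class = "teletmle_validation_error")
    }
  }
  if (!"mode" %in% names(consultations)) {
    consultations <- dplyr::mutate(consultations, mode = classify_mode(.data$mode_marker))
  }
  has_code <- function(x, code) {
    # codes are ";"-separated tokens; pad so fixed matching is exact
    grepl(paste0(";", code, ";"), paste0(";", x, ";"), fixed = TRUE)
  }
  is_ari <- Reduce(`|`, lapply(ari_code_set, has_code, x = consultations$diagnosis_codes))
  cons <- tibble::tibble(
    patient_id = consultations$patient_id, date = consultations$date,
    remote = consultations$mode == "remote", is_ari = is_ari,
    is_covid = has_code(consultations$diagnosis_codes, "COVID")
  )
  ep <- dplyr::select(episodes, "episode_id", "patient_id", "index_date")

  joined <- ep |>
    dplyr::inner_join(cons, by = "patient_id", relationship = "many-to-many") |>
    dplyr::mutate(lag = as.numeric(.data$index_date - .data$date)) |>
    dplyr::filter(.data$lag >= 1, .data$lag <= wmax)
  blocks <- lapply(windows, function(w) {
    inw <- joined$lag <= w
    m <- cbind(
      inw,
      inw & !joined$remote, inw & joined$remote,
      inw & joined$is_ari,
      inw & joined$is_ari & !joined$remote, inw & joined$is_ari & joined$remote,
      inw & joined$is_covid
    )
    colnames(m) <- paste0(
      c("cons_all_", "cons_f2f_", "cons_remote_",
        "ari_all_", "ari_f2f_", "ari_remote_", "covid_"), w, "d")
    m
  })
  counts <- rowsum(do.call(cbind, blocks) * 1L, joined$episode_id)
  covid_cols <- grep("^covid_", colnames(counts))
  counts[, covid_cols] <- (counts[, covid_cols] > 0) * 1L
  cons_out <- dplyr::bind_cols(
    tibble::tibble(episode_id = rownames(counts)),
    tibble::as_tibble(counts)
  )

  abx <- dplyr::filter(prescriptions, .data$antibiotic_flag == 1)
  abx_joined <- ep |>
    dplyr::inner_join(dplyr::select(abx, "patient_id", "date"),
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::mutate(lag = as.numeric(.data$index_date - .data$date)) |>
    dplyr::filter(.data$lag >= 1, .data$lag <= wmax)
  abx_m <- do.call(cbind, lapply(windows, function(w) (abx_joined$lag <= w) * 1L))
  colnames(abx_m) <- paste0("abx_", windows, "d")
  abx_counts <- rowsum(abx_m, abx_joined$episode_id)
  abx_out <- dplyr::bind_cols(
    tibble::tibble(episode_id = rownames(abx_counts)),
    tibble::as_tibble(abx_counts)
  )

  out <- ep |>
    dplyr::select("episode_id") |>
    dplyr::left_join(cons_out, by = "episode_id") |>
    dplyr::left_join(abx_out, by = "episode_id")
  out[is.na(out)] <- 0L
  out
}

count_in_window <- function(sorted_dates, index_dates, w) {
  findInterval(as.numeric(index_dates) - 1, sorted_dates) -
    findInterval(as.numeric(index_dates) - w - 1, sorted_dates)
}

#' Practice-level activity rates per 10,000 patient-days
#'
#' For each episode: `10000 * events at the practice in the 365 days before
#' index / registered patient-days at the practice over the same 365 days`,
#' computed for antibiotic prescriptions and for all consultations.
#'
#' @param episodes Episode tibble with `episode_id`, `practice_id`,
#'   `index_date`.
#' @param consultations,prescriptions Event tables.
#' @param patients Patient table with `practice_id`, `reg_start`, `reg_end`.
#' @param window_days Rate window before index (default 365).
#' @return Tibble: `episode_id`, `practice_abx_rate_10k`,
#'   `practice_cons_rate_10k`.
#' @export
practice_rates <- function(episodes, consultations, prescriptions, patients,
                           window_days = 365) {
  pat_pr <- dplyr::select(patients, "patient_id", pr = "practice_id",
                          "reg_start", "reg_end")
  cons_pr <- consultations |>
    dplyr::inner_join(dplyr::select(pat_pr, "patient_id", "pr"), by = "patient_id")
  abx_pr <- prescriptions |>
    dplyr::filter(.data$antibiotic_flag == 1) |>
    dplyr::inner_join(dplyr::select(pat_pr, "patient_id", "pr"), by = "patient_id")

  cons_dates <- split(as.numeric(cons_pr$date), cons_pr$pr)
  abx_dates <- split(as.numeric(abx_pr$date), abx_pr$pr)
  cons_dates <- lapply(cons_dates, sort)
  abx_dates <- lapply(abx_dates, sort)

  # registered patient-days of the practice over [index - w, index)
  pd <- episodes |>
    dplyr::select("episode_id", "practice_id", "index_date") |>
    dplyr::inner_join(pat_pr, by = c(practice_id = "pr"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      lo = pmax(as.numeric(.data$reg_start), as.numeric(.data$index_date) - window_days),
      hi = pmin(as.numeric(.data$reg_end), as.numeric(.data$index_date) - 1),
      days = pmax(0, .data$hi - .data$lo + 1)
    ) |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(patient_days = sum(.data$days), .groups = "drop")

  out <- episodes |>
    dplyr::select("episode_id", "practice_id", "index_date") |>
    dplyr::left_join(pd, by = "episode_id")
  if (any(is.na(out$patient_days)) || any(out$patient_days <= 0)) {
    abort("zero registered patient-days at a practice in the rate window",
          class = "teletmle_validation_error")
  }
  n_abx <- n_cons <- numeric(nrow(out))
  for (p in unique(out$practice_id)) {
    i <- out$practice_id == p
    ad <- abx_dates[[p]] %||% numeric(0)
    cd <- cons_dates[[p]] %||% numeric(0)
    n_abx[i] <- count_in_window(ad, out$index_date[i], window_days)
    n_cons[i] <- count_in_window(cd, out$index_date[i], window_days)
  }
  tibble::tibble(
    episode_id = out$episode_id,
    practice_abx_rate_10k = 10000 * n_abx / out$patient_days,
    practice_cons_rate_10k = 10000 * n_cons / out$patient_days
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach the regional infection prevalence to episodes
#'
#' Last-observation-carried-forward join: each episode receives its region's
#' rate at the most recent series date on or before the index date.
#'
#' @param episodes Episode tibble with `episode_id`, `practice_id`,
#'   `index_date`.
#' @param prevalence Series tibble (`region`, `date`, `infection_rate`).
#' @param practices Practice table mapping `practice_id` to `region`.
#' @return Tibble: `episode_id`, `region`, `infection_rate`.
#' @export
join_prevalence <- function(episodes, prevalence, practices) {
  ep <- episodes |>
    dplyr::select("episode_id", "practice_id", "index_date") |>
    dplyr::left_join(dplyr::select(practices, "practice_id", "region"), by = "practice_id")
  missing_region <- setdiff(unique(ep$region), unique(prevalence$region))
  if (length(missing_region) || anyNA(ep$region)) {
    abort(paste0("region(s) absent from the prevalence series: ",
                 paste(missing_region, collapse = ", ")),
          class = "teletmle_validation_error")
  }
  rate <- numeric(nrow(ep))
  for (r in unique(ep$region)) {
    ser <- prevalence |>
      dplyr::filter(.data$region == r) |>
      dplyr::arrange(.data$date)
    i <- ep$region == r
    pos <- findInterval(as.numeric(ep$index_date[i]), as.numeric(ser$date))
    if (any(pos == 0)) {
      abort("episode index date precedes the prevalence series",
            class = "teletmle_validation_error")
    }
    rate[i] <- ser$infection_rate[pos]
  }
  tibble::tibble(episode_id = ep$episode_id, region = ep$region, infection_rate = rate)
}

#' Build the per-episode covariate matrix
#'
#' Assembles the full covariate set used by both the treatment and outcome
#' models: patient factors (age, sex, IMD quintile, ethnicity with an
#' explicit missing category, comorbidity flags), consultation factors
#' (clinician role, infection-subtype indicators), practice factors (region,
#' urban/rural, list size, prior-year antibiotic and consultation rates per
#' 10,000 patient-days), the regional COVID prevalence at index, and the
#' lookback-count grid. No value is missing after construction.
#'
#' @param cohort A `cohort` object (or an episode tibble).
#' @param tables The raw `event_tables` the cohort was built from.
#' @param windows Lookback windows in days.
#' @return A covariate tibble keyed by `episode_id`, with id/design roles
#'   recorded in the `"schema"` attribute.
#' @export
build_covariates <- function(cohort, tables, windows = LOOKBACK_WINDOWS) {
  episodes <- if (inherits(cohort, "cohort")) cohort$episodes else cohort
  pats <- tables$patients
  lb <- lookback_counts(episodes, tables$consultations, tables$prescriptions,
                        windows = windows,
                        registrations = dplyr::select(pats, "patient_id", "reg_start"))
  pr <- practice_rates(episodes, tables$consultations, tables$prescriptions, pats)
  prev <- join_prevalence(episodes, tables$prevalence, tables$practices)

  subtype_flags <- purrr::map_dfc(setNames(nm = toupper(ARI_SUBTYPES)), function(s) {
    as.integer(vapply(parse_codes(episodes$infection_subtypes),
                      function(cc) s %in% cc, logical(1)))
  })
  names(subtype_flags) <- paste0("subtype_", tolower(names(subtype_flags)))

  out <- episodes |>
    dplyr::select("episode_id", "patient_id", "practice_id", "stratum",
                  age = "age_at_index", "sex", "imd_quintile", "clinician_role") |>
    dplyr::left_join(
      dplyr::select(pats, "patient_id", "ethnicity",
                    dplyr::all_of(ADULT_COMORBIDITIES)),
      by = "patient_id"
    ) |>
    dplyr::left_join(
      dplyr::select(tables$practices, "practice_id", "urban_flag", "list_size"),
      by = "practice_id"
    ) |>
    dplyr::bind_cols(subtype_flags) |>
    dplyr::left_join(lb, by = "episode_id") |>
    dplyr::left_join(pr, by = "episode_id") |>
    dplyr::left_join(prev, by = "episode_id") |>
    dplyr::mutate(imd_quintile = factor(.data$imd_quintile, levels = 1:5))
  stopifnot(!anyNA(out))
  categorical <- c("sex", "imd_quintile", "ethnicity", "clinician_role", "region")
  schema <- tibble::tibble(
    column = names(out),
    role = dplyr::case_when(
      names(out) %in% c("episode_id", "patient_id", "practice_id", "stratum") ~ "id",
      names(out) %in% categorical ~ "categorical",
      TRUE ~ "numeric"
    ),
    reference_level = purrr::map_chr(names(out), function(cl) {
      if (cl %in% categorical) as.character(sort(unique(as.character(out[[cl]])))[1]) else NA_character_
    })
  )
  attr(out, "schema") <- schema
  out
}

#' One-hot encode a covariate tibble into a numeric design matrix
#'
#' Categorical columns become indicator columns `col.level` for every
#' non-reference level (reference levels come from the covariate schema);
#' numeric columns pass through. For the child stratum, adult-only
#' comorbidity columns are dropped. Column order is deterministic.
#'
#' @param covariates Output of [build_covariates()].
#' @param stratum `NULL` (keep all columns) or `"adult"` / `"child"`.
#' @return List with `x` (numeric matrix, syntactic column names), `schema`,
#'   and `levels` (per-categorical level sets, for decoding).
#' @export
encode_covariates <- function(covariates, stratum = NULL) {
  schema <- attr(covariates, "schema")
  stopifnot(!is.null(schema))
  drop_cols <- schema$column[schema$role == "id"]
  if (identical(stratum, "child")) {
    drop_cols <- c(drop_cols, setdiff(ADULT_COMORBIDITIES, CHILD_COMORBIDITIES))
  }
  design_cols <- setdiff(schema$column, drop_cols)
  levels_map <- list()
  blocks <- lapply(design_cols, function(cl) {
    role <- schema$role[schema$column == cl]
    v <- covariates[[cl]]
    if (role == "numeric") {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cl))
      return(m)
    }
    lev <- sort(unique(as.character(v)))
    ref <- schema$reference_level[schema$column == cl]
    lev <- c(ref, setdiff(lev, ref))
    levels_map[[cl]] <<- lev
    keep <- lev[-1]
    m <- vapply(keep, function(l) as.numeric(as.character(v) == l),
                numeric(length(v)))
    m <- matrix(m, ncol = length(keep),
                dimnames = list(NULL, paste0(cl, ".", keep)))
    m
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  stopifnot(!anyNA(x))
  list(x = x, schema = schema, levels = levels_map, design_cols = design_cols)
}

#' Decode an encoded design matrix back to raw labels
#'
#' Inverse of [encode_covariates()] for its categorical block; used to check
#' the encoding round-trip.
#'
#' @param encoded Output of [encode_covariates()].
#' @return Tibble of the categorical columns with original labels.
#' @export
decode_covariates <- function(encoded) {
  out <- list()
  for (cl in names(encoded$levels)) {
    lev <- encoded$levels[[cl]]
    cols <- make.names(paste0(cl, ".", lev[-1]))
    sub <- encoded$x[, intersect(cols, colnames(encoded$x)), drop = FALSE]
    lab <- rep(lev[1], nrow(sub))
    if (ncol(sub)) {
      hit <- max.col(cbind(0.5, sub), ties.method = "first") - 1L
      lab[hit > 0] <- lev[-1][hit[hit > 0]]
    }
    out[[cl]] <- lab
  }
  tibble::as_tibble(out)
}
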