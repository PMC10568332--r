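# Exchangeability and positivity diagnostics: standardized mean differences
# with a 10% noteworthy-imbalance threshold, descriptive tables with
# small-cell disclosure suppression (< 10), and propensity-extreme reporting.

#' Standardized mean difference between two groups
#'
#' Continuous: `|m1 - m0| / sqrt((s1^2 + s0^2)/2)` (unweighted two-group
#' pooled SD). Binary: `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0))/2)`.
#' Zero pooled variance with unequal means is reported as `Inf` with a
#' warning; with equal means the SMD is 0.
#'
#' @param m1,m0 Group means (continuous) or proportions (binary).
#' @param s1,s0 Group SDs (continuous type only).
#' @param type `"continuous"` or `"binary"`.
#' @return Nonnegative scalar.
#' @examples
#' smd(0.3, 0.2, type = "binary")
#' @export
smd <- function(m1, m0, s1 = NULL, s0 = NULL, type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (type == "binary") {
    stopifnot(m1 >= 0, m1 <= 1, m0 >= 0, m0 <= 1)
    s1 <- sqrt(m1 * (1 - m1)); s0 <- sqrt(m0 * (1 - m0))
  } else {
    stopifnot(!is.null(s1), !is.null(s0), s1 >= 0, s0 >= 0)
  }
  pooled <- sqrt((s1^2 + s0^2) / 2)
  if (pooled == 0) {
    if (m1 == m0) return(0)
    warn("zero pooled variance with unequal means; SMD is infinite")
    return(Inf)
  }
  abs(m1 - m0) / pooled
}

#' Covariate balance report between treatment arms
#'
#' Per covariate, the SMD between the two arms: continuous covariates use
#' the pooled-SD form; binary covariates the proportion form; multi-level
#' categoricals report the maximum over level-wise binary SMDs (per-level
#' values are also emitted). Covariates with SMD above `threshold` are
#' flagged; rows whose smaller arm holds fewer than `suppress_n` episodes
#' are marked suppressed.
#'
#' @param data Tibble holding the covariates and the arm column.
#' @param arm Name of the binary arm column (1 = remote).
#' @param vars Covariate columns to assess (default: all but `arm` and id-ish
#'   columns).
#' @param threshold Noteworthy-imbalance SMD threshold (default 0.10).
#' @param suppress_n Small-cell suppression threshold (default 10).
#' @return A `balance_report` tibble: `variable`, `level` (NA for
#'   continuous), `smd`, `flag`, `suppressed`, `n1`, `n0`.
#' @export
balance_report <- function(data, arm = "A", vars = NULL, threshold = 0.10,
                           suppress_n = 10) {
  a <- data[[arm]]
  stopifnot(all(a %in% 0:1))
  if (is.null(vars)) {
    vars <- setdiff(names(data), c(arm, "episode_id", "patient_id", "practice_id",
                                   "index_date", "Y", "stratum"))
  }
  n1 <- sum(a == 1); n0 <- sum(a == 0)
  rows <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      s <- smd(mean(x[a == 1]), mean(x[a == 0]), sd(x[a == 1]), sd(x[a == 0]),
               type = "continuous")
      return(tibble::tibble(variable = v, level = NA_character_, smd = s))
    }
    lev <- sort(unique(as.character(x)))
    per <- purrr::map_dbl(lev, function(l) {
      smd(mean(as.character(x)[a == 1] == l), mean(as.character(x)[a == 0] == l),
          type = "binary")
    })
    out <- tibble::tibble(variable = v, level = lev, smd = per)
    if (length(lev) > 2) {
      out <- dplyr::bind_rows(
        tibble::tibble(variable = v, level = "(max over levels)", smd = max(per)),
        out
      )
    }
    out
  })
  out <- rows |>
    dplyr::mutate(
      flag = .data$smd > threshold,
      suppressed = min(n1, n0) < suppress_n,
      n1 = n1, n0 = n0
    )
  class(out) <- c("balance_report", class(out))
  out
}

#' Arm-wise descriptive summary table with disclosure suppression
#'
#' Counts and percentages for categorical variables and median (IQR) for
#' numeric variables, per arm and overall. Every cell of a group holding
#' fewer than `suppress_n` episodes is suppressed (statistics set to `NA`,
#' `suppressed = TRUE`); suppression never alters other cells.
#'
#' @param data Episode-level tibble.
#' @param vars Variables to summarise.
#' @param by Grouping column (default the arm `A`).
#' @param suppress_n Small-group suppression threshold (default 10).
#' @return Tibble with one row per variable/level/group: `n`, `denom`,
#'   `pct` (categorical) or `median`, `q1`, `q3` (numeric), `suppressed`.
#' @export
summary_table <- function(data, vars, by = "A", suppress_n = 10) {
  groups <- c(split(data, paste0(by, "=", data[[by]])), list(overall = data))
  purrr::map_dfr(names(groups), function(g) {
    d <- groups[[g]]
    denom <- nrow(d)
    sup <- denom < suppress_n
    purrr::map_dfr(vars, function(v) {
      x <- d[[v]]
      if (is.numeric(x) && length(unique(data[[v]])) > 10) {
        q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
        tibble::tibble(
          variable = v, level = NA_character_, group = g, n = denom,
          denom = denom, pct = NA_real_,
          median = if (sup) NA_real_ else q[2],
          q1 = if (sup) NA_real_ else q[1],
          q3 = if (sup) NA_real_ else q[3],
          suppressed = sup
        )
      } else {
        lev <- sort(unique(as.character(data[[v]])))
        purrr::map_dfr(lev, function(l) {
          n <- sum(as.character(x) == l)
          tibble::tibble(
            variable = v, level = l, group = g,
            n = if (sup) NA_integer_ else n, denom = denom,
            pct = if (sup) NA_real_ else 100 * n / denom,
            median = NA_real_, q1 = NA_real_, q3 = NA_real_,
            suppressed = sup
          )
        })
      }
    })
  })
}

#' Positivity diagnostics from estimated propensity scores
#'
#' Reports the minimum and maximum propensity, a histogram, and the share of
#' scores outside configurable bounds. Extremes breaching the bounds raise a
#' warning (never an error); a propensity at or outside 0/1 is an error.
#'
#' @param propensities Numeric vector of estimated P(A=1|W), all in (0, 1).
#' @param bounds Length-2 reporting bounds.
#' @param breaks Histogram bin count.
#' @return A `positivity_report` list: `min`, `max`, `share_outside`,
#'   `bounds`, `histogram` (tibble of bin mids and counts), `n`.
#' @export
positivity_report <- function(propensities, bounds = c(0.025, 0.975), breaks = 20) {
  if (any(propensities <= 0 | propensities >= 1)) {
    abort("propensity scores must lie strictly inside (0, 1)",
          class = "teletmle_validation_error")
  }
  h <- graphics::hist(propensities, breaks = seq(0, 1, length.out = breaks + 1),
                      plot = FALSE)
  out <- structure(
    list(
      min = min(propensities), max = max(propensities),
      share_outside = mean(propensities < bounds[1] | propensities > bounds[2]),
      bounds = bounds,
      histogram = tibble::tibble(mid = h$mids, count = h$counts),
      n = length(propensities)
    ),
    class = "positivity_report"
  )
  if (out$min < bounds[1] || out$max > bounds[2]) {
    warn(sprintf("propensity extremes [%.3f, %.3f] breach reporting bounds [%.3f, %.3f]",
                 out$min, out$max, bounds[1], bounds[2]))
  }
  out
}

#' @export
print.positivity_report <- function(x, ...) {
  cat(sprintf("<positivity report> n = %d, min = %.3f, max = %.3f, %.1f%% outside [%.3f, %.3f]\n",
              x$n, x$min, x$max, 100 * x$share_outside, x$bounds[1], x$bounds[2]))
  invisible(x)
}
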