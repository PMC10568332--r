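# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TMLE fit
#'
#' @param x A `tmle_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`psi0`, `psi1`, `ate`, `or`):
#'   `estimate`, `se`, `ci_lower`, `ci_upper`.
#' @export
tidy.tmle_fit <- function(x, ...) x$estimates

#' @rdname tidy.tmle_fit
#' @export
glance.tmle_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, eps = x$eps, score = x$score,
    psi1 = x$psi1, psi0 = x$psi0, ate = x$ate, or = x$or,
    se_ate = x$se_ate, variance = x$variance
  )
}

#' Tidy a stratified TMLE analysis
#'
#' @param x A `tmle_analysis` from [run_tmle()].
#' @param ... Unused.
#' @return Parameter tibble with a `stratum` column.
#' @export
tidy.tmle_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$strata), function(st) {
    dplyr::mutate(x$strata[[st]]$tmle$estimates, stratum = st, .before = 1)
  })
}

#' @rdname tidy.tmle_analysis
#' @export
glance.tmle_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$strata), function(st) {
    f <- x$strata[[st]]
    dplyr::mutate(glance(f$tmle), stratum = st,
                  n_remote = f$n_remote,
                  g_min = f$positivity$min, g_max = f$positivity$max,
                  .before = 1)
  })
}

#' Tidy a superlearner fit
#'
#' @param x A `superlearner_fit`.
#' @param ... Unused.
#' @return Tibble of learners with metalearner weight and CV risks.
#' @export
tidy.superlearner_fit <- function(x, ...) {
  dplyr::mutate(x$cv_risk, weight = as.numeric(x$alpha), .after = 1)
}
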