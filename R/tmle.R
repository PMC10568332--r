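# Targeted maximum likelihood estimation of the ATE and marginal odds ratio
# for a binary exposure and binary outcome, with influence-curve inference.
#
# The initial outcome model Q0 is fluctuated along the one-parameter logistic
# submodel logit Q*(A,W) = logit Q0(A,W) + eps * H(A,W), where H is the
# clever covariate A/g - (1-A)/(1-g). At the MLE the efficient-influence-
# function score equation mean(H * (Y - Q*)) = 0 is solved, which yields the
# double-robustness and plug-in efficiency of the estimator.

#' Clever covariate for the ATE fluctuation
#'
#' `H = A/g - (1-A)/(1-g)`, together with the counterfactual versions
#' `H1 = 1/g` and `H0 = -1/(1-g)` used to target the two potential-outcome
#' predictions.
#'
#' @param A Binary exposure vector.
#' @param g Propensity vector P(A=1|W), strictly inside (0, 1).
#' @return Tibble with columns `H`, `H1`, `H0`.
#' @examples
#' clever_covariate(c(1, 0), c(0.5, 0.25))
#' @export
clever_covariate <- function(A, g) {
  if (any(g <= 0 | g >= 1)) {
    abort("propensity scores must be strictly inside (0, 1); clip upstream",
          class = "teletmle_validation_error")
  }
  stopifnot(all(A %in% 0:1), length(A) == length(g))
  tibble::tibble(H = A / g - (1 - A) / (1 - g), H1 = 1 / g, H0 = -1 / (1 - g))
}

#' Bundle and validate TMLE inputs
#'
#' @param Y Binary outcome vector.
#' @param A Binary exposure vector.
#' @param Q_A,Q_1,Q_0 Initial outcome-model probabilities at the observed,
#'   treated and control exposure.
#' @param g Propensity vector (already clipped).
#' @param cluster Optional cluster (practice) identifier for cluster-robust
#'   variance.
#' @return A `tmle_inputs` list.
#' @export
tmle_inputs <- function(Y, A, Q_A, Q_1, Q_0, g, cluster = NULL) {
  n <- length(Y)
  stopifnot(all(Y %in% 0:1), all(A %in% 0:1),
            length(A) == n, length(Q_A) == n, length(Q_1) == n,
            length(Q_0) == n, length(g) == n)
  Q_A <- clip_prob(Q_A); Q_1 <- clip_prob(Q_1); Q_0 <- clip_prob(Q_0)
  if (any(g <= 0 | g >= 1)) {
    abort("propensity scores must be strictly inside (0, 1)",
          class = "teletmle_validation_error")
  }
  structure(list(Y = Y, A = A, Q_A = Q_A, Q_1 = Q_1, Q_0 = Q_0, g = g,
                 cluster = cluster, n = n),
            class = "tmle_inputs")
}

#' Solve the fluctuation coefficient
#'
#' One-parameter logistic maximum likelihood of `Y` on the clever covariate
#' `H` with offset `logit Q_A`: Newton-Raphson with analytic gradient and
#' step-halving, converged when the mean score `|mean(H (Y - Q*))|` falls
#' below `tol`.
#'
#' @param inputs A [tmle_inputs()] object.
#' @param tol Convergence tolerance on the mean score (default 1e-10).
#' @param max_iter Iteration cap.
#' @return The fluctuation coefficient `eps` (scalar), with the final mean
#'   score as attribute `"score"`.
#' @export
fluctuate <- function(inputs, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(inputs, "tmle_inputs"))
  H <- clever_covariate(inputs$A, inputs$g)$H
  off <- logit(inputs$Q_A)
  y <- inputs$Y
  n <- inputs$n
  eps <- 0
  score_at <- function(e) {
    q <- expit(off + e * H)
    list(score = mean(H * (y - q)), info = mean(H^2 * q * (1 - q)))
  }
  s <- score_at(eps)
  for (it in seq_len(max_iter)) {
    if (abs(s$score) < tol) break
    step <- s$score / max(s$info, 1e-12)
    # step-halving on the absolute score
    for (h in 0:30) {
      cand <- eps + step / 2^h
      s2 <- score_at(cand)
      if (abs(s2$score) < abs(s$score)) break
    }
    if (abs(s2$score) >= abs(s$score)) break
    eps <- cand
    s <- s2
  }
  if (abs(s$score) >= tol * 10 && abs(s$score) > 1e-8) {
    abort(sprintf("fluctuation did not converge; final mean score %.3e", s$score),
          class = "teletmle_fit_error")
  }
  structure(eps, score = s$score)
}

#' Target the outcome model and estimate ATE and marginal OR
#'
#' Applies the fluctuation to the counterfactual predictions,
#' `Q*_a = expit(logit Q_a + eps * H_a)`, averages them into the targeted
#' counterfactual means `psi1` and `psi0`, and forms the ATE
#' `psi1 - psi0` and the marginal odds ratio
#' `[psi1/(1-psi1)]/[psi0/(1-psi0)]`. Standard errors come from the
#' empirical efficient influence curve (`sd(D)/sqrt(n)`), optionally made
#' cluster-robust by summing influence-curve contributions within practice;
#' odds-ratio inference is on the log scale by the delta method. Confidence
#' intervals use the 1.96 normal quantile.
#'
#' @param inputs A [tmle_inputs()] object.
#' @param eps Fluctuation coefficient from [fluctuate()].
#' @param variance `"individual"` (default) or `"cluster"`.
#' @return A `tmle_fit` object.
#' @export
target_and_estimate <- function(inputs, eps, variance = c("individual", "cluster")) {
  variance <- match.arg(variance)
  cc <- clever_covariate(inputs$A, inputs$g)
  n <- inputs$n
  Qs1 <- expit(logit(inputs$Q_1) + eps * cc$H1)
  Qs0 <- expit(logit(inputs$Q_0) + eps * cc$H0)
  QsA <- ifelse(inputs$A == 1, Qs1, Qs0)
  psi1 <- mean(Qs1); psi0 <- mean(Qs0)
  if (psi1 <= 2e-6 || psi1 >= 1 - 2e-6 || psi0 <= 2e-6 || psi0 >= 1 - 2e-6) {
    abort("degenerate targeted mean at 0 or 1", class = "teletmle_fit_error")
  }
  ate <- psi1 - psi0
  or <- marginal_or(psi1, psi0)
  resid <- inputs$Y - QsA
  D1 <- (inputs$A / inputs$g) * resid + Qs1 - psi1
  D0 <- ((1 - inputs$A) / (1 - inputs$g)) * resid + Qs0 - psi0
  D_ate <- D1 - D0
  D_logOR <- D1 / (psi1 * (1 - psi1)) - D0 / (psi0 * (1 - psi0))
  se_of <- function(D) {
    if (variance == "cluster") {
      if (is.null(inputs$cluster)) {
        abort("cluster variance requested but no cluster ids supplied",
              class = "teletmle_validation_error")
      }
      s <- tapply(D - mean(D), inputs$cluster, sum)
      m <- length(s)
      sqrt(m / (m - 1) * sum(s^2)) / n
    } else {
      sd(D) / sqrt(n)
    }
  }
  se1 <- se_of(D1); se0 <- se_of(D0)
  se_ate <- se_of(D_ate); se_logor <- se_of(D_logOR)
  z <- 1.96
  est <- tibble::tibble(
    parameter = c("psi0", "psi1", "ate", "or"),
    estimate = c(psi0, psi1, ate, or),
    se = c(se0, se1, se_ate, NA_real_),
    ci_lower = c(psi0 - z * se0, psi1 - z * se1, ate - z * se_ate,
                 exp(log(or) - z * se_logor)),
    ci_upper = c(psi0 + z * se0, psi1 + z * se1, ate + z * se_ate,
                 exp(log(or) + z * se_logor))
  )
  structure(
    list(estimates = est, psi1 = psi1, psi0 = psi0, ate = ate, or = or,
         se_ate = se_ate, se_logor = se_logor, eps = as.numeric(eps),
         score = mean(cc$H * resid),
         ic = tibble::tibble(D1 = D1, D0 = D0, D_ate = D_ate, D_logOR = D_logOR),
         n = n, variance = variance),
    class = "tmle_fit"
  )
}

#' One-shot TMLE from precomputed nuisance estimates
#'
#' Convenience wrapper: bundle inputs, clip the propensity, solve the
#' fluctuation and estimate.
#'
#' @inheritParams tmle_inputs
#' @param g_bounds Propensity clipping bounds (default `c(0.005, 0.995)`).
#' @param variance `"individual"` or `"cluster"`.
#' @return A `tmle_fit`.
#' @export
tmle_fit <- function(Y, A, g, Q_1, Q_0, Q_A = NULL, cluster = NULL,
                     g_bounds = c(0.005, 0.995),
                     variance = c("individual", "cluster")) {
  if (is.null(Q_A)) Q_A <- ifelse(A == 1, Q_1, Q_0)
  g <- clip_prob(g, g_bounds)
  inputs <- tmle_inputs(Y, A, Q_A, Q_1, Q_0, g, cluster = cluster)
  eps <- fluctuate(inputs)
  target_and_estimate(inputs, eps, variance = match.arg(variance))
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf("<tmle fit> n = %d, eps = %.4g, score = %.2e\n", x$n, x$eps, x$score))
  print(x$estimates)
  invisible(x)
}

#' Full TMLE analysis of a cohort: superlearner nuisances plus targeting
#'
#' Orchestrates the full targeted analysis per stratum: practice-clustered
#' outcome-stratified folds, a cross-validated superlearner for the
#' treatment model `g(W) = P(A=1|W)` and the outcome model
#' `Q(A,W) = E[Y|A,W]` (the same covariate set, the outcome model
#' additionally taking A), positivity diagnostics, the fluctuation step,
#' and influence-curve inference.
#'
#' @param cohort A `cohort` object (or episode tibble with `A`, `Y`).
#' @param covariates Covariate tibble from [build_covariates()].
#' @param stratum `"both"` (adult and child separately), `"adult"`,
#'   `"child"`, or `"all"` (pooled).
#' @param learner_profile Profile passed to [learner_library()], or a
#'   learner list.
#' @param K Cross-validation folds (default 10).
#' @param seed Root seed for folds and stochastic learners.
#' @param g_bounds Propensity clipping bounds.
#' @param positivity_bounds Soft reporting bounds; extremes outside them
#'   warn.
#' @param hard_bounds Hard positivity bounds; raw propensity extremes
#'   outside them abort. Default `c(0, 1)` (off).
#' @param variance `"individual"` or `"cluster"` influence-curve variance.
#' @param metalearner `"nnls"` or `"discrete"`.
#' @return A `tmle_analysis` object: per-stratum `tmle_fit`s, superlearner
#'   fits, fold maps and positivity reports, plus a run manifest.
#' @examples
#' \donttest{
#' tabs <- generate_study(generator_config(n_practices = 20,
#'                                         patients_per_practice = 40, seed = 2))
#' coh <- build_cohort(tabs)
#' W <- build_covariates(coh, tabs)
#' fit <- run_tmle(coh, W, stratum = "all", learner_profile = "glm", K = 5)
#' tidy(fit)
#' }
#' @export
run_tmle <- function(cohort, covariates,
                     stratum = c("both", "adult", "child", "all"),
                     learner_profile = "fast", K = 10, seed = 1,
                     g_bounds = c(0.005, 0.995),
                     positivity_bounds = c(0.025, 0.975),
                     hard_bounds = c(0, 1),
                     variance = c("individual", "cluster"),
                     metalearner = "nnls") {
  stratum <- match.arg(stratum)
  variance <- match.arg(variance)
  episodes <- if (inherits(cohort, "cohort")) cohort$episodes else cohort
  library <- if (is.character(learner_profile)) learner_library(learner_profile) else learner_profile
  strata <- switch(stratum, both = c("adult", "child"), stratum)
  fits <- list()
  for (st in strata) {
    dat <- if (st == "all") episodes else dplyr::filter(episodes, .data$stratum == st)
    cov_st <- dplyr::semi_join(covariates, dat, by = "episode_id")
    dat <- dat[match(cov_st$episode_id, dat$episode_id), ]
    if (length(unique(dat$A)) < 2) {
      abort(sprintf("stratum '%s' has a single exposure arm", st),
            class = "teletmle_validation_error")
    }
    enc <- encode_covariates(cov_st, stratum = if (st %in% c("adult", "child")) st else NULL)
    x <- enc$x
    folds <- make_folds(dat$practice_id, dat$Y, K = K, seed = seed)
    g_fit <- cv_fit(x, dat$A, folds, library = library,
                    metalearner = metalearner, seed = seed)
    g_raw <- predict(g_fit, x)
    if (min(g_raw) < hard_bounds[1] || max(g_raw) > hard_bounds[2]) {
      abort(sprintf("positivity violation: propensity extremes [%.4f, %.4f] outside hard bounds",
                    min(g_raw), max(g_raw)),
            class = "teletmle_positivity_error")
    }
    pos <- positivity_report(g_raw, bounds = positivity_bounds)
    xq <- cbind(A = dat$A, x)
    q_fit <- cv_fit(xq, dat$Y, folds, library = library,
                    metalearner = metalearner, seed = seed + 1)
    q1 <- predict(q_fit, cbind(A = 1, x))
    q0 <- predict(q_fit, cbind(A = 0, x))
    fit <- tmle_fit(dat$Y, dat$A, g_raw, q1, q0,
                    cluster = dat$practice_id, g_bounds = g_bounds,
                    variance = variance)
    fits[[st]] <- list(tmle = fit, g_fit = g_fit, q_fit = q_fit,
                       positivity = pos, folds = folds,
                       n = nrow(dat), n_remote = sum(dat$A == 1))
  }
  structure(
    list(strata = fits,
         manifest = list(seed = seed, K = K, g_bounds = g_bounds,
                         variance = variance, metalearner = metalearner,
                         learners = vapply(library, `[[`, character(1), "name"),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "tmle_analysis"
  )
}

#' @export
print.tmle_analysis <- function(x, ...) {
  cat("<tmle analysis>\n")
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Human-readable results narrative
#'
#' Formats each stratum's targeted counterfactual prescribing proportions,
#' ATE and marginal odds ratio as sentences.
#'
#' @param analysis A `tmle_analysis`.
#' @return Character vector, one sentence per stratum.
#' @export
report_text <- function(analysis) {
  vapply(names(analysis$strata), function(st) {
    f <- analysis$strata[[st]]$tmle
    e <- f$estimates
    ci <- function(p) {
      r <- e[e$parameter == p, ]
      sprintf("%.1f, %.1f", 100 * r$ci_lower, 100 * r$ci_upper)
    }
    orr <- e[e$parameter == "or", ]
    sprintf(paste0(
      "[%s] %.1f%% (95%% CI: %s) would have been prescribed antibiotics if all ",
      "seen face-to-face vs %.1f%% (95%% CI: %s) if all seen remotely; ",
      "ATE %.1f%% (95%% CI: %s), odds ratio %.2f (95%% CI: %.2f, %.2f)."),
      st, 100 * f$psi0, ci("psi0"), 100 * f$psi1, ci("psi1"),
      100 * f$ate, ci("ate"), f$or, orr$ci_lower, orr$ci_upper)
  }, character(1))
}
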