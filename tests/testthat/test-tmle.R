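# The targeting step: clever covariate, fluctuation, estimation, inference.

test_that("clever covariate evaluates its closed form", {
  cc <- clever_covariate(c(1, 0, 1), c(0.5, 0.5, 0.25))
  expect_equal(cc$H, c(2, -2, 4))
  expect_equal(cc$H1, c(2, 2, 4))
  expect_equal(cc$H0, c(-2, -2, -4/3))
  expect_error(clever_covariate(1, 1), class = "teletmle_validation_error")
  expect_error(clever_covariate(0, 0), class = "teletmle_validation_error")
})

rand_inputs <- function(n, seed, beta = 0.6) {
  set.seed(seed)
  w <- rnorm(n)
  g <- plogis(0.3 + 0.8 * w)
  a <- rbinom(n, 1, g)
  py <- plogis(-0.2 + beta * a + 0.7 * w)
  y <- rbinom(n, 1, py)
  # deliberately crude initial outcome model: logistic in A only
  m <- glm(y ~ a, family = binomial())
  q1 <- plogis(coef(m)[1] + coef(m)[2])
  q0 <- plogis(coef(m)[1])
  list(Y = y, A = a, g = g,
       Q_1 = rep(q1, n), Q_0 = rep(q0, n))
}

test_that("fluctuation solves the score equation on arbitrary fixtures", {
  for (s in 1:5) {
    d <- rand_inputs(500, s)
    fit <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0)
    expect_lt(abs(fit$score), 1e-8)
  }
})

test_that("epsilon is zero when the initial fit already solves the score", {
  d <- rand_inputs(400, 7)
  # arm-specific means with g = mean(A) solve the score exactly
  q1 <- rep(mean(d$Y[d$A == 1]), 400)
  q0 <- rep(mean(d$Y[d$A == 0]), 400)
  inputs <- tmle_inputs(d$Y, d$A, ifelse(d$A == 1, q1, q0), q1, q0,
                        rep(mean(d$A), 400))
  eps <- fluctuate(inputs)
  expect_equal(as.numeric(eps), 0, tolerance = 1e-12)
})

test_that("the fluctuation MLE matches a brute-force one-dimensional likelihood grid", {
  d <- rand_inputs(300, 9)
  inputs <- tmle_inputs(d$Y, d$A, ifelse(d$A == 1, d$Q_1, d$Q_0),
                        d$Q_1, d$Q_0, clip_prob(d$g, c(0.01, 0.99)))
  eps <- as.numeric(fluctuate(inputs))
  H <- clever_covariate(inputs$A, inputs$g)$H
  off <- qlogis(inputs$Q_A)
  loglik <- function(e) {
    q <- plogis(off + e * H)
    sum(inputs$Y * log(q) + (1 - inputs$Y) * log(1 - q))
  }
  grid <- seq(eps - 0.2, eps + 0.2, length.out = 4001)
  expect_equal(eps, grid[which.max(vapply(grid, loglik, numeric(1)))],
               tolerance = 2e-4)
  expect_gte(loglik(eps), max(vapply(grid, loglik, numeric(1))) - 1e-10)
})

test_that("with no covariates TMLE returns arm means and the crude 2x2 odds ratio exactly", {
  set.seed(10)
  n <- 600
  a <- rbinom(n, 1, 0.45)
  y <- rbinom(n, 1, ifelse(a == 1, 0.55, 0.4))
  q1 <- rep(mean(y[a == 1]), n); q0 <- rep(mean(y[a == 0]), n)
  fit <- tmle_fit(y, a, rep(mean(a), n), q1, q0)
  # contingency arithmetic
  n11 <- sum(a == 1 & y == 1); n10 <- sum(a == 1 & y == 0)
  n01 <- sum(a == 0 & y == 1); n00 <- sum(a == 0 & y == 0)
  expect_equal(fit$psi1, n11 / (n11 + n10), tolerance = 1e-10)
  expect_equal(fit$psi0, n01 / (n01 + n00), tolerance = 1e-10)
  expect_equal(fit$ate, n11 / (n11 + n10) - n01 / (n01 + n00), tolerance = 1e-10)
  expect_equal(fit$or, (n11 * n00) / (n10 * n01), tolerance = 1e-10)
  expect_equal(fit$eps, 0, tolerance = 1e-10)
})

test_that("estimates stay in bounds and CIs bracket the point estimates", {
  for (s in 1:4) {
    d <- rand_inputs(400, 20 + s)
    fit <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0)
    e <- fit$estimates
    expect_true(fit$psi1 > 0 && fit$psi1 < 1)
    expect_true(fit$psi0 > 0 && fit$psi0 < 1)
    expect_true(fit$ate > -1 && fit$ate < 1)
    expect_gt(fit$or, 0)
    ate <- e[e$parameter == "ate", ]
    expect_lt(ate$ci_lower, fit$ate); expect_gt(ate$ci_upper, fit$ate)
    orr <- e[e$parameter == "or", ]
    expect_gt(orr$ci_lower, 0)
    expect_lt(orr$ci_lower, fit$or); expect_gt(orr$ci_upper, fit$or)
  }
})

test_that("relabelling the arms maps ate to -ate and or to 1/or", {
  d <- rand_inputs(500, 30)
  fit <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0)
  flip <- tmle_fit(d$Y, 1 - d$A, 1 - d$g, d$Q_0, d$Q_1)
  expect_equal(flip$ate, -fit$ate, tolerance = 1e-10)
  expect_equal(flip$or, 1 / fit$or, tolerance = 1e-10)
})

test_that("influence-curve pieces combine as specified and yield the delta-method OR interval", {
  d <- rand_inputs(400, 31)
  fit <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0)
  ic <- fit$ic
  expect_equal(ic$D_ate, ic$D1 - ic$D0)
  expect_equal(ic$D_logOR,
               ic$D1 / (fit$psi1 * (1 - fit$psi1)) - ic$D0 / (fit$psi0 * (1 - fit$psi0)))
  expect_equal(fit$se_ate, sd(ic$D_ate) / sqrt(fit$n))
  orr <- fit$estimates[fit$estimates$parameter == "or", ]
  expect_equal(orr$ci_lower, exp(log(fit$or) - 1.96 * fit$se_logor), tolerance = 1e-6)
})

test_that("cluster-robust variance uses practice-summed influence curves", {
  d <- rand_inputs(600, 32)
  cl <- rep(sprintf("pr%02d", 1:30), each = 20)
  fit_i <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0, cluster = cl)
  fit_c <- tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0, cluster = cl, variance = "cluster")
  expect_equal(fit_c$ate, fit_i$ate)
  D <- fit_i$ic$D_ate
  s <- tapply(D - mean(D), cl, sum)
  expect_equal(fit_c$se_ate, sqrt(30 / 29 * sum(s^2)) / 600)
  expect_error(tmle_fit(d$Y, d$A, d$g, d$Q_1, d$Q_0, variance = "cluster"),
               class = "teletmle_validation_error")
})

test_that("run_tmle rejects a single-arm stratum and reports per stratum", {
  tabs <- generate_study(small_config(seed = 51))
  coh <- build_cohort(tabs)
  W <- build_covariates(coh, tabs)
  one_arm <- coh
  one_arm$episodes <- dplyr::mutate(one_arm$episodes, A = 1L)
  expect_error(run_tmle(one_arm, W, stratum = "all", learner_profile = "glm", K = 5),
               class = "teletmle_validation_error")
  fit <- run_tmle(coh, W, stratum = "both", learner_profile = "glm", K = 5, seed = 2)
  td <- tidy(fit)
  expect_setequal(unique(td$stratum), c("adult", "child"))
  expect_equal(nrow(td), 8)
  gl <- glance(fit)
  expect_true(all(gl$score < 1e-8))
  expect_true(all(gl$g_min > 0 & gl$g_max < 1))
  txt <- report_text(fit)
  expect_length(txt, 2)
  expect_match(txt[1], "odds ratio")
})

test_that("probabilities are clipped before the logit transform and degenerate targets error", {
  d <- rand_inputs(200, 40)
  inp <- tmle_inputs(d$Y, d$A, rep(1 - 1e-12, 200), rep(1 - 1e-12, 200),
                     rep(1e-12, 200), clip_prob(d$g, c(1e-4, 1 - 1e-4)))
  expect_equal(max(inp$Q_1), 1 - 1e-6)
  expect_equal(min(inp$Q_0), 1e-6)
  expect_true(all(is.finite(qlogis(inp$Q_1))))
  expect_error(
    target_and_estimate(
      tmle_inputs(rep(0L, 50), rep(c(0L, 1L), 25), rep(1e-7, 50), rep(1e-7, 50),
                  rep(1e-7, 50), rep(0.5, 50)), eps = 0),
    class = "teletmle_fit_error"
  )
})
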