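#' @importFrom rlang .data abort warn .env
#' @importFrom stats plogis qlogis rbinom rnorm runif rpois glm binomial predict
#'   coef sd quantile median model.matrix setNames rbeta var
#' @importFrom utils head
NULL

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

#' Clip probabilities away from 0 and 1
#'
#' @param p Numeric vector of probabilities.
#' @param bounds Length-2 numeric, lower and upper clipping bound.
#' @return `p` with every element forced into `[bounds[1], bounds[2]]`.
#' @export
clip_prob <- function(p, bounds = c(1e-6, 1 - 1e-6)) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] < 1, bounds[1] < bounds[2])
  pmin(pmax(p, bounds[1]), bounds[2])
}

# Deterministic stream splitting: every stage of a run draws from its own
# seed derived from the root seed, so adding draws to one stage never
# perturbs another. Kept below 2^31 - 1.
derive_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1)
  offsets <- c(
    practices = 11, patients = 23, episodes = 37, consultations = 53,
    prescriptions = 71, prevalence = 89, folds = 101, learners = 113,
    mc = 131, reps = 149
  )
  if (!stream %in% names(offsets)) abort(paste0("unknown rng stream: ", stream))
  as.integer((abs(as.numeric(root_seed)) * 7919 + offsets[[stream]]) %% 2147483629)
}

with_stream_seed <- function(root_seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(root_seed, stream))
  force(code)
}

#' Marginal odds ratio from two counterfactual mean probabilities
#'
#' The causal odds ratio formed from the population mean outcome
#' probability had everyone been treated (`psi1`) versus untreated
#' (`psi0`): `[psi1/(1-psi1)] / [psi0/(1-psi0)]`.
#'
#' @param psi1,psi0 Counterfactual mean outcome probabilities in (0, 1).
#' @return The marginal odds ratio, a positive scalar.
#' @examples
#' marginal_or(0.499, 0.447)
#' @export
marginal_or <- function(psi1, psi0) {
  stopifnot(all(psi1 > 0 & psi1 < 1), all(psi0 > 0 & psi0 < 1))
  (psi1 / (1 - psi1)) / (psi0 / (1 - psi0))
}
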