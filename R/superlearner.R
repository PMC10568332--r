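# Cross-validated superlearner: a pluggable library of probability learners
# behind a uniform fit/predict interface, practice-clustered outcome-
# stratified folds, and a non-negative-least-squares metalearner on the
# out-of-fold prediction matrix.

#' Learner constructors
#'
#' Each learner is a list with a `name`, a `fit(x, y)` function returning a
#' model, and a `predict(model, x)` function returning probabilities; `x` is
#' a numeric design matrix. The default six-learner library spans a plain
#' logistic model, a generalized additive model with smooth terms, a random
#' forest, gradient boosting, a natural-cubic-spline logistic model, and an
#' L1-penalised logistic model.
#'
#' @param nlambda,alpha `glmnet` path controls; the path lambda minimising
#'   the training BIC is used (no nested CV).
#' @param k Basis dimension of the GAM smooths.
#' @param num_trees,min_node_size Random-forest controls.
#' @param nrounds,max_depth,eta Boosting controls.
#' @param df Spline degrees of freedom per continuous covariate.
#' @return A learner specification list.
#' @name learners
NULL

continuous_cols <- function(x, min_unique = 20) {
  which(apply(x, 2, function(v) length(unique(v))) >= min_unique)
}

#' @rdname learners
#' @export
lrnr_glm <- function() {
  list(
    name = "glm",
    fit = function(x, y) {
      xm <- cbind(`(Intercept)` = 1, x)
      fit <- suppressWarnings(stats::glm.fit(xm, y, family = binomial()))
      beta <- coef(fit)
      if (anyNA(beta)) {
        keep <- which(!is.na(beta))
        fit <- suppressWarnings(stats::glm.fit(xm[, keep, drop = FALSE], y,
                                               family = binomial()))
        beta <- setNames(rep(0, ncol(xm)), colnames(xm))
        beta[keep] <- coef(fit)
        beta[is.na(beta)] <- 0
      }
      beta
    },
    predict = function(model, x) {
      expit(drop(cbind(1, x[, names(model)[-1], drop = FALSE]) %*% model))
    }
  )
}

#' @rdname learners
#' @export
lrnr_mean <- function() {
  list(
    name = "mean",
    fit = function(x, y) mean(y),
    predict = function(model, x) rep(model, nrow(x))
  )
}

#' @rdname learners
#' @export
lrnr_glmnet <- function(alpha = 1, nlambda = 40) {
  list(
    name = "lasso_logistic",
    fit = function(x, y) {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                            nlambda = nlambda, standardize = TRUE)
      n <- length(y)
      dev <- stats::deviance(fit)
      bic <- dev + log(n) * fit$df
      list(fit = fit, lambda = fit$lambda[which.min(bic)])
    },
    predict = function(model, x) {
      as.numeric(predict(model$fit, newx = x, s = model$lambda, type = "response"))
    }
  )
}

#' @rdname learners
#' @export
lrnr_gam <- function(k = 5) {
  list(
    name = "gam",
    fit = function(x, y) {
      cc <- continuous_cols(x)
      df <- data.frame(y = y, x, check.names = TRUE)
      vars <- colnames(df)[-1]
      sm <- vars[cc]
      lin <- setdiff(vars, sm)
      rhs <- paste(c(
        if (length(sm)) paste0("s(", sm, ", k = ", k, ")"),
        lin
      ), collapse = " + ")
      suppressWarnings(
        mgcv::bam(stats::as.formula(paste("y ~", rhs)), data = df,
                  family = binomial(), method = "fREML", discrete = TRUE)
      )
    },
    predict = function(model, x) {
      as.numeric(predict(model, newdata = data.frame(x, check.names = TRUE),
                         type = "response"))
    }
  )
}

#' @rdname learners
#' @export
lrnr_ranger <- function(num_trees = 300, min_node_size = 20) {
  list(
    name = "random_forest",
    fit = function(x, y) {
      ranger::ranger(
        x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = num_trees, min.node.size = min_node_size,
        num.threads = 1, seed = sample.int(1e6, 1)
      )
    },
    predict = function(model, x) {
      as.numeric(predict(model, data = x, num.threads = 1)$predictions[, "1"])
    }
  )
}

#' @rdname learners
#' @export
lrnr_xgboost <- function(nrounds = 60, max_depth = 3, eta = 0.3) {
  list(
    name = "xgboost",
    fit = function(x, y) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = nrounds, verbose = 0
      )
    },
    predict = function(model, x) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))
    }
  )
}

#' @rdname learners
#' @export
lrnr_spline <- function(df = 4) {
  list(
    name = "spline_logistic",
    fit = function(x, y) {
      cc <- continuous_cols(x)
      basis <- x
      if (length(cc)) {
        sp <- do.call(cbind, lapply(cc, function(j) {
          b <- splines::ns(x[, j], df = df)
          colnames(b) <- paste0(colnames(x)[j], "_ns", seq_len(ncol(b)))
          b
        }))
        basis <- cbind(x[, -cc, drop = FALSE], sp)
        knots <- lapply(cc, function(j) {
          b <- splines::ns(x[, j], df = df)
          list(knots = attr(b, "knots"), boundary = attr(b, "Boundary.knots"))
        })
      } else {
        knots <- list()
      }
      dat <- data.frame(y = y, basis, check.names = TRUE)
      m <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
      list(model = m, cc = cc, knots = knots, df = df, orig_cols = colnames(x))
    },
    predict = function(model, x) {
      basis <- x
      if (length(model$cc)) {
        sp <- do.call(cbind, purrr::map2(model$cc, model$knots, function(j, kn) {
          b <- splines::ns(x[, j], knots = kn$knots, Boundary.knots = kn$boundary)
          colnames(b) <- paste0(model$orig_cols[j], "_ns", seq_len(ncol(b)))
          b
        }))
        basis <- cbind(x[, -model$cc, drop = FALSE], sp)
      }
      as.numeric(suppressWarnings(
        predict(model$model, newdata = data.frame(basis, check.names = TRUE),
                type = "response")
      ))
    }
  )
}

#' Assemble a learner library
#'
#' `"default"` mirrors a six-family ensemble (logistic, GAM, random forest,
#' gradient boosting, spline logistic, L1 logistic); `"fast"` is a lean
#' profile (logistic, L1 logistic, shallow boosting) for simulation work;
#' `"glm"` is the logistic model alone.
#'
#' @param profile `"default"`, `"fast"` or `"glm"`.
#' @return List of learner specifications.
#' @export
learner_library <- function(profile = c("default", "fast", "glm")) {
  profile <- match.arg(profile)
  switch(profile,
    default = list(lrnr_glm(), lrnr_gam(), lrnr_ranger(), lrnr_xgboost(),
                   lrnr_spline(), lrnr_glmnet()),
    fast = list(lrnr_glm(), lrnr_glmnet(), lrnr_xgboost(nrounds = 30, max_depth = 2)),
    glm = list(lrnr_glm())
  )
}

#' Practice-clustered, outcome-stratified cross-validation folds
#'
#' Assigns whole clusters (practices) to folds: clusters are sorted by
#' outcome prevalence (seeded jitter breaks ties) and dealt to the K folds
#' serpentine-style, then fold sizes are rebalanced by pairwise cluster
#' swaps that do not worsen the spread of fold-level outcome prevalence.
#' No cluster is ever split across folds.
#'
#' @param cluster_ids Per-observation cluster (practice) identifier.
#' @param outcomes Per-observation binary outcome.
#' @param K Number of folds (default 10).
#' @param seed Seed for tie-breaking.
#' @return A `fold_assignment` list: `fold` (per observation), `cluster_fold`
#'   tibble, `K`, `seed`.
#' @export
make_folds <- function(cluster_ids, outcomes, K = 10, seed = 1) {
  stopifnot(length(cluster_ids) == length(outcomes), K >= 2)
  cl <- tibble::tibble(cluster = cluster_ids, y = outcomes) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(), events = sum(.data$y), .groups = "drop") |>
    dplyr::mutate(prev = .data$events / .data$size)
  if (nrow(cl) < K) {
    abort(sprintf("need at least K = %d clusters, got %d", K, nrow(cl)),
          class = "teletmle_validation_error")
  }
  jit <- with_stream_seed(seed, "folds", runif(nrow(cl), 0, 1e-9))
  ord <- order(cl$prev + jit)
  # serpentine deal: 1..K, K..1, 1..K, ...
  n <- nrow(cl)
  pattern <- rep(c(seq_len(K), rev(seq_len(K))), length.out = n)
  fold_of <- integer(n)
  fold_of[ord] <- pattern
  cl$fold <- fold_of

  fsize <- as.numeric(tapply(cl$size, cl$fold, sum)[as.character(seq_len(K))])
  fevents <- as.numeric(tapply(cl$events, cl$fold, sum)[as.character(seq_len(K))])
  spread_after <- function(fi, fj, dsize, devents) {
    s <- fsize; e <- fevents
    s[fi] <- s[fi] - dsize; e[fi] <- e[fi] - devents
    s[fj] <- s[fj] + dsize; e[fj] <- e[fj] + devents
    diff(range(e / s))
  }
  for (pass in 1:25) {
    big <- which.max(fsize); small <- which.min(fsize)
    gap <- fsize[big] - fsize[small]
    if (gap <= max(2, 0.05 * mean(fsize))) break
    cand_big <- which(cl$fold == big)
    cand_small <- which(cl$fold == small)
    base_spread <- diff(range(fevents / fsize))
    best <- NULL; best_gap <- gap
    for (i in cand_big) {
      for (j in cand_small) {
        dsize <- cl$size[i] - cl$size[j]
        if (dsize <= 0) next
        new_gap <- abs(gap - 2 * dsize)
        if (new_gap >= best_gap) next
        devents <- cl$events[i] - cl$events[j]
        if (spread_after(big, small, dsize, devents) <= base_spread + 1e-9) {
          best <- c(i, j); best_gap <- new_gap
        }
      }
    }
    if (is.null(best)) break
    dsize <- cl$size[best[1]] - cl$size[best[2]]
    devents <- cl$events[best[1]] - cl$events[best[2]]
    fsize[big] <- fsize[big] - dsize; fsize[small] <- fsize[small] + dsize
    fevents[big] <- fevents[big] - devents; fevents[small] <- fevents[small] + devents
    cl$fold[best[1]] <- small; cl$fold[best[2]] <- big
  }
  fold <- cl$fold[match(cluster_ids, cl$cluster)]
  structure(
    list(fold = fold,
         cluster_fold = dplyr::select(cl, "cluster", "fold", "size", "prev"),
         K = K, seed = seed),
    class = "fold_assignment"
  )
}

#' Non-negative least squares metalearner weights
#'
#' Solves `argmin_{a >= 0} ||y - Z a||^2` (Lawson-Hanson NNLS) over the
#' out-of-fold prediction matrix `Z`, then normalises the weights to sum to
#' one. An all-zero solution falls back to uniform weights with a warning.
#'
#' @param Z n-by-L matrix of cross-validated predictions in `[0, 1]`.
#' @param y Binary outcome vector.
#' @return Nonnegative weight vector summing to 1 (named by `colnames(Z)`).
#' @export
nnls_meta <- function(Z, y) {
  Z <- as.matrix(Z)
  if (ncol(Z) == 0 || all(Z == 0)) {
    abort("prediction matrix has rank 0", class = "teletmle_validation_error")
  }
  a <- pracma::lsqnonneg(Z, as.numeric(y))$x
  if (sum(a) == 0) {
    warn("NNLS returned the zero vector; falling back to uniform weights")
    a <- rep(1, ncol(Z))
  }
  a <- a / sum(a)
  names(a) <- colnames(Z)
  a
}

#' Cross-validated superlearner fit
#'
#' For each fold, trains every learner in the library on the fold's
#' complement and predicts the held-out fold, filling the out-of-fold
#' prediction matrix `Z`; solves the metalearner on `(Z, y)`; and refits
#' every learner on the full data for prediction. A learner failing on any
#' fold is dropped entirely with a warning, never silently zeroed.
#'
#' @param x Numeric design matrix (fully encoded, no missing values).
#' @param y Binary outcome vector.
#' @param folds A `fold_assignment` from [make_folds()].
#' @param library Learner list (see [learner_library()]).
#' @param metalearner `"nnls"` (default) or `"discrete"` (weight 1 on the
#'   learner with the lowest cross-validated squared error).
#' @param seed Seed for stochastic learners.
#' @return A `superlearner_fit` with weights `alpha`, the matrix `Z`,
#'   per-learner CV risks, and full-data refits; predict with
#'   [predict.superlearner_fit()].
#' @export
cv_fit <- function(x, y, folds, library = learner_library("fast"),
                   metalearner = c("nnls", "discrete"), seed = 1) {
  metalearner <- match.arg(metalearner)
  stopifnot(inherits(folds, "fold_assignment"), nrow(x) == length(y),
            all(y %in% 0:1))
  x <- as.matrix(x)
  L <- length(library)
  nm <- vapply(library, `[[`, character(1), "name")
  nm <- make.unique(nm)
  Z <- matrix(NA_real_, nrow(x), L, dimnames = list(NULL, nm))
  failed <- rep(FALSE, L)
  for (k in sort(unique(folds$fold))) {
    tr <- folds$fold != k
    te <- !tr
    for (l in seq_len(L)) {
      if (failed[l]) next
      res <- tryCatch({
        set.seed(derive_seed(seed, "learners") + 1000L * l + k)
        m <- library[[l]]$fit(x[tr, , drop = FALSE], y[tr])
        clip_prob(library[[l]]$predict(m, x[te, , drop = FALSE]))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("learner '%s' failed on fold %d and was dropped: %s",
                     nm[l], k, conditionMessage(res)))
        failed[l] <- TRUE
      } else {
        Z[te, l] <- res
      }
    }
  }
  keep <- which(!failed)
  if (!length(keep)) abort("every learner failed", class = "teletmle_fit_error")
  Z <- Z[, keep, drop = FALSE]
  cv_risk <- tibble::tibble(
    learner = nm[keep],
    mse = apply(Z, 2, function(z) mean((y - z)^2)),
    logloss = apply(Z, 2, function(z) -mean(y * log(z) + (1 - y) * log(1 - z)))
  )
  alpha <- if (metalearner == "nnls") {
    nnls_meta(Z, y)
  } else {
    a <- rep(0, ncol(Z)); a[which.min(cv_risk$mse)] <- 1
    setNames(a, colnames(Z))
  }
  refits <- lapply(keep, function(l) {
    set.seed(derive_seed(seed, "learners") + 1000L * l)
    library[[l]]$fit(x, y)
  })
  structure(
    list(learners = library[keep], learner_names = nm[keep], alpha = alpha,
         Z = Z, folds = folds, cv_risk = cv_risk, refits = refits,
         metalearner = metalearner, seed = seed),
    class = "superlearner_fit"
  )
}

#' Predict from a superlearner fit
#'
#' The stacked prediction `sum_l alpha_l * learner_l(x)`, clipped into
#' (0, 1).
#'
#' @param object A `superlearner_fit`.
#' @param newdata Numeric design matrix with the training columns.
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.superlearner_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- matrix(0, nrow(newdata), length(object$refits))
  for (l in seq_along(object$refits)) {
    p[, l] <- clip_prob(object$learners[[l]]$predict(object$refits[[l]], newdata))
  }
  clip_prob(drop(p %*% object$alpha))
}

#' @export
print.superlearner_fit <- function(x, ...) {
  cat("<superlearner fit>", length(x$refits), "learners,", x$folds$K, "folds\n")
  w <- x$alpha
  for (l in seq_along(w)) {
    cat(sprintf("  %-16s weight %.3f  cv-mse %.4f\n",
                x$learner_names[l], w[l], x$cv_risk$mse[l]))
  }
  invisible(x)
}
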