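#' Single-chain predictive mean matching imputation
#'
#' Chained single imputation: per variable with missing entries, a linear
#' regression on the remaining variables (using current imputations)
#' predicts every row; each missing entry receives the observed value of
#' one of the `k_donors` donors whose predicted means are nearest, chosen
#' at random.  The chain is iterated and is reproducible from `seed`.
#'
#' @param scores subject x variable numeric matrix (may contain `NA`).
#' @param k_donors donor pool size.
#' @param iterations chained passes over the variables.
#' @param seed integer seed.
#' @return matrix of the same shape with no missing values.
#' @export
pmm_impute <- function(scores, k_donors = 5, iterations = 10, seed = 1L) {
  x <- as.matrix(scores)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  stop_if(any(colSums(!miss) < k_donors),
          "each variable needs at least k_donors observed values")
  with_seed(derive_seed(seed, 17L), {
    # initialise with column means of observed values
    for (j in seq_len(ncol(x))) {
      x[miss[, j], j] <- mean(x[!miss[, j], j])
    }
    for (it in seq_len(iterations)) {
      for (j in which(colSums(miss) > 0)) {
        obs <- which(!miss[, j])
        mis <- which(miss[, j])
        X <- cbind(1, x[, -j, drop = FALSE])
        fit <- lm.fit(X[obs, , drop = FALSE], scores[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred <- as.numeric(X %*% beta)
        for (i in mis) {
          d <- abs(pred[obs] - pred[i])
          donors <- obs[order(d)[seq_len(k_donors)]]
          x[i, j] <- scores[sample(donors, 1), j]
        }
      }
    }
    x
  })
}

#' Inter-subject FC-similarity kernel
#'
#' `K(s, s')` is the Pearson correlation between the subjects'
#' upper-triangle Fisher-z vectors; the kernel is made positive
#' semidefinite by clipping negative eigenvalues at zero and renormalising
#' to unit diagonal.
#'
#' @param fc_list list of `fc_matrix` objects (or a subject x edge matrix).
#' @return subject x subject kernel matrix.
#' @export
correlation_kernel <- function(fc_list) {
  z <- if (is.list(fc_list) && inherits(fc_list[[1]], "fc_matrix")) {
    do.call(rbind, lapply(fc_list, function(f) upper_tri_vec(f$z)))
  } else as.matrix(fc_list)
  stop_if(nrow(z) < 3, "need at least 3 subjects")
  stop_if(any(apply(z, 1, sd) == 0), "zero-variance FC vector")
  K <- cor(t(z))
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  K <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(K), 1e-12))
  K <- K / (d %o% d)
  (K + t(K)) / 2
}

default_lambda_grid <- function() 10^seq(-3, 3, length.out = 16)

# Ridge solve with automatic fall-forward through the grid on singularity.
krr_solve <- function(K_tt, y_t, lambda, grid) {
  gi <- which(grid >= lambda)
  for (l in grid[gi]) {
    a <- tryCatch(solve(K_tt + diag(l, nrow(K_tt)), y_t),
                  error = function(e) NULL)
    if (!is.null(a)) {
      if (l > lambda) warning("lambda increased to ", signif(l, 3),
                              " to avoid a singular system")
      return(a)
    }
  }
  stop("kernel system singular at every lambda", call. = FALSE)
}

#' Cross-validated kernel ridge regression accuracy
#'
#' Repeated k-fold CV.  Within each training fold, covariates (e.g. mean
#' FD) are regressed from the behaviour (betas learned on the training
#' set and applied to the test set) and the behaviour is z-normalised on
#' training statistics; an inner 5-fold CV selects the ridge penalty from
#' `lambda_grid` by validation correlation; test predictions are
#' `K_xt (K_tt + lambda I)^{-1} y_t`.  Accuracy is the Pearson correlation
#' between prediction and residualised observed behaviour, averaged over
#' folds and repeats.
#'
#' @param kernel subject x subject kernel from [correlation_kernel()].
#' @param y per-subject behaviour vector, or subject x behaviour matrix.
#' @param covariates optional subject x k covariate matrix.
#' @param folds outer folds.
#' @param repeats outer repeats.
#' @param lambda_grid candidate ridge penalties.
#' @param inner_folds folds of the lambda-selection CV.
#' @param seed integer seed for fold shuffling.
#' @return named numeric vector of mean accuracies, one per behaviour.
#' @export
cv_evaluate <- function(kernel, y, covariates = NULL, folds = 5,
                        repeats = 10, lambda_grid = default_lambda_grid(),
                        inner_folds = 5, seed = 1L) {
  y <- as.matrix(y)
  n <- nrow(y)
  stop_if(nrow(kernel) != n, "kernel and behaviour are misaligned")
  stop_if(length(lambda_grid) == 0, "lambda grid is empty")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stop_if(nrow(covariates) != n, "covariates misaligned")
  }

  resid_cov <- function(yv, train, test) {
    if (is.null(covariates)) {
      list(train = yv[train], test = yv[test])
    } else {
      X <- cbind(1, covariates)
      beta <- lm.fit(X[train, , drop = FALSE], yv[train])$coefficients
      beta[is.na(beta)] <- 0
      list(train = yv[train] - as.numeric(X[train, , drop = FALSE] %*% beta),
           test = yv[test] - as.numeric(X[test, , drop = FALSE] %*% beta))
    }
  }

  acc <- matrix(NA_real_, repeats, ncol(y))
  for (rep_i in seq_len(repeats)) {
    assign_outer <- with_seed(derive_seed(seed, rep_i), {
      sample(rep_len(seq_len(folds), n))
    })
    pred_all <- matrix(NA_real_, n, ncol(y))
    yres_all <- matrix(NA_real_, n, ncol(y))
    for (f in seq_len(folds)) {
      test <- which(assign_outer == f)
      train <- which(assign_outer != f)
      if (length(test) < 2 || length(train) < inner_folds + 2) next
      for (b in seq_len(ncol(y))) {
        yr <- resid_cov(y[, b], train, test)
        mu <- mean(yr$train); s <- sd(yr$train)
        if (s == 0) next
        y_tr <- (yr$train - mu) / s
        y_te <- (yr$test - mu) / s

        # inner CV for lambda
        assign_inner <- with_seed(derive_seed(seed, 1000L + rep_i * 10L + f), {
          sample(rep_len(seq_len(inner_folds), length(train)))
        })
        best_r <- -Inf; best_l <- lambda_grid[1]
        for (l in lambda_grid) {
          preds <- rep(NA_real_, length(train))
          for (g in seq_len(inner_folds)) {
            val <- which(assign_inner == g)
            tr <- which(assign_inner != g)
            if (length(val) < 2) next
            a <- tryCatch(solve(kernel[train[tr], train[tr]] +
                                  diag(l, length(tr)), y_tr[tr]),
                          error = function(e) NULL)
            if (is.null(a)) next
            preds[val] <- as.numeric(kernel[train[val], train[tr]] %*% a)
          }
          ok <- !is.na(preds)
          if (sum(ok) > 3 && sd(preds[ok]) > 0 && sd(y_tr[ok]) > 0) {
            r <- cor(preds[ok], y_tr[ok])
            if (is.finite(r) && r > best_r) { best_r <- r; best_l <- l }
          }
        }
        a <- krr_solve(kernel[train, train], y_tr, best_l, lambda_grid)
        pred_all[test, b] <- as.numeric(kernel[test, train] %*% a)
        yres_all[test, b] <- y_te
      }
    }
    # accuracy per repeat: correlation over predictions pooled across folds
    for (b in seq_len(ncol(y))) {
      ok <- !is.na(pred_all[, b]) & !is.na(yres_all[, b])
      if (sum(ok) > 3 && sd(pred_all[ok, b]) > 0 && sd(yres_all[ok, b]) > 0) {
        acc[rep_i, b] <- cor(pred_all[ok, b], yres_all[ok, b])
      }
    }
  }
  out <- colMeans(acc, na.rm = TRUE)
  names(out) <- colnames(y)
  out
}

#' Aggregate prediction accuracies into family and overall means
#'
#' @param accuracies named per-behaviour accuracy vector.
#' @param cognition names of the cognitive behaviours.
#' @return list: `cognition`, `personality`, `overall` (mean of the two
#'   family means).
#' @export
aggregate_prediction <- function(accuracies,
                                 cognition = c("vocabulary",
                                               "matrix_reasoning")) {
  nm <- names(accuracies)
  if (is.null(nm)) nm <- behavior_names(length(accuracies))
  is_cog <- nm %in% cognition
  stop_if(!any(is_cog) || all(is_cog),
          "need at least one behaviour in each family")
  cog <- mean(accuracies[is_cog])
  pers <- mean(accuracies[!is_cog])
  list(cognition = cog, personality = pers, overall = mean(c(cog, pers)))
}
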