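#' Registered presence/pseudo-absence learners
#'
#' @return character vector of algorithm ids.
#' @export
sdm_algorithms <- function() {
  c("GLM", "GBM", "RF", "CTA", "ANN", "FDA", "MARS", "MAXENT", "XGBOOST")
}

# predictor frame with categorical columns as factors on fixed levels
predictor_frame <- function(df, variables, categorical, cat_levels = NULL) {
  out <- df[, variables, drop = FALSE]
  for (v in categorical) {
    lv <- if (!is.null(cat_levels[[v]])) cat_levels[[v]] else sort(unique(out[[v]]))
    out[[v]] <- factor(out[[v]], levels = lv)
  }
  out
}

# dummy-coded numeric design matrix (no intercept column)
design_matrix <- function(pf) {
  stats::model.matrix(~ ., data = pf)[, -1L, drop = FALSE]
}

# hinge feature expansion used by the MAXENT-style learner
maxent_features <- function(pf, categorical, knots = NULL, center = NULL,
                            scale = NULL) {
  cont <- setdiff(names(pf), categorical)
  x <- as.matrix(pf[, cont, drop = FALSE])
  if (is.null(center)) {
    center <- colMeans(x); scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
    knots <- lapply(cont, function(v) {
      stats::quantile(x[, v], c(0.25, 0.5, 0.75), names = FALSE)
    })
    names(knots) <- cont
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  feats <- cbind(xs, xs^2)
  colnames(feats) <- c(cont, paste0(cont, "_sq"))
  for (v in cont) {
    kv <- (knots[[v]] - center[v]) / scale[v]
    h <- vapply(kv, function(k) pmax(0, xs[, v] - k), numeric(nrow(xs)))
    colnames(h) <- paste0(v, "_h", seq_along(kv))
    feats <- cbind(feats, h)
  }
  if (length(categorical)) {
    feats <- cbind(feats, design_matrix(pf[, categorical, drop = FALSE]))
  }
  list(x = feats, knots = knots, center = center, scale = scale)
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# one fitter per algorithm id; each returns list(predict_fun = function(pf) probs)
fit_learner <- function(algorithm, pf, y, seed, params = list()) {
  categorical <- names(pf)[vapply(pf, is.factor, TRUE)]
  switch(algorithm,
    GLM = {
      d <- cbind(pf, .y = y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      list(predict_fun = function(new) {
        clamp01(suppressWarnings(stats::predict(fit, newdata = new, type = "response")))
      })
    },
    CTA = {
      d <- cbind(pf, .y = factor(y, levels = c(0, 1)))
      fit <- with_seed(seed, rpart::rpart(.y ~ ., data = d, method = "class",
        control = rpart::rpart.control(minsplit = params$minsplit %||% 10,
                                       cp = params$cp %||% 0.01)))
      list(predict_fun = function(new) {
        clamp01(stats::predict(fit, newdata = new, type = "prob")[, "1"])
      })
    },
    RF = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = pf, y = factor(y, levels = c(0, 1)),
        ntree = params$ntree %||% 500))
      list(predict_fun = function(new) {
        clamp01(stats::predict(fit, newdata = new, type = "prob")[, "1"])
      })
    },
    GBM = ,
    XGBOOST = {
      hp <- if (algorithm == "GBM") {
        list(eta = 0.1, max_depth = 3, nrounds = 100)
      } else {
        list(eta = 0.3, max_depth = 6, nrounds = 60)
      }
      hp[names(params)] <- params
      dm <- design_matrix(pf)
      dtrain <- xgboost::xgb.DMatrix(dm, label = y)
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1),
        data = dtrain, nrounds = hp$nrounds, verbose = 0))
      cols <- colnames(dm)
      list(predict_fun = function(new) {
        nd <- design_matrix(new)[, cols, drop = FALSE]
        clamp01(stats::predict(fit, newdata = xgboost::xgb.DMatrix(nd)))
      })
    },
    ANN = {
      dm <- design_matrix(pf)
      ctr <- colMeans(dm); scl <- apply(dm, 2L, stats::sd); scl[scl == 0] <- 1
      xs <- sweep(sweep(dm, 2L, ctr), 2L, scl, "/")
      fit <- with_seed(seed, nnet::nnet(
        x = xs, y = y, size = params$size %||% 5,
        decay = params$decay %||% 0.01, maxit = params$maxit %||% 300,
        entropy = TRUE, trace = FALSE))
      if (stats::sd(as.numeric(stats::predict(fit, xs))) < 1e-8) {
        stop("network converged to constant output")
      }
      cols <- colnames(dm)
      list(predict_fun = function(new) {
        nd <- design_matrix(new)[, cols, drop = FALSE]
        nds <- sweep(sweep(nd, 2L, ctr), 2L, scl, "/")
        clamp01(stats::predict(fit, nds))
      })
    },
    FDA = {
      # discriminant on a linear + quadratic basis of the continuous terms
      cont <- setdiff(names(pf), categorical)
      basis <- function(new) {
        x <- as.matrix(new[, cont, drop = FALSE])
        b <- cbind(x, x^2)
        colnames(b) <- c(cont, paste0(cont, "_sq"))
        if (length(categorical)) {
          b <- cbind(b, design_matrix(new[, categorical, drop = FALSE]))
        }
        b
      }
      fit <- MASS::lda(x = basis(pf), grouping = factor(y, levels = c(0, 1)))
      list(predict_fun = function(new) {
        clamp01(stats::predict(fit, newdata = basis(new))$posterior[, "1"])
      })
    },
    MARS = {
      # adaptive spline surface: penalized smooth per continuous term
      cont <- setdiff(names(pf), categorical)
      k <- params$k %||% 5
      terms <- c(
        vapply(cont, function(v) sprintf("s(%s, k = %d)", v, k), ""),
        categorical
      )
      d <- cbind(pf, .y = y)
      fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      fit <- with_seed(seed, mgcv::gam(fml, data = d, family = stats::binomial(),
                                      method = "REML"))
      list(predict_fun = function(new) {
        clamp01(stats::predict(fit, newdata = new, type = "response"))
      })
    },
    MAXENT = {
      # regularized logistic regression on linear + quadratic + hinge features
      mf <- maxent_features(pf, categorical)
      foldid <- with_seed(seed, sample(rep_len(1:5, length(y))))
      cv <- glmnet::cv.glmnet(mf$x, y, family = "binomial", alpha = 1,
                              foldid = foldid)
      list(predict_fun = function(new) {
        nf <- maxent_features(new, categorical, knots = mf$knots,
                              center = mf$center, scale = mf$scale)
        clamp01(stats::predict(cv, newx = nf$x, s = "lambda.1se",
                               type = "response"))
      })
    },
    stop(sprintf("unknown algorithm id '%s'", algorithm))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one learner and evaluate it on the held-out split
#'
#' Trains the named learner family on the `train` rows of a model table
#' and computes validation metrics (TSS-optimal threshold, AUC, kappa,
#' CSI) plus the composite score on the `valid` rows only. A fit that
#' errors or collapses to constant output is returned flagged `failed`
#' (it is recorded, not dropped, so model-count bookkeeping stays
#' honest) and is excluded from ensembles downstream.
#'
#' @param algorithm one of [sdm_algorithms()].
#' @param table a model table with a `split` column (see [split_rows()]).
#' @param seed RNG seed for the stochastic learners.
#' @param repetition repetition index carried into reports.
#' @param params named list of hyperparameter overrides; defaults are
#'   pinned in the fitters so runs are reproducible.
#' @return object of class `sdm_fit`.
#' @export
fit_single_model <- function(algorithm, table, seed = 1, repetition = 1L,
                             params = list()) {
  algorithm <- match.arg(algorithm, sdm_algorithms())
  variables <- attr(table, "variables")
  categorical <- attr(table, "categorical") %||% character()
  if (is.null(table$split)) stop("model table has no `split` column")
  tr <- table[table$split == "train", , drop = FALSE]
  va <- table[table$split == "valid", , drop = FALSE]
  if (length(unique(tr$response)) < 2L) stop("train split needs both classes")
  cat_levels <- lapply(categorical, function(v) sort(unique(table[[v]])))
  names(cat_levels) <- categorical
  pf_tr <- predictor_frame(tr, variables, categorical, cat_levels)
  base <- list(algorithm = algorithm, repetition = as.integer(repetition),
               seed = seed, variables = variables, categorical = categorical,
               cat_levels = cat_levels)
  res <- tryCatch({
    lrn <- fit_learner(algorithm, pf_tr, tr$response, seed, params)
    pf_va <- predictor_frame(va, variables, categorical, cat_levels)
    scores <- lrn$predict_fun(pf_va)
    metrics <- evaluate_predictions(scores, va$response)
    c(base, list(predict_fun = lrn$predict_fun, metrics = metrics,
                 gamma = gamma_score(metrics), failed = FALSE, message = NULL))
  }, error = function(e) {
    c(base, list(predict_fun = NULL, metrics = NULL, gamma = NA_real_,
                 failed = TRUE, message = conditionMessage(e)))
  })
  structure(res, class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("sdm_fit %s (rep %d): FAILED (%s)\n", x$algorithm,
                x$repetition, x$message))
  } else {
    cat(sprintf("sdm_fit %s (rep %d): TSS %.3f AUC %.3f gamma %.3f\n",
                x$algorithm, x$repetition, x$metrics$K_TSS,
                x$metrics$K_ROC, x$gamma))
  }
  invisible(x)
}

#' Predict occurrence probabilities from a fit or ensemble
#'
#' @param object an `sdm_fit` or `sdm_ensemble`.
#' @param newdata data.frame containing the fit's predictor columns.
#' @param ... unused.
#' @return numeric probabilities in `[0, 1]`.
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  if (object$failed) stop("cannot predict from a failed fit")
  pf <- predictor_frame(newdata, object$variables, object$categorical,
                        object$cat_levels)
  clamp01(object$predict_fun(pf))
}

#' @rdname predict.sdm_fit
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(f) predict(f, newdata),
                  numeric(nrow(newdata)))
  rowMeans(preds)
}

#' Rank model fits and combine the top k into an ensemble
#'
#' Failed fits and fits below the quality gate are excluded; survivors
#' are ranked by the selection metric (ties broken by higher AUC, then
#' lower repetition index) and the top `k` are combined by unweighted
#' pointwise mean of probabilities. The ensemble is re-evaluated on the
#' validation rows of `table`.
#'
#' @param fits list of `sdm_fit` objects.
#' @param table the model table the fits were trained on.
#' @param metric selection metric: `"TSS"`, `"AUC"` or `"gamma"`.
#' @param k ensemble size (default 5).
#' @param quality_gate minimum TSS for eligibility (default 0.7 for
#'   TSS/gamma-ranked selection, `NULL` = no gate for AUC-ranked
#'   selection).
#' @return object of class `sdm_ensemble` with `members`, `metrics`,
#'   `gamma`.
#' @export
select_and_ensemble <- function(fits, table, metric = c("TSS", "AUC", "gamma"),
                                k = 5,
                                quality_gate = if (match.arg(metric) == "AUC") NULL else 0.7) {
  metric <- match.arg(metric)
  ok <- Filter(function(f) !f$failed, fits)
  if (length(ok) == 0L) stop("no successful fits to ensemble")
  df <- data.frame(
    TSS = vapply(ok, function(f) f$metrics$K_TSS, 0),
    AUC = vapply(ok, function(f) f$metrics$K_ROC, 0),
    gamma = vapply(ok, function(f) f$gamma, 0),
    repetition = vapply(ok, function(f) f$repetition, 0L)
  )
  sel <- select_top_models(df, metric, k, quality_gate)
  members <- ok[sel]
  ens <- structure(list(members = members, metric = metric, k = k),
                   class = "sdm_ensemble")
  va <- table[table$split == "valid", , drop = FALSE]
  scores <- predict(ens, va)
  ens$metrics <- evaluate_predictions(scores, va$response)
  ens$gamma <- gamma_score(ens$metrics)
  ens
}

#' Rank a model-metrics table and return the top-k row indices
#'
#' Selection rule shared by [select_and_ensemble()] and usable on any
#' table of per-model metrics: optional TSS quality gate, rank by the
#' chosen metric descending, ties broken by higher AUC then lower
#' repetition index.
#'
#' @param df data.frame with columns `TSS`, `AUC`, `repetition` and (for
#'   `metric = "gamma"`) `gamma`.
#' @param metric column to rank by.
#' @param k number of rows to select.
#' @param quality_gate minimum TSS, or `NULL` for no gate.
#' @return integer vector of selected row indices, in rank order.
#' @export
select_top_models <- function(df, metric = "TSS", k = 5, quality_gate = 0.7) {
  stopifnot(metric %in% names(df))
  pass <- if (is.null(quality_gate)) rep(TRUE, nrow(df)) else df$TSS >= quality_gate
  if (!any(pass)) {
    stop(sprintf("no model passes the quality gate (best TSS = %.3f)",
                 max(df$TSS)))
  }
  idx <- which(pass)
  ord <- idx[order(-df[[metric]][idx], -df$AUC[idx], df$repetition[idx])]
  ord[seq_len(min(k, length(ord)))]
}

#' Predict a suitability surface over a stack
#'
#' @param object an `sdm_fit` or `sdm_ensemble`.
#' @param stack an [env_stack()] holding every predictor the fit uses.
#' @param variables predictor names (default: the fit's own variables).
#' @return matrix of probabilities in `[0, 1]`; cells with missing
#'   predictor values are `NA`.
#' @export
predict_suitability <- function(object, stack, variables = NULL) {
  if (is.null(variables)) {
    variables <- object$variables %||% object$members[[1L]]$variables
  }
  for (v in variables) {
    if (is.null(stack$layers[[v]]) && is.null(stack$categorical[[v]])) {
      stop(sprintf("variable '%s' missing from stack", v))
    }
  }
  centers <- cell_centers(stack)
  df <- centers
  for (v in variables) {
    df[[v]] <- layer_at_cells(stack, v, centers$row, centers$col)
  }
  complete <- stats::complete.cases(df[, variables, drop = FALSE])
  p <- rep(NA_real_, nrow(df))
  if (any(complete)) {
    p[complete] <- predict(object, df[complete, , drop = FALSE])
  }
  out <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  out[cbind(centers$row, centers$col)] <- p
  out
}

#' Permutation variable importance
#'
#' importance(v) = 1 - Pearson correlation between predictions on the
#' original table and on the table with column `v` permuted, averaged
#' over `n_permutations` seeded permutations and clipped to `[0, 1]`.
#' If the model's predictions are constant, all importances are 0.
#'
#' @param object an `sdm_fit` or `sdm_ensemble`.
#' @param table a model table (all rows are used).
#' @param n_permutations permutations per variable (>= 1).
#' @param seed RNG seed.
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
variable_importance <- function(object, table, n_permutations = 5, seed = 1) {
  stopifnot_scalar_pos(n_permutations, "n_permutations")
  variables <- object$variables %||% object$members[[1L]]$variables
  p0 <- predict(object, table)
  if (stats::sd(p0) < 1e-12) {
    return(stats::setNames(rep(0, length(variables)), variables))
  }
  imp <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    vals <- numeric(n_permutations)
    for (j in seq_len(n_permutations)) {
      perm <- table
      perm[[v]] <- with_seed(derive_seed(seed, j * 131 + match(v, variables)),
                             sample(perm[[v]]))
      pj <- predict(object, perm)
      r <- if (stats::sd(pj) < 1e-12) 0 else stats::cor(p0, pj)
      vals[j] <- 1 - r
    }
    imp[v] <- min(max(mean(vals), 0), 1)
  }
  imp
}
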