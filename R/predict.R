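#' Build a model matrix of RV features for patients
#'
#' Selects patients with the requested target, orders rows
#' deterministically by subject id, and returns the raw (unstandardized)
#' feature matrix: standardization statistics are computed on training
#' folds only, inside the model-fitting routines, to avoid leakage.
#'
#' @param features feature table (`subject_id` + metrics).
#' @param subjects subject table (`group`, `crsr_total`, `outcome`).
#' @param target `"crsr"` (CRS-R total, regression) or `"outcome"`
#'   (binary improved = 1 / unimproved = 0).
#' @return list with `X` (numeric matrix, subjects x metrics), `y`, and
#'   `subject_id`.
#' @export
build_matrix <- function(features, subjects, target = c("crsr", "outcome")) {
  target <- match.arg(target)
  d <- merge(features, subjects, by = "subject_id", sort = FALSE)
  d <- d[d$group == "patient", , drop = FALSE]
  y <- if (target == "crsr") d$crsr_total else
    as.integer(d$outcome == "improved")
  keep <- !is.na(y)
  d <- d[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(d) < 10) {
    stop(sprintf("insufficient data: %d labeled patient(s), need >= 10",
                 nrow(d)), call. = FALSE)
  }
  ord <- order(d$subject_id)
  metric_cols <- intersect(names(features),
                           as.vector(outer(rv_parameters(), rv_metrics(),
                                           paste, sep = "_")))
  X <- as.matrix(d[ord, metric_cols, drop = FALSE])
  rownames(X) <- d$subject_id[ord]
  list(X = X, y = y[ord], subject_id = d$subject_id[ord])
}

# ---- shared tuning machinery ----------------------------------------------

scale_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

make_folds <- function(n, k, strat = NULL) {
  # stratified k-fold assignment; caller controls the RNG state
  f <- integer(n)
  if (is.null(strat)) strat <- rep(1L, n)
  for (s in unique(strat)) {
    i <- which(strat == s)
    f[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  f
}

draw_params <- function(model) {
  switch(model,
    random_forest = list(ntree = sample(c(200L, 300L, 500L), 1),
                         mtry = sample(2:12, 1),
                         nodesize = sample(1:8, 1)),
    elastic_net = list(alpha = stats::runif(1, 0.05, 1),
                       lambda = 10^stats::runif(1, -3, 0.5)),
    svm_rfe = list(cost = 10^stats::runif(1, -1, 2),
                   gamma = 10^stats::runif(1, -3, 0),
                   n_feat = sample(c(5L, 10L, 15L, 20L, 35L), 1)),
    pls = list(ncomp = sample(1:10, 1)),
    logistic_en = list(alpha = stats::runif(1, 0.05, 1),
                       lambda = 10^stats::runif(1, -3, 0.5)),
    logistic_rf = list(k = sample(c(3L, 5L, 8L, 12L), 1),
                       ntree = 300L))
}

# linear-surrogate SVM-RFE feature ranking: iteratively fit a linear SVM
# and drop the half of the features with the smallest |w|
svm_rfe_rank <- function(X, y, classification = FALSE) {
  feats <- colnames(X)
  ranking <- character(0)
  while (length(feats) > 1) {
    fit <- e1071::svm(X[, feats, drop = FALSE], y, kernel = "linear",
                      scale = FALSE,
                      type = if (classification) "C-classification" else
                        "eps-regression")
    w <- t(fit$coefs) %*% fit$SV
    score <- drop(w)^2
    ord <- order(score, feats) # ties by name for determinism
    n_drop <- max(1L, floor(length(feats) / 2))
    dropped <- feats[ord[seq_len(n_drop)]]
    ranking <- c(dropped, ranking)
    feats <- setdiff(feats, dropped)
  }
  c(feats, ranking) # best first
}

fit_crsr_model <- function(model, params, Xtr, ytr) {
  sc <- scale_fit(Xtr)
  Xs <- scale_apply(Xtr, sc)
  obj <- switch(model,
    random_forest = randomForest::randomForest(
      Xtr, ytr, ntree = params$ntree,
      mtry = min(params$mtry, ncol(Xtr)), nodesize = params$nodesize),
    elastic_net = glmnet::glmnet(Xs, ytr, alpha = params$alpha,
                                 lambda = params$lambda),
    svm_rfe = {
      rk <- svm_rfe_rank(Xs, ytr)
      feats <- rk[seq_len(min(params$n_feat, length(rk)))]
      list(svm = e1071::svm(Xs[, feats, drop = FALSE], ytr,
                            kernel = "radial", cost = params$cost,
                            gamma = params$gamma, scale = FALSE),
           feats = feats)
    },
    pls = mixOmics::pls(Xs, ytr, ncomp = params$ncomp, mode = "regression"))
  list(model = model, obj = obj, params = params, scaling = sc,
       feature_names = colnames(Xtr))
}

predict_crsr_model <- function(fit, Xte) {
  Xs <- scale_apply(Xte[, fit$feature_names, drop = FALSE], fit$scaling)
  switch(fit$model,
    random_forest = as.numeric(predict(
      fit$obj, Xte[, fit$feature_names, drop = FALSE])),
    elastic_net = as.numeric(predict(fit$obj, Xs, s = fit$params$lambda)),
    svm_rfe = as.numeric(predict(
      fit$obj$svm, Xs[, fit$obj$feats, drop = FALSE])),
    pls = as.numeric(predict(fit$obj, Xs)$predict[, 1, fit$params$ncomp]))
}

tune_crsr <- function(model, Xtr, ytr, n_iter, inner_k) {
  folds <- make_folds(length(ytr), inner_k)
  best <- NULL
  best_mse <- Inf
  trace <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    params <- draw_params(model)
    pred <- rep(NA_real_, length(ytr))
    ok <- TRUE
    for (f in seq_len(inner_k)) {
      te <- folds == f
      fit <- try(fit_crsr_model(model, params, Xtr[!te, , drop = FALSE],
                                ytr[!te]), silent = TRUE)
      if (inherits(fit, "try-error")) { ok <- FALSE; break }
      pred[te] <- predict_crsr_model(fit, Xtr[te, , drop = FALSE])
    }
    if (!ok) next
    mse <- mean((pred - ytr)^2)
    trace[[i]] <- c(params, mse = mse)
    if (mse < best_mse) { best_mse <- mse; best <- params }
  }
  if (is.null(best)) stop(sprintf("tuning failed for %s", model),
                          call. = FALSE)
  list(params = best, mse = best_mse, trace = trace)
}

#' Benchmark CRS-R regression models with nested cross-validation
#'
#' Four model families — random forest, elastic net, RBF-SVM with
#' recursive feature elimination on a linear-surrogate ranking, and
#' partial least squares — evaluated by nested cross-validation: an
#' outer k-fold for honest error estimation, an inner k-fold random
#' search for hyperparameter tuning within each outer training set.
#' MSE, RMSE, MAE and R-squared are computed on the pooled outer-fold
#' predictions. A final model per family is tuned and refit on all data
#' for deployment via [predict_single()].
#'
#' @param X,y from [build_matrix()] with `target = "crsr"`.
#' @param config list: `models`, `n_iter` (random-search draws, default
#'   50), `outer_k`, `inner_k` (default 5 and 5).
#' @param seed integer seed.
#' @return object of class `regression_report`: list with `metrics`
#'   (data.frame model x {mse, rmse, mae, r2}), `predictions`,
#'   `importance` (random-forest permutation importance, descending),
#'   `bundles` (per-model deployment fits), `tuning` traces.
#' @export
train_crsr_models <- function(X, y, config = list(), seed = 1L) {
  models <- config$models %||% c("random_forest", "elastic_net",
                                 "svm_rfe", "pls")
  n_iter <- config$n_iter %||% 50L
  outer_k <- config$outer_k %||% 5L
  inner_k <- config$inner_k %||% 5L
  if (stats::var(y) == 0) stop("degenerate target: y is constant",
                               call. = FALSE)
  out_metrics <- list(); out_pred <- list(); bundles <- list(); tuning <- list()
  for (model in models) {
    pred <- rep(NA_real_, length(y))
    folds <- with_seed(child_seed(seed, 1L), make_folds(length(y), outer_k))
    for (f in seq_len(outer_k)) {
      te <- folds == f
      tuned <- with_seed(child_seed(seed, 100L + f),
                         tune_crsr(model, X[!te, , drop = FALSE], y[!te],
                                   n_iter, inner_k))
      fit <- with_seed(child_seed(seed, 200L + f),
                       fit_crsr_model(model, tuned$params,
                                      X[!te, , drop = FALSE], y[!te]))
      pred[te] <- predict_crsr_model(fit, X[te, , drop = FALSE])
    }
    mse <- mean((pred - y)^2)
    out_metrics[[model]] <- data.frame(
      model = model, mse = mse, rmse = sqrt(mse),
      mae = mean(abs(pred - y)),
      r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
    out_pred[[model]] <- pred
    final_tuned <- with_seed(child_seed(seed, 300L),
                             tune_crsr(model, X, y, n_iter, inner_k))
    bundles[[model]] <- with_seed(
      child_seed(seed, 301L),
      c(fit_crsr_model(model, final_tuned$params, X, y),
        list(task = "crsr", y_range = range(y))))
    class(bundles[[model]]) <- "respvar_bundle"
    tuning[[model]] <- final_tuned$trace
  }
  imp <- NULL
  if ("random_forest" %in% models) {
    rf_fit <- with_seed(child_seed(seed, 400L), randomForest::randomForest(
      X, y, ntree = 500, importance = TRUE))
    imp <- importance_top_k(rf_fit, k = ncol(X))
  }
  structure(list(metrics = do.call(rbind, c(out_metrics,
                                            make.row.names = FALSE)),
                 predictions = out_pred, importance = imp,
                 bundles = bundles, tuning = tuning, seed = seed),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("CRS-R regression (nested CV, pooled outer-fold predictions):\n")
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}

# ---- outcome classification ------------------------------------------------

fit_outcome_pipeline <- function(pipeline, params, Xtr, ytr) {
  sc <- scale_fit(Xtr)
  Xs <- scale_apply(Xtr, sc)
  obj <- switch(pipeline,
    rf_direct = randomForest::randomForest(
      Xtr, factor(ytr, levels = 0:1), ntree = params$ntree %||% 300L,
      mtry = min(params$mtry %||% 6L, ncol(Xtr)),
      nodesize = params$nodesize %||% 1L),
    en_select_logistic = {
      en <- glmnet::glmnet(Xs, ytr, family = "binomial",
                           alpha = params$alpha, lambda = params$lambda)
      co <- as.matrix(stats::coef(en))[-1, 1]
      feats <- names(co)[co != 0]
      if (length(feats) == 0) feats <- colnames(Xs)[1] # null model guard
      glm_fit <- stats::glm(
        y ~ ., family = stats::binomial(),
        data = data.frame(y = ytr, Xs[, feats, drop = FALSE]))
      list(glm = glm_fit, feats = feats)
    },
    rf_select_logistic = {
      rf <- randomForest::randomForest(Xtr, factor(ytr, levels = 0:1),
                                       ntree = params$ntree %||% 300L,
                                       importance = TRUE)
      feats <- importance_top_k(rf, k = params$k)$feature
      glm_fit <- stats::glm(
        y ~ ., family = stats::binomial(),
        data = data.frame(y = ytr, Xs[, feats, drop = FALSE]))
      list(glm = glm_fit, feats = feats)
    })
  list(pipeline = pipeline, obj = obj, params = params, scaling = sc,
       feature_names = colnames(Xtr))
}

predict_outcome_pipeline <- function(fit, Xte) {
  Xs <- scale_apply(Xte[, fit$feature_names, drop = FALSE], fit$scaling)
  switch(fit$pipeline,
    rf_direct = unname(predict(fit$obj,
                               Xte[, fit$feature_names, drop = FALSE],
                               type = "prob")[, "1"]),
    en_select_logistic = ,
    rf_select_logistic = unname(predict(
      fit$obj$glm,
      newdata = as.data.frame(Xs[, fit$obj$feats, drop = FALSE]),
      type = "response")))
}

loocv_auc <- function(pipeline, params, Xtr, ytr) {
  pred <- rep(NA_real_, length(ytr))
  for (i in seq_along(ytr)) {
    fit <- try(suppressWarnings(
      fit_outcome_pipeline(pipeline, params, Xtr[-i, , drop = FALSE],
                           ytr[-i])), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    pred[i] <- suppressWarnings(
      predict_outcome_pipeline(fit, Xtr[i, , drop = FALSE]))
  }
  as.numeric(suppressMessages(pROC::auc(pROC::roc(ytr, pred, quiet = TRUE,
                                                  direction = "<"))))
}

#' Benchmark clinical-outcome classification pipelines
#'
#' Three pipelines: direct random forest; elastic-net-penalized logistic
#' feature selection followed by plain logistic regression; and
#' random-forest permutation-importance selection (top-k) followed by
#' logistic regression. Hyperparameters and feature-selection settings
#' are tuned by leave-one-out cross-validated AUC with random search
#' inside the training partition; performance is reported on a held-out
#' stratified validation split at a 0.5 probability threshold, together
#' with the full ROC so users can re-threshold.
#'
#' @param X,y from [build_matrix()] with `target = "outcome"`.
#' @param config list: `pipelines`, `n_iter` (default 20), `split`
#'   (training fraction, default 0.7).
#' @param seed integer seed.
#' @return object of class `classification_report`: list with `metrics`
#'   (pipeline x {auc, accuracy, sensitivity, specificity, f1}), `roc`
#'   (per-pipeline points), `selected` features, `bundles`, `split`.
#' @export
train_outcome_models <- function(X, y, config = list(), seed = 1L) {
  pipelines <- config$pipelines %||% c("rf_direct", "en_select_logistic",
                                       "rf_select_logistic")
  n_iter <- config$n_iter %||% 20L
  split <- config$split %||% 0.7
  if (length(unique(y)) < 2) {
    stop("stratification error: both outcome classes must be present",
         call. = FALSE)
  }
  idx_tr <- with_seed(child_seed(seed, 1L), {
    i1 <- which(y == 1); i0 <- which(y == 0)
    sort(c(sample(i1, round(split * length(i1))),
           sample(i0, round(split * length(i0)))))
  })
  if (length(unique(y[idx_tr])) < 2 ||
      length(unique(y[-idx_tr])) < 2) {
    stop("stratification error: a partition has a single class",
         call. = FALSE)
  }
  Xtr <- X[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
  Xva <- X[-idx_tr, , drop = FALSE]; yva <- y[-idx_tr]
  metrics <- list(); rocs <- list(); selected <- list(); bundles <- list()
  for (pipeline in pipelines) {
    param_model <- switch(pipeline, rf_direct = "logistic_rf",
                          en_select_logistic = "logistic_en",
                          rf_select_logistic = "logistic_rf")
    best <- NULL; best_auc <- -Inf
    for (i in seq_len(n_iter)) {
      params <- with_seed(child_seed(seed, 10L + i), draw_params(param_model))
      auc_i <- with_seed(child_seed(seed, 1000L + i),
                         loocv_auc(pipeline, params, Xtr, ytr))
      if (!is.na(auc_i) && auc_i > best_auc) { best_auc <- auc_i
                                               best <- params }
    }
    fit <- with_seed(child_seed(seed, 2000L),
                     suppressWarnings(
                       fit_outcome_pipeline(pipeline, best, Xtr, ytr)))
    prob <- suppressWarnings(predict_outcome_pipeline(fit, Xva))
    pred <- as.integer(prob >= 0.5)
    tp <- sum(pred == 1 & yva == 1); tn <- sum(pred == 0 & yva == 0)
    fp <- sum(pred == 1 & yva == 0); fn <- sum(pred == 0 & yva == 1)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    roc_obj <- suppressMessages(pROC::roc(yva, prob, quiet = TRUE,
                                          direction = "<"))
    metrics[[pipeline]] <- data.frame(
      pipeline = pipeline,
      auc = as.numeric(pROC::auc(roc_obj)),
      accuracy = (tp + tn) / length(yva),
      sensitivity = rec,
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
      f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
        2 * prec * rec / (prec + rec))
    rocs[[pipeline]] <- data.frame(
      fpr = 1 - roc_obj$specificities, tpr = roc_obj$sensitivities)
    selected[[pipeline]] <- if (is.list(fit$obj) &&
                                !is.null(fit$obj$feats)) fit$obj$feats else
      colnames(X)
    bundles[[pipeline]] <- c(fit, list(task = "outcome"))
    class(bundles[[pipeline]]) <- "respvar_bundle"
  }
  structure(list(metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 roc = rocs, selected = selected, bundles = bundles,
                 split = list(train = rownames(X)[idx_tr],
                              validation = rownames(X)[-idx_tr]),
                 seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("outcome classification (stratified %d/%d train/validation):\n",
              length(x$split$train), length(x$split$validation)))
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Top-k features by random-forest permutation importance
#'
#' @param model a fitted [randomForest::randomForest()] with
#'   `importance = TRUE`.
#' @param k number of features to return (default 20; capped at the
#'   number of features).
#' @return data.frame `feature`, `importance`, descending; ties broken
#'   by feature-name order.
#' @export
importance_top_k <- function(model, k = 20L) {
  imp <- randomForest::importance(model, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp))
  top <- head(ord, min(k, length(imp)))
  data.frame(feature = names(imp)[top], importance = unname(imp[top]),
             row.names = NULL)
}

#' Predict CRS-R or improvement probability for one subject
#'
#' @param bundle a deployment bundle from [train_crsr_models()] or
#'   [train_outcome_models()].
#' @param feature_values named numeric vector (or 1-row data.frame) with
#'   all features the bundle was trained on.
#' @return for CRS-R bundles a point estimate; for outcome bundles the
#'   probability of improvement in \[0, 1\].
#' @export
predict_single <- function(bundle, feature_values) {
  if (!inherits(bundle, "respvar_bundle")) {
    stop("`bundle` must be a respvar_bundle", call. = FALSE)
  }
  if (is.data.frame(feature_values)) {
    feature_values <- unlist(feature_values[1, , drop = TRUE])
  }
  missing <- setdiff(bundle$feature_names, names(feature_values))
  if (length(missing)) {
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  Xn <- matrix(feature_values[bundle$feature_names], nrow = 1,
               dimnames = list(NULL, bundle$feature_names))
  if (bundle$task == "crsr") {
    predict_crsr_model(bundle, Xn)
  } else {
    suppressWarnings(predict_outcome_pipeline(bundle, Xn))
  }
}
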