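#' Classifier families
#'
#' Four families, trained on normalized construction data over a selected
#' feature subset: support vector machines (linear, polynomial of order 3,
#' Gaussian with median-heuristic kernel scale; box constraint tuned over
#' 1..50), Gaussian naive Bayes (no tuning), ensembles (bagging via random
#' forest, and discrete AdaBoost over depth-1 stumps; 100 learners), and
#' logistic regression (plain GLM or p-value-driven stepwise selection).
#' Every model scores cases with the posterior probability of the responder
#' class; SVM margins are calibrated with a Platt-style sigmoid fitted on
#' the training decision values, keeping scores comparable across families.
#'
#' @name classification
NULL

#' Classifier specification
#'
#' @param family `"svm"`, `"naive_bayes"`, `"ensemble"` or `"logistic"`.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"`, `"gaussian"`.
#' @param cost SVM box constraint.
#' @param degree polynomial order.
#' @param aggregation ensemble aggregation: `"bagging_random_forest"` or
#'   `"adaboost"`.
#' @param n_learners ensemble size.
#' @param mode logistic mode: `"glm"` or `"stepwise"`.
#' @param p_enter,p_remove stepwise entry/removal p-value thresholds
#'   (`p_enter < p_remove`).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "naive_bayes", "ensemble",
                                       "logistic"),
                            kernel = "linear", cost = 1, degree = 3,
                            aggregation = "bagging_random_forest",
                            n_learners = 100, mode = "glm",
                            p_enter = 0.05, p_remove = 0.2) {
  family <- match.arg(family)
  kernel <- match.arg(kernel, c("linear", "polynomial", "gaussian"))
  aggregation <- match.arg(aggregation, c("bagging_random_forest", "adaboost"))
  mode <- match.arg(mode, c("glm", "stepwise"))
  if (family == "logistic" && mode == "stepwise" && p_enter >= p_remove)
    stop("stepwise logistic requires p_enter < p_remove")
  structure(list(family = family, kernel = kernel, cost = cost,
                 degree = degree, aggregation = aggregation,
                 n_learners = n_learners, mode = mode,
                 p_enter = p_enter, p_remove = p_remove),
            class = "classifier_spec")
}

.assert_no_validation <- function(table) {
  if (!is.null(table$split) && any(table$split == "validation"))
    stop("validation rows must never be seen during training")
}

# median-heuristic Gaussian kernel scale -> e1071 gamma
.median_gamma <- function(x) {
  d <- stats::dist(x)
  h <- stats::median(d[d > 0])
  if (!is.finite(h) || h == 0) h <- 1
  1 / (2 * h^2)
}

# Platt-style sigmoid calibration of decision values to P(positive)
.fit_platt <- function(f, y) {
  fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  stats::coef(fit)
}

.rpart_stump <- function(df, w) {
  rpart::rpart(y ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                              minsplit = 2, minbucket = 1,
                                              xval = 0, maxsurrogate = 0))
}

# discrete AdaBoost with depth-1 stumps, learning rate 1
.fit_adaboost <- function(x, y, n_learners) {
  df <- data.frame(x, check.names = FALSE)
  df$y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_learners)) {
    fit <- .rpart_stump(df, w * n)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    if (err == 0) {
      stumps[[t]] <- fit; alphas[t] <- 10  # capped vote for a perfect stump
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[t]] <- fit; alphas[t] <- alpha
    w <- w * exp(-alpha * ifelse(pred == y, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # no stump beat chance: majority-class model
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas,
       majority = as.integer(mean(y) >= 0.5))
}

.predict_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  F <- rep(0, nrow(df))
  for (t in seq_along(fit$stumps)) {
    st <- fit$stumps[[t]]
    if (is.null(st)) { F <- F + (2 * fit$majority - 1); next }
    pred <- as.integer(as.character(predict(st, df, type = "class")))
    F <- F + fit$alphas[t] * (2 * pred - 1)
  }
  stats::plogis(2 * F)
}

#' Train a classifier
#'
#' @param spec a [classifier_spec()].
#' @param table normalized construction-row feature table with `label`.
#' @param features feature names to train on.
#' @param normalization optional [fit_minmax()] parameters stored with the
#'   model (applied by [predict.trained_model()] when given raw tables).
#' @return object of class `trained_model`.
#' @export
train_classifier <- function(spec, table, features, normalization = NULL) {
  .assert_no_validation(table)
  x <- .feature_matrix(table, features)
  y <- .binary_labels(table$label)
  if (length(unique(y)) < 2) stop("training data holds a single class")
  fit <- platt <- NULL
  if (spec$family == "svm") {
    kern <- switch(spec$kernel, linear = "linear", polynomial = "polynomial",
                   gaussian = "radial")
    gamma <- if (spec$kernel == "gaussian") .median_gamma(x)
             else 1 / max(1, ncol(x))
    fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = kern,
                      cost = spec$cost, degree = spec$degree, gamma = gamma,
                      coef0 = if (spec$kernel == "polynomial") 1 else 0,
                      scale = FALSE)
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
    platt <- .fit_platt(dv, y)
  } else if (spec$family == "naive_bayes") {
    fit <- e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
    # floor zero variances so degenerate features cannot produce NaN scores
    for (f in names(fit$tables)) {
      tb <- fit$tables[[f]]
      if (any(tb[, 2] == 0)) {
        warning("zero-variance feature under naive Bayes: ", f,
                " (variance floored)")
        tb[tb[, 2] == 0, 2] <- 1e-6
        fit$tables[[f]] <- tb
      }
    }
  } else if (spec$family == "ensemble") {
    if (spec$aggregation == "bagging_random_forest") {
      fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                        ntree = spec$n_learners,
                                        mtry = max(1, floor(sqrt(ncol(x)))))
    } else {
      fit <- .fit_adaboost(x, y, spec$n_learners)
    }
  } else {  # logistic
    if (spec$mode == "stepwise") {
      return(stepwise_logistic(table, features, spec$p_enter, spec$p_remove,
                               normalization = normalization, spec = spec))
    }
    fit <- .fit_logistic(x, y)
  }
  structure(list(spec = spec, features = features, fit = fit, platt = platt,
                 normalization = normalization, threshold = 0.5),
            class = "trained_model")
}

# binomial GLM with ridge fallback under perfect separation
.fit_logistic <- function(x, y) {
  df <- data.frame(x, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep && ncol(x) >= 2) {
    warning("perfect separation: refitting with a ridge penalty (1e-6)")
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    cf <- as.numeric(stats::coef(rf))
    names(cf) <- rownames(stats::coef(rf))
    return(structure(list(coef = cf), class = "ridge_logistic"))
  }
  fit
}

#' Stepwise logistic regression
#'
#' Forward-backward term selection from the intercept-only model: at each
#' round the candidate whose addition gives the smallest deviance-F p-value
#' below `p_enter` is added, then any included term whose removal p-value
#' exceeds `p_remove` is dropped (largest first); rounds alternate until the
#' model is stable.
#'
#' @inheritParams train_classifier
#' @param p_enter,p_remove entry and removal thresholds, `p_enter < p_remove`.
#' @param spec optional originating [classifier_spec()].
#' @return a `trained_model` whose `features` are the retained terms (the
#'   full candidate set is kept in `candidate_features`).
#' @export
stepwise_logistic <- function(table, features, p_enter = 0.05, p_remove = 0.2,
                              normalization = NULL, spec = NULL) {
  if (p_enter >= p_remove) stop("stepwise logistic requires p_enter < p_remove")
  .assert_no_validation(table)
  x <- .feature_matrix(table, features)
  y <- .binary_labels(table$label)
  n <- length(y)
  dev_of <- function(cols) {
    if (!length(cols))
      return(stats::glm(y ~ 1, family = stats::binomial())$deviance)
    xx <- x[, cols, drop = FALSE]
    suppressWarnings(
      stats::glm(y ~ ., data = data.frame(y = y, xx, check.names = FALSE),
                 family = stats::binomial())$deviance)
  }
  f_pval <- function(dev0, dev1, p1) {
    # deviance-based F approximation for adding one term
    df2 <- max(1, n - p1 - 1)
    fstat <- max(0, dev0 - dev1) / max(dev1 / df2, 1e-12)
    stats::pf(fstat, 1, df2, lower.tail = FALSE)
  }
  included <- character(0)
  repeat {
    changed <- FALSE
    dev_cur <- dev_of(included)
    cand <- setdiff(features, included)
    if (length(cand)) {
      pv <- vapply(cand, function(f)
        f_pval(dev_cur, dev_of(c(included, f)), length(included) + 1),
        numeric(1))
      best <- cand[order(pv, cand)][1]
      if (pv[best] < p_enter) {
        included <- c(included, best); changed <- TRUE
      }
    }
    if (length(included)) {
      dev_cur <- dev_of(included)
      pv <- vapply(included, function(f)
        f_pval(dev_of(setdiff(included, f)), dev_cur, length(included)),
        numeric(1))
      worst <- included[order(-pv, included)][1]
      if (pv[worst] > p_remove) {
        included <- setdiff(included, worst); changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- if (length(included)) .fit_logistic(x[, included, drop = FALSE], y)
         else suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
  sp <- if (is.null(spec))
    classifier_spec("logistic", mode = "stepwise", p_enter = p_enter,
                    p_remove = p_remove) else spec
  structure(list(spec = sp, features = if (length(included)) included
                 else character(0),
                 candidate_features = features, fit = fit, platt = NULL,
                 normalization = normalization, threshold = 0.5),
            class = "trained_model")
}

#' Predict from a trained model
#'
#' @param object a `trained_model`.
#' @param newdata feature table or matrix holding the model's features
#'   (raw values if the model stores normalization parameters, which are
#'   then applied; already-normalized otherwise).
#' @param ... unused.
#' @return data.frame with `score` (posterior probability of responder) and
#'   `label` (1 = responder at the 0.5 threshold).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  feats <- object$features
  need <- if (length(feats)) feats else object$candidate_features
  if (length(need)) {
    missing <- setdiff(need, colnames(newdata))
    if (length(missing))
      stop("prediction input misses features: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(object$normalization)) {
    cols <- names(object$normalization$min)
    newdata <- suppressWarnings(
      apply_minmax(object$normalization, newdata,
                   feature_cols = intersect(cols, colnames(newdata))))
  }
  x <- if (length(feats)) .feature_matrix(newdata, feats)
       else matrix(0, nrow(newdata), 0)
  spec <- object$spec
  score <- if (spec$family == "svm") {
    dv <- attr(predict(object$fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    stats::plogis(object$platt[1] + object$platt[2] * dv)
  } else if (spec$family == "naive_bayes") {
    predict(object$fit, x, type = "raw")[, "1"]
  } else if (spec$family == "ensemble") {
    if (spec$aggregation == "bagging_random_forest")
      predict(object$fit, x, type = "prob")[, "1"]
    else .predict_adaboost(object$fit, x)
  } else {
    if (inherits(object$fit, "ridge_logistic")) {
      eta <- drop(cbind(1, x) %*%
                    object$fit$coef[c("(Intercept)", colnames(x))])
      stats::plogis(eta)
    } else if (!length(feats)) {
      rep(stats::plogis(stats::coef(object$fit)[1]), nrow(newdata))
    } else {
      stats::predict(object$fit,
                     newdata = data.frame(x, check.names = FALSE),
                     type = "response")
    }
  }
  score <- as.numeric(score)
  data.frame(score = score, label = as.integer(score >= object$threshold))
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$spec$family,
      if (x$spec$family == "svm") x$spec$kernel
      else if (x$spec$family == "ensemble") x$spec$aggregation
      else if (x$spec$family == "logistic") x$spec$mode else "",
      "-", length(x$features), "features\n")
  invisible(x)
}

# stratified k-fold assignment
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# mean stratified k-fold CV accuracy of a spec on a table
.cv_accuracy <- function(spec, table, features, cv_folds = 6, seed = 1L) {
  y <- .binary_labels(table$label)
  set.seed(seed)
  fold <- .stratified_folds(y, cv_folds)
  acc <- numeric(0)
  for (k in sort(unique(fold))) {
    tr <- table[fold != k, , drop = FALSE]
    te <- table[fold == k, , drop = FALSE]
    if (length(unique(.binary_labels(tr$label))) < 2) next
    mdl <- tryCatch(train_classifier(spec, tr, features),
                    error = function(e) NULL)
    if (is.null(mdl)) next
    pred <- predict(mdl, te)
    acc <- c(acc, mean(pred$label == .binary_labels(te$label)))
  }
  if (!length(acc)) return(NA_real_)
  mean(acc)
}

#' Default hyperparameter grids
#'
#' Box constraints discretized over the tuned 1..50 range; three SVM
#' kernels; both ensemble aggregations; GLM and stepwise logistic with the
#' tuned entry/removal thresholds.
#'
#' @param family classifier family.
#' @param cost_grid SVM box-constraint values.
#' @return list of [classifier_spec()] candidates, ordered simple-to-complex
#'   so that cross-validation ties resolve toward the simpler model.
#' @export
default_grid <- function(family, cost_grid = c(1, 2, 5, 8, 10, 15, 20, 30,
                                               40, 50)) {
  switch(family,
    svm = {
      out <- list()
      for (kern in c("linear", "polynomial", "gaussian"))
        for (C in cost_grid)
          out[[length(out) + 1L]] <- classifier_spec("svm", kernel = kern,
                                                     cost = C)
      out
    },
    naive_bayes = list(classifier_spec("naive_bayes")),
    ensemble = list(
      classifier_spec("ensemble", aggregation = "bagging_random_forest"),
      classifier_spec("ensemble", aggregation = "adaboost")),
    logistic = {
      out <- list(classifier_spec("logistic", mode = "glm"))
      for (pe in c(0.05, 0.1)) for (pr in c(0.2, 0.3))
        out[[length(out) + 1L]] <- classifier_spec("logistic",
                                                   mode = "stepwise",
                                                   p_enter = pe, p_remove = pr)
      out
    },
    stop("unknown family: ", family))
}

#' Grid search over a classifier family
#'
#' Picks the candidate with the highest mean stratified k-fold CV accuracy
#' on the construction rows; ties resolve toward the simpler candidate
#' (linear before polynomial before Gaussian kernels, smaller box
#' constraint, GLM before stepwise). Families whose best CV accuracy does
#' not exceed 0.5 are flagged ineligible for model selection.
#'
#' @param family classifier family.
#' @param table normalized construction rows.
#' @param features selected feature names.
#' @param cv_folds CV folds.
#' @param seed RNG seed (folds and stochastic learners).
#' @param grid optional explicit list of [classifier_spec()] candidates.
#' @return list: `model` (trained on all rows of `table`), `spec`,
#'   `cv_accuracy`, `eligible`.
#' @export
grid_search <- function(family, table, features, cv_folds = 6, seed = 1L,
                        grid = NULL) {
  if (is.null(grid)) grid <- default_grid(family)
  if (!length(grid)) stop("empty hyperparameter grid")
  accs <- vapply(grid, function(sp) {
    set.seed(seed)
    .cv_accuracy(sp, table, features, cv_folds, seed = seed)
  }, numeric(1))
  accs[is.na(accs)] <- -Inf
  best <- which.max(accs)  # first max: grids are ordered simple-to-complex
  set.seed(seed)
  model <- train_classifier(grid[[best]], table, features)
  list(model = model, spec = grid[[best]], cv_accuracy = accs[best],
       eligible = is.finite(accs[best]) && accs[best] > 0.5)
}
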