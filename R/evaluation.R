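#' Performance evaluation, model selection and comparison
#'
#' Metrics follow the clinical conventions with the responder class
#' positive: sensitivity = correctly classified responders over all
#' responders, specificity = correctly classified nonresponders over all
#' nonresponders, plus accuracy, NPV and PPV. Percentages are rounded to
#' the nearest integer, halves away from zero; 95% confidence intervals use
#' Clopper-Pearson for proportions and a stratified bootstrap for the AUC.
#'
#' @name evaluation
NULL

#' Confusion counts
#'
#' @param predictions predicted labels (1/`"responder"` positive).
#' @param labels reference labels.
#' @return list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predictions, labels) {
  p <- .binary_labels(predictions); y <- .binary_labels(labels)
  if (length(p) != length(y)) stop("prediction/label length mismatch")
  list(tp = sum(p == 1 & y == 1), fp = sum(p == 1 & y == 0),
       tn = sum(p == 0 & y == 0), fn = sum(p == 0 & y == 1))
}

# round half away from zero (10/16 -> 62.5 -> 63)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

.proportion_entry <- function(num, den) {
  if (den == 0)
    return(list(value = NA_real_, percent = NA_real_, rate = paste0(num, "/", den),
                ci = c(NA_real_, NA_real_), defined = FALSE))
  ci <- stats::binom.test(num, den)$conf.int
  list(value = num / den,
       percent = .round_half_up(100 * num / den),
       rate = paste0(num, "/", den),
       ci = as.numeric(ci), defined = TRUE)
}

#' Performance metrics from confusion counts
#'
#' @param c confusion counts from [confusion()].
#' @return object of class `performance_report`: entries `accuracy`,
#'   `sensitivity`, `specificity`, `npv`, `ppv`, each with the raw
#'   fraction, integer percent, rate string and Clopper-Pearson 95% CI;
#'   metrics with a zero denominator are reported as undefined.
#' @export
metrics <- function(c) {
  n <- c$tp + c$fp + c$tn + c$fn
  structure(list(
    accuracy = .proportion_entry(c$tp + c$tn, n),
    sensitivity = .proportion_entry(c$tp, c$tp + c$fn),
    specificity = .proportion_entry(c$tn, c$tn + c$fp),
    npv = .proportion_entry(c$tn, c$tn + c$fn),
    ppv = .proportion_entry(c$tp, c$tp + c$fp),
    counts = c), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(e, nm) {
    if (!e$defined) return(sprintf("%s undefined [%s]", nm, e$rate))
    sprintf("%s %d%% (%d-%d) [%s]", nm, e$percent,
            .round_half_up(100 * e$ci[1]), .round_half_up(100 * e$ci[2]),
            e$rate)
  }
  if (!is.null(x$auc))
    cat(sprintf("AUC %.2f (%.2f-%.2f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(fmt(x$accuracy, "ACC"), fmt(x$sensitivity, "SE"),
      fmt(x$specificity, "SP"), fmt(x$npv, "NPV"), fmt(x$ppv, "PPV"),
      sep = "  ")
  cat("\n")
  invisible(x)
}

#' ROC AUC with bootstrap confidence interval
#'
#' Unfolded Mann-Whitney AUC (responder orientation) with a stratified
#' bootstrap percentile CI.
#'
#' @param scores continuous scores, larger = more responder-like.
#' @param labels reference labels.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param ci compute the bootstrap CI.
#' @return list `auc`, `ci`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L, ci = TRUE) {
  y <- .binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  auc1 <- function(s, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    r <- rank(s)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  a <- auc1(scores, y)
  out <- list(auc = a, ci = c(NA_real_, NA_real_))
  if (ci) {
    set.seed(seed)
    i1 <- which(y == 1); i0 <- which(y == 0)
    reps <- replicate(n_boot, {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      auc1(scores[idx], y[idx])
    })
    out$ci <- as.numeric(stats::quantile(reps, c(0.025, 0.975), type = 7))
  }
  out
}

#' Full performance report including AUC
#'
#' @param scores continuous responder scores.
#' @param labels reference labels.
#' @param threshold decision threshold on the score.
#' @inheritParams roc_auc
#' @export
performance_report <- function(scores, labels, threshold = 0.5,
                               n_boot = 2000, seed = 1L) {
  rep_ <- metrics(confusion(as.integer(scores >= threshold), labels))
  a <- roc_auc(scores, labels, n_boot = n_boot, seed = seed)
  rep_$auc <- a$auc; rep_$auc_ci <- a$ci
  rep_
}

#' Best-model selection rule
#'
#' Candidates whose construction AUC is at or above the overfitting bound
#' (0.99) are excluded and logged; among the remainder the winner maximizes
#' construction accuracy, ties broken by PPV, then by fewer selected
#' features.
#'
#' @param candidates list of entries, each a list with `model` and `report`
#'   (a `performance_report` with `auc`), optionally `name`.
#' @param overfit_auc AUC at or above which a candidate is dropped.
#' @param on_all_excluded what to do when every candidate carries the
#'   overfitting flag: `"error"` (default) aborts; `"fallback"` applies the
#'   ACC/PPV rule to the full candidate list with a warning, for cohorts
#'   whose class signal is strong enough that near-perfect construction
#'   discrimination is genuine rather than overfitting.
#' @return list `chosen` (the winning entry), `excluded` (names + reasons).
#' @export
select_best <- function(candidates, overfit_auc = 0.99,
                        on_all_excluded = c("error", "fallback")) {
  on_all_excluded <- match.arg(on_all_excluded)
  if (!length(candidates)) stop("no candidate models")
  nm <- vapply(seq_along(candidates), function(i) {
    if (!is.null(candidates[[i]]$name)) candidates[[i]]$name
    else paste0("candidate_", i)
  }, character(1))
  aucs <- vapply(candidates, function(cd) cd$report$auc, numeric(1))
  excluded <- data.frame(name = nm[aucs >= overfit_auc],
                         reason = sprintf("overfitting (AUC %.2f >= %.2f)",
                                          aucs[aucs >= overfit_auc],
                                          overfit_auc))
  keep <- which(aucs < overfit_auc)
  if (!length(keep)) {
    if (on_all_excluded == "error")
      stop("every candidate was excluded as overfitting")
    warning("every candidate reached the overfitting bound (AUC >= ",
            overfit_auc, "); falling back to the accuracy/PPV rule over ",
            "all candidates")
    keep <- seq_along(candidates)
    excluded <- excluded[0, , drop = FALSE]
  }
  acc <- vapply(candidates, function(cd) cd$report$accuracy$value, numeric(1))
  ppv <- vapply(candidates, function(cd) {
    v <- cd$report$ppv$value; if (is.na(v)) -1 else v
  }, numeric(1))
  nfeat <- vapply(candidates, function(cd)
    length(cd$model$features), numeric(1))
  ord <- keep[order(-acc[keep], -ppv[keep], nfeat[keep])]
  list(chosen = candidates[[ord[1]]], chosen_name = nm[ord[1]],
       excluded = excluded)
}

#' Validate a model on a held-out split
#'
#' Applies the frozen model (with its stored normalization) to the rows of
#' the requested split under the requested mask provenance. Hybrid
#' validation is the same call with the other provenance's feature rows.
#' Overlap between validation ids and the model's training ids is a hard
#' error (leakage guard).
#'
#' @param model a `trained_model`; if it carries `training_ids`, these are
#'   checked against the validation rows.
#' @param table full feature table.
#' @param split split to validate on (default `"validation"`).
#' @param provenance mask provenance of the feature rows.
#' @param seed bootstrap seed for the AUC CI.
#' @return list `report` (`performance_report`), `predictions` (per-case).
#' @export
validate_model <- function(model, table, split = "validation",
                           provenance = "manual", seed = 1L) {
  rows <- table[table$split == split & table$provenance == provenance, ,
                drop = FALSE]
  if (!nrow(rows)) stop("no rows for split ", split, " / ", provenance)
  if (!is.null(model$training_ids) &&
      length(intersect(rows$id, model$training_ids)))
    stop("leakage: validation rows overlap the model's training cases")
  pred <- predict(model, rows)
  rep_ <- performance_report(pred$score, rows$label, seed = seed)
  list(report = rep_,
       predictions = data.frame(id = rows$id, label = .binary_labels(rows$label),
                                score = pred$score, predicted = pred$label))
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration when both groups have at most 8 observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @return list `statistic` (U of the first sample), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "not applicable (empty group)"))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = as.numeric(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Error analysis between the manual and automatic pipelines
#'
#' Identifies per-case correctness for each provenance track and their
#' intersection, then runs Mann-Whitney contrasts: ROI volume of correct
#' versus misclassified cases per pipeline, DSC of correct versus
#' misclassified cases (automatic pipeline), and volume of manually- versus
#' automatically-misclassified cases.
#'
#' @param preds_manual,preds_auto predicted labels per case, aligned.
#' @param labels reference labels, aligned.
#' @param dsc_by_case per-case manual-vs-automatic DSC.
#' @param volume_by_case per-case ROI volume (mm^3).
#' @param ids optional case identifiers.
#' @return list of correctness sets and test results.
#' @export
error_analysis <- function(preds_manual, preds_auto, labels, dsc_by_case,
                           volume_by_case, ids = seq_along(labels)) {
  y <- .binary_labels(labels)
  ok_man <- .binary_labels(preds_manual) == y
  ok_auto <- .binary_labels(preds_auto) == y
  mis_both <- !ok_man & !ok_auto
  list(
    misclassified_manual = ids[!ok_man],
    misclassified_automatic = ids[!ok_auto],
    misclassified_both = ids[mis_both],
    volume_manual = mann_whitney(volume_by_case[ok_man],
                                 volume_by_case[!ok_man]),
    volume_automatic = mann_whitney(volume_by_case[ok_auto],
                                    volume_by_case[!ok_auto]),
    dsc_automatic = mann_whitney(dsc_by_case[ok_auto], dsc_by_case[!ok_auto]),
    volume_mis_manual_vs_auto = mann_whitney(volume_by_case[!ok_man],
                                             volume_by_case[!ok_auto]))
}

#' Compare two models on the same cases
#'
#' Reports (a) the unpaired two-proportion z-test per metric, mirroring the
#' common reporting style, and (b) McNemar's exact test on the paired
#' disagreements, the statistically appropriate paired comparison, as the
#' primary result.
#'
#' @param preds_a,preds_b predicted labels per case, aligned.
#' @param labels reference labels.
#' @return list `mcnemar` (exact, primary) and `two_proportion` (accuracy).
#' @export
compare_models <- function(preds_a, preds_b, labels) {
  y <- .binary_labels(labels)
  pa <- .binary_labels(preds_a); pb <- .binary_labels(preds_b)
  ok_a <- pa == y; ok_b <- pb == y
  b <- sum(ok_a & !ok_b); c <- sum(!ok_a & ok_b)
  mc_p <- if (b + c == 0) 1
          else stats::binom.test(b, b + c, 0.5)$p.value
  n <- length(y)
  two_prop <- two_proportion_test(sum(ok_a), n, sum(ok_b), n)
  list(mcnemar = list(discordant = c(b = b, c = c), p_value = mc_p,
                      method = "exact McNemar (primary paired test)"),
       two_proportion = two_prop)
}

#' Unpaired two-proportion z-test
#'
#' @param x1,n1 successes and size of the first arm.
#' @param x2,n2 successes and size of the second arm.
#' @return list `p_value`, `z`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z)
}
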