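test_that("confusion counts follow the responder-positive convention", {
  expect_equal(confusion(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               list(tp = 2, fp = 0, tn = 2, fn = 0))
  expect_equal(confusion(c(0, 1), c(1, 0)),
               list(tp = 0, fp = 1, tn = 0, fn = 1))
  # 15 responders with 9 predicted responder; 13 nonresponders with 10
  # predicted nonresponder
  preds <- c(rep(1, 9), rep(0, 6), rep(0, 10), rep(1, 3))
  labs <- c(rep(1, 15), rep(0, 13))
  expect_equal(confusion(preds, labs), list(tp = 9, fp = 3, tn = 10, fn = 6))
  expect_error(confusion(1, c(1, 0)), "mismatch")
})

test_that("metrics reproduce the external-validation worked examples", {
  # manual model, validation: 19/28, 9/15, 10/13, 10/16, 9/12
  m <- metrics(list(tp = 9, fn = 6, tn = 10, fp = 3))
  expect_equal(m$accuracy$percent, 68)
  expect_equal(m$sensitivity$percent, 60)
  expect_equal(m$specificity$percent, 77)
  expect_equal(m$npv$percent, 63)      # 10/16 = 62.5, half away from zero
  expect_equal(m$ppv$percent, 75)
  expect_equal(m$accuracy$rate, "19/28")
  # automatic model, validation: 21/28, 12/15, 9/13, 9/12, 12/16
  a <- metrics(list(tp = 12, fn = 3, tn = 9, fp = 4))
  expect_equal(a$accuracy$percent, 75)
  expect_equal(a$sensitivity$percent, 80)
  expect_equal(a$specificity$percent, 69)
  expect_equal(a$npv$percent, 75)
  expect_equal(a$ppv$percent, 75)
  # perfect classification
  p <- metrics(list(tp = 50, fn = 0, tn = 50, fp = 0))
  for (e in p[c("accuracy", "sensitivity", "specificity", "npv", "ppv")])
    expect_equal(e$percent, 100)
})

test_that("every printed construction/validation/hybrid rate is reproduced", {
  # (tp, fn, tn, fp) |-> ACC, SE, SP, NPV, PPV percentages; reproduces each
  # reported model row whose printed percentages are arithmetically
  # consistent with its printed [x/y] rates under half-away-from-zero
  # rounding (a handful of construction rows are internally inconsistent in
  # the source report, e.g. the same 54/67 printed as both 80% and 81%)
  rows <- list(
    list(c(25, 2, 29, 11), c(81, 93, 73, 94, 69)),  # construction, manual
    list(c(22, 5, 27, 9), c(78, 81, 75, 84, 71)),   # construction, automatic
    list(c(26, 1, 17, 19), c(68, 96, 47, 94, 58)),  # construction, bagging
    list(c(9, 6, 10, 3), c(68, 60, 77, 63, 75)),    # validation, manual
    list(c(12, 3, 9, 4), c(75, 80, 69, 75, 75)),    # validation, automatic
    list(c(7, 8, 11, 2), c(64, 47, 85, 58, 78)))    # hybrid, reversed
  for (r in rows) {
    cc <- list(tp = r[[1]][1], fn = r[[1]][2], tn = r[[1]][3],
               fp = r[[1]][4])
    m <- metrics(cc)
    got <- c(m$accuracy$percent, m$sensitivity$percent,
             m$specificity$percent, m$npv$percent, m$ppv$percent)
    expect_equal(got, r[[2]])
  }
})

test_that("zero denominators report undefined metrics, not zero", {
  m <- metrics(list(tp = 0, fn = 0, tn = 5, fp = 2))
  expect_false(m$sensitivity$defined)
  expect_true(is.na(m$sensitivity$percent))
  expect_true(m$specificity$defined)
})

test_that("Clopper-Pearson intervals contain the point estimate", {
  m <- metrics(list(tp = 9, fn = 6, tn = 10, fp = 3))
  for (e in m[c("accuracy", "sensitivity", "specificity", "npv", "ppv")]) {
    expect_lte(e$ci[1], e$value)
    expect_gte(e$ci[2], e$value)
  }
})

test_that("ROC AUC is the unfolded pair-counting statistic", {
  expect_equal(roc_auc(1:10, rep(c(0, 1), each = 5), ci = FALSE)$auc, 1.0)
  expect_equal(roc_auc(10:1, rep(c(0, 1), each = 5), ci = FALSE)$auc, 0.0)
  expect_equal(roc_auc(c(.1, .4, .35, .8), c(0, 0, 1, 1), ci = FALSE)$auc,
               0.75)
  a <- roc_auc(c(.1, .4, .35, .8, .2, .9), c(0, 0, 1, 1, 0, 1), seed = 2)
  expect_lte(a$ci[1], a$auc); expect_gte(a$ci[2], a$auc)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60) + 0.8 * y
  ours <- roc_auc(s, y, ci = FALSE)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

fake_candidate <- function(name, acc_counts, auc, ppv_counts = NULL,
                           n_features = 5) {
  rep_ <- metrics(acc_counts)
  rep_$auc <- auc; rep_$auc_ci <- c(auc - 0.05, auc + 0.05)
  list(model = list(features = seq_len(n_features)), report = rep_,
       name = name)
}

test_that("model selection excludes overfit candidates then maximizes ACC/PPV", {
  overfit <- fake_candidate("mrmr+ensemble",
                            list(tp = 39, fn = 0, tn = 27, fp = 1), 1.00)
  honest <- fake_candidate("ranking+svm",
                           list(tp = 23, fn = 4, tn = 32, fp = 8), 0.90)
  out <- select_best(list(overfit, honest))
  expect_equal(out$chosen_name, "ranking+svm")
  expect_equal(out$excluded$name, "mrmr+ensemble")
  # equal accuracy, tie to higher PPV
  a <- fake_candidate("A", list(tp = 23, fn = 4, tn = 32, fp = 8), 0.90)
  b <- fake_candidate("B", list(tp = 20, fn = 7, tn = 35, fp = 5), 0.88)
  expect_equal(select_best(list(a, b))$chosen_name, "B")  # same ACC, PPV 80>74
  expect_equal(metrics(list(tp = 20, fn = 7, tn = 35, fp = 5))$accuracy$rate,
               "55/67")
  # single honest candidate returns itself; all-overfit errors
  expect_equal(select_best(list(honest))$chosen_name, "ranking+svm")
  expect_error(select_best(list(overfit)), "excluded")
  borderline <- fake_candidate("edge", list(tp = 30, fn = 3, tn = 30,
                                            fp = 4), 0.99)
  expect_error(select_best(list(borderline)), "excluded")  # 0.99 is excluded
})

test_that("validation refuses rows that overlap the training cases", {
  tab <- blob_tab(40, d = 3, seed = 6)
  mdl <- suppressWarnings(
    train_classifier(classifier_spec("logistic"), tab, c("f1", "f2")))
  mdl$training_ids <- tab$id
  tab$split <- "validation"
  expect_error(validate_model(mdl, tab, "validation", "manual"), "leakage")
  # disjoint validation rows pass and identical provenances agree (hybrid
  # with identical features is a no-op)
  val <- blob_tab(20, d = 3, seed = 7, split = "validation")
  val$id <- val$id + 1000
  v1 <- validate_model(mdl, val, "validation", "manual", seed = 1)
  val2 <- val; val2$provenance <- "automatic"
  v2 <- validate_model(mdl, rbind(val, val2), "validation", "automatic",
                       seed = 1)
  expect_equal(v1$report$accuracy$value, v2$report$accuracy$value)
})

test_that("Mann-Whitney matches exact enumeration for small groups", {
  # {1,2,3} vs {4,5,6}: most extreme of choose(6,3)=20 orderings -> p = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  # full agreement with enumeration over all label assignments, n=4+4
  set.seed(10)
  a <- rnorm(4); b <- rnorm(4) + 1
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(a, b)
  pool <- c(a, b)
  combos <- combn(8, 4)
  us <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  exact_p <- mean(abs(us - 8) >= abs(obs - 8) - 1e-12)
  expect_equal(mann_whitney(a, b)$p_value, exact_p, tolerance = 1e-12)
  expect_equal(mann_whitney(numeric(0), 1:3)$p_value, NA_real_)
})

test_that("Mann-Whitney null p-values are uniform", {
  set.seed(123)
  ps <- replicate(1000, mann_whitney(rnorm(12), rnorm(15))$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("error analysis partitions misclassifications and runs contrasts", {
  labels <- c(1, 1, 1, 0, 0, 0, 1, 0)
  pm <- c(1, 0, 1, 0, 1, 0, 1, 0)   # wrong on 2, 5
  pa <- c(1, 0, 1, 0, 0, 1, 1, 0)   # wrong on 2, 6
  set.seed(4)
  vols <- rexp(8) * 1000; dscs <- runif(8, 0.5, 0.95)
  ea <- error_analysis(pm, pa, labels, dscs, vols, ids = letters[1:8])
  expect_equal(ea$misclassified_manual, c("b", "e"))
  expect_equal(ea$misclassified_automatic, c("b", "f"))
  expect_equal(ea$misclassified_both, "b")
  expect_true(ea$volume_manual$p_value > 0 && ea$volume_manual$p_value <= 1)
  # identical prediction vectors make "both" equal each set
  ea2 <- error_analysis(pm, pm, labels, dscs, vols)
  expect_equal(ea2$misclassified_both, ea2$misclassified_manual)
})

test_that("model comparison reports exact McNemar and the proportion test", {
  labels <- rep(c(1, 0), 10)
  cmp <- compare_models(labels, labels, labels)
  expect_equal(cmp$mcnemar$p_value, 1)
  # A correct everywhere, B wrong everywhere: p = 2 * 2^-20 * C(20,0)... the
  # exact binomial two-sided tail with b=20, c=0
  pa <- labels; pb <- 1 - labels
  cmp2 <- compare_models(pa, pb, labels)
  expect_equal(cmp2$mcnemar$discordant, c(b = 20, c = 0))
  expect_equal(cmp2$mcnemar$p_value, 2 * 2^-20 * 1, tolerance = 1e-12)
  # directional consistency of the two-proportion test
  gaps <- c(2, 5, 8)
  ps <- sapply(gaps, function(g)
    two_proportion_test(12, 15, 12 - g, 15)$p_value)
  expect_true(all(diff(ps) < 0))
})
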