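#' Feature selection
#'
#' Three strategies over the normalized construction-set feature table:
#' stability-resampled AUC ranking with Pearson correlation pruning,
#' affinity-propagation exemplar selection, and minimum-redundancy
#' maximum-relevance (mutual-information quotient). Subset sizes are chosen
#' at the overfitting point of cross-validated accuracy curves.
#'
#' @name feature-selection
NULL

.positive_class <- "responder"

#' Ranking-method configuration
#'
#' @param correlation_threshold Pearson correlation at or above which the
#'   lower-AUC member of a feature pair is discarded.
#' @param resamples number of random re-compositions of the training set.
#' @param resample_fraction fraction of construction patients per resample.
#' @param min_selections minimum survival count for a feature to be kept.
#' @param auc_threshold relevance filter: features whose folded AUC on the
#'   resample falls below this are treated as non-discriminative and do not
#'   survive that resample. 0.5 disables the filter (folded AUCs never fall
#'   below it).
#' @param cv_folds folds for the cross-validated accuracy curves.
#' @export
ranking_config <- function(correlation_threshold = 0.85, resamples = 100,
                           resample_fraction = 0.70, min_selections = 70,
                           auc_threshold = 0.6, cv_folds = 6) {
  stopifnot(correlation_threshold > 0, correlation_threshold <= 1,
            min_selections <= resamples, cv_folds >= 2,
            auc_threshold >= 0.5, auc_threshold < 1,
            resample_fraction > 0, resample_fraction <= 1)
  list(correlation_threshold = correlation_threshold, resamples = resamples,
       resample_fraction = resample_fraction,
       min_selections = min_selections, auc_threshold = auc_threshold,
       cv_folds = cv_folds)
}

#' Min-max normalization anchored on the construction set
#'
#' `fit_minmax` learns per-feature minima and maxima from construction rows
#' only; `apply_minmax` maps x to (x - min) / (max - min). A constant
#' feature maps to 0 everywhere. Validation rows transformed with
#' construction parameters may leave `[0, 1]`; they are not clipped, and a
#' warning reports how many values fell outside.
#'
#' @param table feature table (construction rows) or matrix of features.
#' @param feature_cols feature column names; defaults to all non-metadata
#'   columns.
#' @return `fit_minmax`: list with `min`, `max` per feature.
#' @export
fit_minmax <- function(table, feature_cols = NULL) {
  x <- .feature_matrix(table, feature_cols)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname fit_minmax
#' @param params output of `fit_minmax`.
#' @export
apply_minmax <- function(params, table, feature_cols = NULL) {
  x <- .feature_matrix(table, feature_cols)
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min[colnames(x)])
  out <- sweep(out, 2, ifelse(rng[colnames(x)] > 0, rng[colnames(x)], 1), "/")
  out[, rng[colnames(x)] == 0] <- 0
  n_out <- sum(out < 0 | out > 1)
  if (n_out > 0)
    warning(n_out, " normalized value(s) outside [0, 1] ",
            "(rows beyond the construction range)")
  if (is.data.frame(table)) {
    table[, colnames(x)] <- out
    table
  } else out
}

.feature_matrix <- function(table, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- setdiff(colnames(table), feature_table_meta_cols())
  as.matrix(table[, feature_cols, drop = FALSE])
}

.binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == .positive_class)
  else as.integer(labels)
}

#' Direction-folded Mann-Whitney AUC of a single feature
#'
#' Tie-corrected rank AUC, folded to `max(a, 1 - a)` so that a feature
#' discriminates regardless of direction.
#'
#' @param values numeric feature values.
#' @param labels binary labels (1/`"responder"` positive).
#' @return AUC in `[0.5, 1]`.
#' @export
feature_auc <- function(values, labels) {
  y <- .binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# vectorized folded AUC over the columns of a feature matrix
.feature_aucs <- function(x, y) {
  apply(x, 2, feature_auc, labels = y)
}

#' Correlation pruning
#'
#' Of every feature pair with `|Pearson r|` at or above the threshold, the
#' member with the lower AUC is discarded. Implemented as a greedy sweep in
#' descending AUC order (ties broken by name): a feature is retained only
#' if it is not correlated at or above the threshold with any
#' already-retained (higher-AUC) feature. The sweep is deterministic and
#' resolves correlation chains by discrimination: in a chain A-B-C where
#' only the consecutive pairs are tight and A has the best AUC, B is
#' dropped and A and C are both retained.
#'
#' @param x feature matrix (rows = cases).
#' @param aucs named per-feature AUCs.
#' @param threshold correlation threshold.
#' @return character vector of retained feature names (original column
#'   order).
#' @export
correlation_prune <- function(x, aucs, threshold = 0.85) {
  feats <- colnames(x)
  if (length(feats) < 2) return(feats)
  cm <- abs(suppressWarnings(stats::cor(x)))
  cm[is.na(cm)] <- 0
  ord <- feats[order(-aucs[feats], feats)]
  kept <- character(0)
  for (f in ord) {
    if (!length(kept) || all(cm[f, kept] < threshold))
      kept <- c(kept, f)
  }
  feats[feats %in% kept]
}

#' Stability-resampled AUC ranking
#'
#' Repeats relevance scoring plus correlation pruning on randomly
#' re-composed training subsets (stratified by label to guarantee both
#' classes): within each resample, features whose folded AUC on the
#' resample falls below `auc_threshold` are dropped as non-discriminative,
#' and correlated survivors are pruned with [correlation_prune()].
#' Pruning decisions use the AUCs computed once on the full construction
#' set, so the lower-discrimination member of a tightly correlated pair
#' loses consistently rather than by resampling noise. Survival counts are
#' accumulated; features surviving at least `min_selections` times are
#' kept, ordered by their full-construction-set AUC, descending.
#'
#' @param table construction-row feature table (normalized).
#' @param cfg a [ranking_config()].
#' @param feature_cols feature columns; default all non-metadata.
#' @return a `selection_result` list: `method`, `ordered_features`,
#'   `feature_auc`, `selection_counts`, `config`.
#' @export
stability_ranking <- function(table, cfg = ranking_config(),
                              feature_cols = NULL) {
  x <- .feature_matrix(table, feature_cols)
  y <- .binary_labels(table$label)
  counts <- setNames(numeric(ncol(x)), colnames(x))
  full_auc <- .feature_aucs(x, y)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  for (b in seq_len(cfg$resamples)) {
    take <- c(sample(idx1, max(1, round(cfg$resample_fraction * length(idx1)))),
              sample(idx0, max(1, round(cfg$resample_fraction * length(idx0)))))
    xb <- x[take, , drop = FALSE]; yb <- y[take]
    aucs_b <- .feature_aucs(xb, yb)
    cand <- names(aucs_b)[aucs_b >= cfg$auc_threshold]
    if (!length(cand)) next
    kept <- correlation_prune(xb[, cand, drop = FALSE], full_auc[cand],
                              cfg$correlation_threshold)
    counts[kept] <- counts[kept] + 1
  }
  survivors <- names(counts)[counts >= cfg$min_selections]
  if (!length(survivors))
    stop("no feature was selected at least ", cfg$min_selections,
         " times; consider relaxing min_selections")
  ord <- survivors[order(-full_auc[survivors], survivors)]
  structure(list(method = "ranking", ordered_features = ord,
                 feature_auc = full_auc[ord], selection_counts = counts,
                 config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$method, "): ", length(x$ordered_features),
      " features", if (!is.null(x$chosen_size))
        paste0(", chosen size ", x$chosen_size), "\n", sep = "")
  invisible(x)
}

#' Overfitting-point subset sizing
#'
#' For each k, trains the given classifier on the top-k features and records
#' the mean k-fold cross-validated training accuracy on the
#' construction-train rows and the accuracy on the held-out
#' construction-test rows. The chosen size is the largest k whose test
#' accuracy is non-decreasing up to k while the first subsequent size shows
#' training accuracy still non-decreasing and test accuracy strictly
#' decreasing; if the pattern never occurs, the smallest k maximizing test
#' accuracy.
#'
#' @param ordered ordered candidate feature names.
#' @param spec a [classifier_spec()] used for the accuracy curves.
#' @param train_table,test_table normalized construction-train and
#'   construction-test rows.
#' @param cv_folds folds for the training-accuracy curve.
#' @param max_size cap on the number of sizes examined.
#' @param seed RNG seed for fold assignment.
#' @return list `chosen_size`, `train_accuracy`, `test_accuracy`.
#' @export
overfitting_point <- function(ordered, spec, train_table, test_table,
                              cv_folds = 6, max_size = length(ordered),
                              seed = 1L) {
  ks <- seq_len(min(length(ordered), max_size))
  tr_acc <- te_acc <- numeric(length(ks))
  y_test <- .binary_labels(test_table$label)
  for (k in ks) {
    feats <- ordered[1:k]
    tr_acc[k] <- .cv_accuracy(spec, train_table, feats, cv_folds, seed = seed)
    mdl <- train_classifier(spec, train_table, feats)
    pred <- predict(mdl, test_table)
    te_acc[k] <- mean(pred$label == y_test)
  }
  chosen <- NA_integer_
  for (k in rev(ks[-length(ks)])) {
    if (all(diff(te_acc[1:k]) >= 0) &&
        tr_acc[k + 1] >= tr_acc[k] && te_acc[k + 1] < te_acc[k]) {
      chosen <- k; break
    }
  }
  if (is.na(chosen)) chosen <- which.max(te_acc)  # ties: smallest k
  list(chosen_size = chosen, train_accuracy = tr_acc, test_accuracy = te_acc)
}

#' Affinity-propagation exemplar selection
#'
#' Clusters features by responsibility/availability message passing over a
#' similarity matrix (negative squared Euclidean distance between
#' standardized feature columns) and returns the exemplars as the selected
#' subset. The number of clusters is not set a priori; the shared preference
#' is the median off-diagonal similarity.
#'
#' @param table feature table (normalized construction rows).
#' @param feature_cols feature columns.
#' @param damping message damping factor in (0.5, 1).
#' @param max_iter maximum message-passing iterations.
#' @param convergence_iter iterations of a stable exemplar set required.
#' @param preference similarity preference; default median off-diagonal.
#' @return a `selection_result` (`ordered_features` = exemplars ordered by
#'   folded AUC when labels are available, else by name).
#' @export
affinity_propagation_select <- function(table, feature_cols = NULL,
                                        damping = 0.7, max_iter = 500,
                                        convergence_iter = 30,
                                        preference = NULL) {
  x <- .feature_matrix(table, feature_cols)
  if (ncol(x) < 2) stop("need at least two features")
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  p <- ncol(xs)
  # similarity: negative squared Euclidean distance between feature columns
  s <- -as.matrix(stats::dist(t(xs)))^2
  if (is.null(preference)) preference <- stats::median(s[row(s) != col(s)])
  # lift the preference infinitesimally above any exactly-tied similarity so
  # that points at the median similarity prefer self-exemplification
  diag(s) <- preference + abs(preference) * 1e-6
  # tiny deterministic jitter removes degenerate symmetry ties
  s <- s + s * 1e-12 * matrix(seq_len(p * p) %% 7, p, p)
  R <- A <- matrix(0, p, p)
  stable <- 0L; last <- integer(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    AS <- A + s
    mx1 <- apply(AS, 1, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(1:p, w1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rnew <- s - mx1
    Rnew[cbind(1:p, w1)] <- s[cbind(1:p, w1)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, p, p, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (length(ex) && identical(ex, last)) stable <- stable + 1L
    else { stable <- 0L; last <- ex }
    if (stable >= convergence_iter) { converged <- TRUE; break }
  }
  if (!length(last)) last <- which.max(diag(A + R))
  if (!converged)
    warning("affinity propagation did not converge; ",
            "returning the last stable exemplar set")
  exemplars <- colnames(x)[last]
  ord <- if (!is.null(table$label)) {
    aucs <- .feature_aucs(x[, exemplars, drop = FALSE],
                          .binary_labels(table$label))
    exemplars[order(-aucs, exemplars)]
  } else sort(exemplars)
  structure(list(method = "affinity_propagation", ordered_features = ord,
                 config = list(damping = damping, preference = preference),
                 converged = converged),
            class = "selection_result")
}

# plug-in mutual information between two discrete vectors, in bits
.mi_discrete <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  idx <- tab > 0
  sum(tab[idx] * log2(tab[idx] / outer(pa, pb)[idx]))
}

# equal-frequency binning into n_bins levels
.ef_bin <- function(v, n_bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  if (length(br) < 2) return(rep(1L, length(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Minimum-redundancy maximum-relevance ranking (MIQ)
#'
#' Greedy mutual-information-quotient ranking: the first pick maximizes
#' relevance I(f; y); each subsequent pick maximizes
#' I(f; y) / mean I(f; s) over the already selected s. Mutual information is
#' a plug-in estimate after equal-frequency binning of each feature.
#'
#' @param table feature table with `label`.
#' @param feature_cols feature columns.
#' @param n_bins equal-frequency bins for the MI estimate.
#' @return a `selection_result` with the full ordering and per-feature
#'   relevance.
#' @export
mrmr_rank <- function(table, feature_cols = NULL, n_bins = 4) {
  x <- .feature_matrix(table, feature_cols)
  y <- .binary_labels(table$label)
  if (length(unique(y)) < 2) stop("both classes must be present")
  binned <- apply(x, 2, .ef_bin, n_bins = n_bins)
  rel <- apply(binned, 2, .mi_discrete, b = y)
  feats <- colnames(x)
  sel <- character(0)
  remaining <- feats
  scores <- numeric(0)
  first <- remaining[order(-rel[remaining], remaining)][1]
  sel <- first; remaining <- setdiff(remaining, first)
  scores[first] <- rel[first]
  mi_cache <- matrix(NA_real_, length(feats), length(feats),
                     dimnames = list(feats, feats))
  while (length(remaining)) {
    sc <- vapply(remaining, function(f) {
      red <- vapply(sel, function(s2) {
        if (is.na(mi_cache[f, s2])) {
          v <- .mi_discrete(binned[, f], binned[, s2])
          mi_cache[f, s2] <<- mi_cache[s2, f] <<- v
        }
        mi_cache[f, s2]
      }, numeric(1))
      rel[f] / max(mean(red), 1e-12)
    }, numeric(1))
    best <- remaining[order(-sc, remaining)][1]
    scores[best] <- sc[best]
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
  }
  structure(list(method = "mrmr", ordered_features = sel,
                 relevance = rel[sel], scores = scores,
                 config = list(n_bins = n_bins)),
            class = "selection_result")
}
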