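#' Pipeline orchestration
#'
#' [run_pipeline()] drives the full analysis from a single configuration:
#' cohort simulation or ingestion, feature extraction for both mask
#' provenances, the construction-set exclusion of automatic masks with
#' DSC < 0.20, per-track feature selection and classifier optimisation,
#' best-model selection, external and hybrid validation, error analysis and
#' model comparison. Every artefact is stamped with the configuration hash
#' and seed; re-running an unchanged configuration reproduces all numbers.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param seed global RNG seed.
#' @param output_dir run directory (created); `NULL` for in-memory only.
#' @param simulate arguments for [cohort_spec()] (ignored when `input_csv`
#'   is given).
#' @param input_csv clinical table of an on-disk cohort.
#' @param preprocessing arguments for [preprocessing_config()].
#' @param selection list: `methods` (subset of `ranking`,
#'   `affinity_propagation`, `mrmr`), `ranking` ([ranking_config()] args),
#'   `max_size` cap for subset sizing, `sizing_family` classifier family
#'   used for the overfitting-point curves.
#' @param classification list: `families`, `cost_grid`, `cv_folds`.
#' @param evaluation list: `overfit_auc`, `n_boot`, `dsc_exclusion`.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, output_dir = NULL,
                            simulate = list(), input_csv = NULL,
                            preprocessing = list(),
                            selection = list(),
                            classification = list(),
                            evaluation = list()) {
  sel <- utils::modifyList(list(methods = "ranking", ranking = list(),
                                max_size = 15L, sizing_family = "svm"),
                           selection)
  cls <- utils::modifyList(list(families = c("svm", "naive_bayes",
                                             "ensemble", "logistic"),
                                cost_grid = c(1, 2, 5, 8, 10, 15, 20, 30,
                                              40, 50),
                                cv_folds = 6L), classification)
  ev <- utils::modifyList(list(overfit_auc = 0.99, n_boot = 500L,
                               dsc_exclusion = 0.20), evaluation)
  list(seed = as.integer(seed), output_dir = output_dir,
       simulate = simulate, input_csv = input_csv,
       preprocessing = preprocessing, selection = sel,
       classification = cls, evaluation = ev)
}

.log_lines <- function(state, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste0(...))
  state$log <- c(state$log, line)
  if (isTRUE(state$verbose)) message(line)
  state
}

# pooled stratified-CV construction report: every construction row is
# scored by a model that did not train on it, and the pooled scores feed
# one report (confusion rates out of the full construction size)
.pooled_cv_report <- function(spec, tab_n, feats, cv_folds, seed, n_boot) {
  y <- .binary_labels(tab_n$label)
  set.seed(seed)
  fold <- .stratified_folds(y, cv_folds)
  scores <- rep(NA_real_, length(y))
  for (k in sort(unique(fold))) {
    tr <- tab_n[fold != k, , drop = FALSE]
    if (length(unique(.binary_labels(tr$label))) < 2) next
    mdl_k <- tryCatch(suppressWarnings(train_classifier(spec, tr, feats)),
                      error = function(e) NULL)
    if (is.null(mdl_k)) next
    scores[fold == k] <- predict(mdl_k, tab_n[fold == k, , drop = FALSE])$score
  }
  ok <- !is.na(scores)
  performance_report(scores[ok], tab_n$label[ok], n_boot = n_boot,
                     seed = seed)
}

# per-track candidate construction: FS -> sizing -> per-family grid search
.track_candidates <- function(tab_con, cfg, track, state) {
  pcfg <- do.call(preprocessing_config, cfg$preprocessing)
  rk_cfg <- do.call(ranking_config, cfg$selection$ranking)
  norm <- fit_minmax(tab_con)
  tab_n <- suppressWarnings(apply_minmax(norm, tab_con))
  train_rows <- tab_n[tab_n$split == "construction-train", , drop = FALSE]
  test_rows <- tab_n[tab_n$split == "construction-test", , drop = FALSE]
  sizing_spec <- classifier_spec(cfg$selection$sizing_family)
  selections <- list(); candidates <- list()
  for (method in cfg$selection$methods) {
    set.seed(cfg$seed + 101L)
    sel <- switch(method,
      ranking = stability_ranking(tab_n, rk_cfg),
      affinity_propagation = affinity_propagation_select(tab_n),
      mrmr = mrmr_rank(tab_n),
      stop("unknown selection method: ", method))
    op <- overfitting_point(sel$ordered_features, sizing_spec, train_rows,
                            test_rows, cv_folds = rk_cfg$cv_folds,
                            max_size = cfg$selection$max_size,
                            seed = cfg$seed + 202L)
    sel$chosen_size <- op$chosen_size
    sel$cv_curves <- op[c("train_accuracy", "test_accuracy")]
    selections[[method]] <- sel
    feats <- sel$ordered_features[seq_len(op$chosen_size)]
    state <- .log_lines(state, "select",
                         track, "/", method, ": ",
                         length(sel$ordered_features), " candidates, size ",
                         op$chosen_size)
    for (family in cfg$classification$families) {
      gs <- grid_search(family, tab_n, feats,
                        cv_folds = cfg$classification$cv_folds,
                        seed = cfg$seed + 303L,
                        grid = if (family == "svm")
                          default_grid("svm", cfg$classification$cost_grid)
                        else default_grid(family))
      if (!gs$eligible) {
        state <- .log_lines(state, "train", track, "/", method, "+", family,
                             ": ineligible (CV accuracy ",
                             sprintf("%.2f", gs$cv_accuracy), " <= 0.5)")
        next
      }
      mdl <- gs$model
      mdl$normalization <- norm
      mdl$training_ids <- unique(tab_con$id)
      # construction performance: pooled cross-validated predictions over
      # all construction rows (rates out of the full construction size)
      rep_ <- .pooled_cv_report(gs$spec, tab_n, feats,
                                cv_folds = cfg$classification$cv_folds,
                                seed = cfg$seed + 404L,
                                n_boot = cfg$evaluation$n_boot)
      candidates[[paste(method, family, sep = "+")]] <-
        list(model = mdl, report = rep_,
             name = paste(method, family, sep = "+"),
             cv_accuracy = gs$cv_accuracy)
    }
  }
  list(selections = selections, candidates = candidates, norm = norm,
       state = state)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param cases optional pre-built list of `study_case` objects (overrides
#'   the simulate/input sections).
#' @param verbose print stage log lines.
#' @return list with feature tables, selection results, candidates, chosen
#'   models, validation / hybrid / comparison reports, error analysis and
#'   the stage log.
#' @export
run_pipeline <- function(config = pipeline_config(), cases = NULL,
                         verbose = FALSE) {
  state <- list(log = character(0), verbose = verbose)
  cfg <- config
  pcfg <- do.call(preprocessing_config, cfg$preprocessing)

  if (is.null(cases)) {
    if (!is.null(cfg$input_csv)) {
      cases <- read_cohort(cfg$input_csv)
      state <- .log_lines(state, "ingest", length(cases), " cases from ",
                          cfg$input_csv)
    } else {
      spec <- do.call(cohort_spec, utils::modifyList(cfg$simulate,
                                                     list(seed = cfg$seed)))
      cases <- generate_cohort(spec)
      state <- .log_lines(state, "simulate", length(cases),
                          " synthetic cases (seed ", cfg$seed, ")")
    }
  }

  # case-level geometry: manual-vs-automatic DSC and manual ROI volume
  info <- do.call(rbind, lapply(cases, function(cs) {
    dsc <- if (!is.null(cs$masks$automatic))
      dice(cs$masks$manual, cs$masks$automatic,
           cfg$evaluation$dsc_exclusion)$value else NA_real_
    data.frame(id = cs$id, centre = cs$centre, split = cs$split,
               label = cs$label, dsc = dsc,
               volume_mm3 = roi_volume_mm3(cs$masks$manual))
  }))

  tracks <- intersect(c("manual", "automatic"),
                      unique(unlist(lapply(cases, function(cs)
                        names(cs$masks)))))
  table_all <- extract_feature_table(cases, provenances = tracks, cfg = pcfg)
  state <- .log_lines(state, "extract", nrow(table_all), " feature rows (",
                      paste(tracks, collapse = ", "), ")")

  results <- list(config = cfg, cases_info = info,
                  feature_table = table_all, tracks = list())
  has_validation <- any(table_all$split == "validation")

  for (track in tracks) {
    tab <- table_all[table_all$provenance == track, , drop = FALSE]
    tab_con <- tab[tab$split != "validation", , drop = FALSE]
    if (track == "automatic") {
      # tumours the automatic segmentation failed to find leave construction
      bad <- info$id[!is.na(info$dsc) &
                       info$dsc < cfg$evaluation$dsc_exclusion &
                       info$split != "validation"]
      if (length(bad)) {
        tab_con <- tab_con[!(tab_con$id %in% bad), , drop = FALSE]
        state <- .log_lines(state, "exclude", length(bad),
                            " construction case(s) with DSC < ",
                            cfg$evaluation$dsc_exclusion, ": ",
                            paste(bad, collapse = ", "))
      }
    }
    tc <- .track_candidates(tab_con, cfg, track, state)
    state <- tc$state
    if (!length(tc$candidates))
      stop("no eligible candidate model for the ", track, " track")
    all_excluded_fallback <- FALSE
    best <- withCallingHandlers(
      select_best(tc$candidates, cfg$evaluation$overfit_auc,
                  on_all_excluded = "fallback"),
      warning = function(w) {
        all_excluded_fallback <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (all_excluded_fallback)
      state <- .log_lines(state, "select_best", track,
                          ": every candidate at the overfitting bound; ",
                          "accuracy/PPV rule applied to all candidates")
    state <- .log_lines(state, "select_best", track, ": ", best$chosen_name,
                        if (nrow(best$excluded))
                          paste0(" (excluded: ",
                                 paste(best$excluded$name, collapse = ", "),
                                 ")") else "")
    results$tracks[[track]] <- list(selections = tc$selections,
                                    candidates = lapply(tc$candidates,
                                      function(cd) cd[c("name", "report",
                                                        "cv_accuracy")]),
                                    best_name = best$chosen_name,
                                    excluded = best$excluded,
                                    best = best$chosen)
  }

  if (has_validation) {
    for (track in tracks) {
      mdl <- results$tracks[[track]]$best$model
      val <- validate_model(mdl, table_all, "validation", track,
                            seed = cfg$seed + 505L)
      results$tracks[[track]]$validation <- val
      state <- .log_lines(state, "validate", track, ": accuracy ",
                          val$report$accuracy$percent, "%")
      other <- setdiff(tracks, track)
      if (length(other) == 1) {
        hyb <- validate_model(mdl, table_all, "validation", other,
                              seed = cfg$seed + 606L)
        results$tracks[[track]]$hybrid <- hyb
        state <- .log_lines(state, "hybrid", "train ", track, " + validate ",
                            other, ": accuracy ",
                            hyb$report$accuracy$percent, "%")
      }
    }
    if (length(tracks) == 2) {
      vm <- results$tracks$manual$validation$predictions
      va <- results$tracks$automatic$validation$predictions
      vi <- info[match(vm$id, info$id), ]
      results$error_analysis <- error_analysis(
        vm$predicted, va$predicted[match(vm$id, va$id)], vm$label,
        vi$dsc, vi$volume_mm3, ids = vm$id)
      results$comparison <- compare_models(
        vm$predicted, va$predicted[match(vm$id, va$id)], vm$label)
      state <- .log_lines(state, "error_analysis",
                          length(results$error_analysis$misclassified_manual),
                          " manual / ",
                          length(results$error_analysis$misclassified_automatic),
                          " automatic / ",
                          length(results$error_analysis$misclassified_both),
                          " shared misclassifications")
    }
  } else {
    state <- .log_lines(state, "validate",
                        "no validation split: validation, hybrid and error ",
                        "analysis skipped; construction-only report emitted")
  }

  results$log <- state$log
  if (!is.null(cfg$output_dir)) .write_run_dir(results, cfg)
  results
}

# serialize the run artefacts as plain-text files
.write_run_dir <- function(results, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = cfg$seed,
                config_hash = .config_hash(cfg),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  utils::write.csv(results$feature_table,
                   file.path(cfg$output_dir, "feature_table.csv"),
                   row.names = FALSE)
  utils::write.csv(results$cases_info,
                   file.path(cfg$output_dir, "cases_info.csv"),
                   row.names = FALSE)
  summarize_report <- function(r) list(
    auc = r$auc, auc_ci = r$auc_ci,
    accuracy = r$accuracy[c("percent", "rate", "ci")],
    sensitivity = r$sensitivity[c("percent", "rate", "ci")],
    specificity = r$specificity[c("percent", "rate", "ci")],
    npv = r$npv[c("percent", "rate", "ci")],
    ppv = r$ppv[c("percent", "rate", "ci")])
  out <- list(stamp = stamp, tracks = lapply(results$tracks, function(tr) {
    list(best = tr$best_name,
         excluded = tr$excluded,
         candidates = lapply(tr$candidates, function(cd)
           list(name = cd$name, cv_accuracy = cd$cv_accuracy,
                construction = summarize_report(cd$report))),
         selections = lapply(tr$selections, function(sl)
           list(method = sl$method, ordered = sl$ordered_features,
                chosen_size = sl$chosen_size)),
         validation = if (!is.null(tr$validation))
           summarize_report(tr$validation$report),
         hybrid = if (!is.null(tr$hybrid))
           summarize_report(tr$hybrid$report))
  }))
  if (!is.null(results$error_analysis))
    out$error_analysis <- results$error_analysis
  if (!is.null(results$comparison)) out$comparison <- results$comparison
  jsonlite::write_json(out, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  writeLines(results$log, file.path(cfg$output_dir, "log.txt"))
  invisible(NULL)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "output_dir")],
                        auto_unbox = TRUE, force = TRUE)
  # small rolling hash; provenance stamp, not cryptographic
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%010d", h)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] sections.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
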