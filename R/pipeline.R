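# End-to-end study replica: simulate -> extract -> select -> train ->
# evaluate -> report, with a run manifest for reproducibility.

#' Pipeline run configuration
#'
#' @param n_normal,n_metastatic Cohort class counts (defaults 196/194,
#'   which the 80/20 stratified split partitions into 157/155 training
#'   and 39/39 test nodes).
#' @param seed Master seed; all stage seeds derive from it.
#' @param train_fraction Training fraction (default 0.8).
#' @param n_folds CV folds (default 10).
#' @param kernel SVM kernel (default `"radial"`).
#' @param n_levels Quantization levels (default 8).
#' @param write_images Write per-case NIfTI files during simulate.
#' @param out_dir Output directory for artifacts (NULL = no files).
#' @return A `run_config` object.
#' @export
run_config <- function(n_normal = 196, n_metastatic = 194, seed = 1,
                       train_fraction = 0.8, n_folds = 10,
                       kernel = "radial", n_levels = 8,
                       write_images = FALSE, out_dir = NULL) {
  structure(list(n_normal = n_normal, n_metastatic = n_metastatic,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 n_folds = n_folds, kernel = kernel, n_levels = n_levels,
                 write_images = write_images, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

stage_seeds <- function(config) {
  s <- derive_seeds(config$seed, 5)
  list(cohort = s[1], split = s[2], lasso = s[3], demographic = s[4],
       svm = s[5])
}

#' Run the full study replica
#'
#' Simulates a cohort, extracts the 146-feature panel, splits 80/20
#' stratified, selects radiomic features by LASSO and demographic
#' features by exhaustive search, trains the radiomic and demographic
#' SVMs, applies the clinical 10 mm rule, and evaluates all three
#' models on both cohorts with DeLong comparisons. If `out_dir` is set,
#' writes the feature table, the LASSO path, the three serialized
#' models, a per-model/per-cohort metric report (CSV + JSON), ROC points and a
#' run manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `features`, `split`, `lasso`,
#'   `demographic_selection`, `models`, `report`, `comparisons`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  if (config$n_normal + config$n_metastatic == 0)
    stop("validation error: empty cohort configured")
  seeds <- stage_seeds(config)

  cohort <- generate_cohort(cohort_config(config$n_normal,
                                          config$n_metastatic,
                                          seed = seeds$cohort))
  features <- extract_features(cohort, n_levels = config$n_levels)
  demo <- cohort_table(cohort)

  split <- stratified_split(features$label, config$train_fraction,
                            seed = seeds$split)
  feat_cols <- feature_registry()$name
  x_train <- features[split$train, feat_cols]
  y_train <- features$label[split$train]

  lasso <- lasso_cv_select(x_train, y_train, n_folds = config$n_folds,
                           seed = seeds$lasso)
  radiomic_feats <- lasso$selected_features
  if (length(radiomic_feats) == 0) {
    # degenerate null path: fall back to the strongest single feature
    cors <- abs(vapply(x_train, function(v)
      suppressWarnings(stats::cor(v, y_train)), numeric(1)))
    radiomic_feats <- names(sort(cors, decreasing = TRUE))[1]
  }

  demo_candidates <- demo[, c("age", "gender", "histological_grade",
                              "tumor_location", "short_axis", "long_axis")]
  demo_enc <- encode_demographics(demo_candidates)
  demo_sel <- exhaustive_search_select(demo_candidates[split$train, ],
                                       y_train,
                                       n_folds = config$n_folds,
                                       seed = seeds$demographic)
  demo_cols <- unlist(demo_enc$columns[demo_sel$selected])

  radiomic_svm <- train_svm(x_train[, radiomic_feats, drop = FALSE],
                            y_train, kernel = config$kernel,
                            n_folds = config$n_folds, seed = seeds$svm)
  demographic_svm <- train_svm(
    demo_enc$matrix[split$train, demo_cols, drop = FALSE], y_train,
    kernel = config$kernel, n_folds = config$n_folds, seed = seeds$svm)
  clinical <- clinical_model()

  models <- list(clinical = clinical, demographic = demographic_svm,
                 radiomic = radiomic_svm)

  eval_one <- function(model, idx, tag) {
    newdata <- if (model$kind == "clinical_threshold") {
      demo[idx, , drop = FALSE]
    } else if (all(model$feature_names %in% colnames(demo_enc$matrix))) {
      as.data.frame(demo_enc$matrix[idx, , drop = FALSE])
    } else {
      features[idx, , drop = FALSE]
    }
    pr <- predict(model, newdata)
    ev <- evaluate_predictions(pr$score, pr$class, features$label[idx],
                               cohort = tag)
    c(list(scores = pr$score), ev)
  }
  idx_sets <- list(training = split$train, test = split$test)
  evals <- lapply(names(models), function(mn) {
    lapply(names(idx_sets), function(cn)
      eval_one(models[[mn]], idx_sets[[cn]], cn))
  })
  names(evals) <- names(models)
  for (mn in names(evals)) names(evals[[mn]]) <- names(idx_sets)

  report <- do.call(rbind, lapply(names(evals), function(mn) {
    do.call(rbind, lapply(names(evals[[mn]]), function(cn) {
      e <- evals[[mn]][[cn]]
      data.frame(model = mn, cohort = cn,
                 accuracy = e$metrics["accuracy"],
                 sensitivity = e$metrics["sensitivity"],
                 specificity = e$metrics["specificity"],
                 auc = e$auc$auc,
                 auc_ci_low = e$auc$ci95[1],
                 auc_ci_high = e$auc$ci95[2],
                 row.names = NULL)
    }))
  }))

  cmp_pairs <- list(c("radiomic", "clinical"),
                    c("radiomic", "demographic"),
                    c("demographic", "clinical"))
  comparisons <- lapply(names(idx_sets), function(cn) {
    lab <- features$label[idx_sets[[cn]]]
    out <- lapply(cmp_pairs, function(pr2) {
      ct <- delong_paired_test(evals[[pr2[1]]][[cn]]$scores,
                               evals[[pr2[2]]][[cn]]$scores, lab)
      list(model_a = pr2[1], model_b = pr2[2],
           delta_auc = ct$delta_auc, z = ct$z, p = ct$p)
    })
    names(out) <- vapply(cmp_pairs, paste, character(1), collapse = "_vs_")
    out
  })
  names(comparisons) <- names(idx_sets)

  manifest <- list(package_version =
                     as.character(utils::packageVersion("lnradiomics")),
                   config = unclass(config)[setdiff(names(config),
                                                    "out_dir")],
                   stage_seeds = seeds,
                   radiomic_features = radiomic_feats,
                   demographic_features = demo_sel$selected)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$write_images)
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
    else write.csv(demo, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
    write_feature_table(features,
                        file.path(config$out_dir, "features.csv"))
    jsonlite::write_json(
      list(lambda = lasso$lambda, cv_mse = lasso$cv_mse,
           cv_se = lasso$cv_se, df = as.numeric(lasso$df),
           selected_lambda = lasso$selected_lambda,
           selected_features = lasso$selected_features),
      file.path(config$out_dir, "lasso_path.json"),
      auto_unbox = TRUE, digits = NA)
    write_model_json(clinical,
                     file.path(config$out_dir, "model_clinical.json"))
    write_model_json(demographic_svm,
                     file.path(config$out_dir, "model_demographic.json"))
    write_model_json(radiomic_svm,
                     file.path(config$out_dir, "model_radiomic.json"))
    write.csv(report, file.path(config$out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(comparisons,
                         file.path(config$out_dir, "delong.json"),
                         auto_unbox = TRUE, digits = NA)
    roc_points <- do.call(rbind, lapply(names(evals), function(mn) {
      e <- evals[[mn]][["test"]]
      lab <- features$label[split$test]
      ord <- order(e$scores, decreasing = TRUE)
      data.frame(model = mn,
                 fpr = cumsum(lab[ord] == 0) / sum(lab == 0),
                 tpr = cumsum(lab[ord] == 1) / sum(lab == 1))
    }))
    write.csv(roc_points, file.path(config$out_dir, "roc_test.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(features = features, split = split, lasso = lasso,
                 demographic_selection = demo_sel, models = models,
                 evals = evals, report = report,
                 comparisons = comparisons, manifest = manifest))
}

#' Published reference performance values
#'
#' The printed performance table of the source study: per model and
#' cohort, the reported accuracy, sensitivity, specificity (%) and AUC,
#' plus the class sizes. Bundled so the count/rate arithmetic can be
#' recomputed without external input.
#'
#' @return Data frame with one row per model x cohort.
#' @export
reference_performance <- function() {
  data.frame(
    model = rep(c("clinical", "demographic", "radiomic"), each = 2),
    cohort = rep(c("training", "test"), 3),
    n_pos = rep(c(155, 39), 3),
    n_neg = rep(c(157, 39), 3),
    accuracy = c(65.38, 62.82, 67.31, 73.08, 81.09, 79.49),
    sensitivity = c(83.87, 84.62, 62.58, 69.23, 83.87, 74.36),
    specificity = c(47.13, 41.03, 71.97, 76.92, 78.34, 84.62),
    auc = c(0.703, 0.772, 0.706, 0.773, 0.882, 0.825),
    stringsAsFactors = FALSE)
}
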