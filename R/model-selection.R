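# The three classifiers and their selection protocols: clinical 10 mm
# threshold, demographic SVM chosen by exhaustive subset search, and the
# radiomic SVM on LASSO-selected features; plus the stratified 80/20
# split and 10-fold cross-validation machinery.

#' Stratified train/test split
#'
#' Samples each class without replacement so that class proportions are
#' preserved to within one case; reproducible under `seed`.
#'
#' @param labels 0/1 vector (or a cohort data frame with a `label`
#'   column).
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train`, `test` (integer indices),
#'   `counts`, `seed`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  if (n == 0) stop("empty cohort")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  classes <- sort(unique(labels))
  if (any(table(labels) == 0)) stop("a class has no members")
  train <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sort(sample(idx, n_tr)))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  structure(list(train = train, test = test,
                 counts = list(train = table(labels[train]),
                               test = table(labels[test])),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Clinical size-threshold rule
#'
#' Classifies a node as metastatic iff its long-axis diameter strictly
#' exceeds 10 mm.
#'
#' @param long_axis Long-axis diameter(s) in mm (> 0).
#' @param threshold_mm Decision threshold (default 10).
#' @return Integer vector of 0/1 predictions.
#' @export
clinical_classify <- function(long_axis, threshold_mm = 10) {
  if (any(!is.finite(long_axis)) || any(long_axis <= 0))
    stop("long_axis must be positive and finite")
  as.integer(long_axis > threshold_mm)
}

# Stratified fold assignment (1..n_folds) reproducible under seed.
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  folds
}

#' LASSO feature selection with cross-validation
#'
#' Linear LASSO regression of the 0/1 label on standardized features
#' (squared-error loss); lambda is chosen at the minimum of the 10-fold
#' cross-validation MSE and the selected features are those with nonzero
#' coefficients there. Constant feature columns are dropped with a
#' warning.
#'
#' @param features Numeric matrix or data frame of predictors (cases x
#'   features, named columns).
#' @param labels 0/1 response.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param loss `"mse"` (linear, default) or `"logistic"`.
#' @return A `lasso_path`: list with `lambda`, `cv_mse`, `cv_se`, `df`,
#'   `selected_lambda`, `selected_features`, `coefficients`.
#' @export
lasso_cv_select <- function(features, labels, n_folds = 10, seed = 1,
                            loss = c("mse", "logistic")) {
  loss <- match.arg(loss)
  x <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels are constant: nothing to select")
  if (min(table(y)) < n_folds)
    stop("need at least n_folds cases per class")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  foldid <- stratified_folds(y, n_folds, seed)
  fam <- if (loss == "mse") "gaussian" else "binomial"
  cvfit <- glmnet::cv.glmnet(x, y, family = fam, foldid = foldid,
                             standardize = TRUE)
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))
  nz <- rownames(cf)[cf[, 1] != 0]
  nz <- setdiff(nz, "(Intercept)")
  structure(list(lambda = cvfit$lambda,
                 cv_mse = cvfit$cvm,
                 cv_se = cvfit$cvsd,
                 df = cvfit$nzero,
                 selected_lambda = cvfit$lambda.min,
                 selected_features = nz,
                 coefficients = cf[, 1],
                 seed = seed),
            class = "lasso_path")
}

#' One-hot encode a demographic table
#'
#' Numeric variables pass through; categoricals become 0/1 indicator
#' columns (first level dropped). The variable-to-columns map is kept so
#' subset search can operate on whole variables.
#'
#' @param df Data frame of demographic variables.
#' @return List with `matrix` (encoded) and `columns` (name map).
#' @export
encode_demographics <- function(df) {
  cols <- list()
  mat <- NULL
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      block <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      lev <- sort(unique(as.character(v)))
      block <- vapply(lev[-1], function(l) as.numeric(v == l),
                      numeric(length(v)))
      block <- matrix(block, ncol = length(lev) - 1,
                      dimnames = list(NULL, paste0(nm, "_", lev[-1])))
    }
    cols[[nm]] <- colnames(block)
    mat <- if (is.null(mat)) block else cbind(mat, block)
  }
  list(matrix = mat, columns = cols)
}

# Per-fold misclassification rates of an RBF SVM on a fixed feature
# matrix, with shared folds.
svm_cv_fold_errors <- function(x, y, folds, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  yf <- factor(y)
  ks <- sort(unique(folds))
  vapply(ks, function(k) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = apply(
                        x[tr, , drop = FALSE], 2, sd) > 0)
    mean(predict(fit, x[!tr, , drop = FALSE]) != yf[!tr])
  }, numeric(1))
}

#' Exhaustive demographic subset search
#'
#' Enumerates every non-empty subset of the candidate variables and
#' scores each with the 10-fold cross-validation error of an RBF SVM
#' (shared folds). The winner is chosen by the one-standard-error
#' parsimony rule: among all subsets whose CV error is within one
#' standard error of the minimum, the smallest wins, with remaining
#' ties broken by lexicographic name order. This keeps fold noise from
#' dragging uninformative variables into the model.
#'
#' @param candidates Data frame of candidate variables (numeric or
#'   categorical; categoricals are one-hot encoded).
#' @param labels 0/1 response.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return List with `selected` (variable names), `cv_error` (of the
#'   winner) and `table` (all subsets with their errors).
#' @export
exhaustive_search_select <- function(candidates, labels, n_folds = 10,
                                     seed = 1) {
  if (!is.data.frame(candidates) || ncol(candidates) == 0)
    stop("candidates must be a non-empty data frame")
  if (ncol(candidates) > 8)
    stop("exhaustive search limited to 8 candidate variables")
  enc <- encode_demographics(candidates)
  vars <- names(candidates)
  folds <- stratified_folds(labels, n_folds, seed)
  subsets <- unlist(lapply(seq_along(vars), function(k)
    combn(vars, k, simplify = FALSE)), recursive = FALSE)
  fold_errs <- lapply(subsets, function(ss) {
    cols <- unlist(enc$columns[ss])
    svm_cv_fold_errors(enc$matrix[, cols, drop = FALSE], labels, folds)
  })
  errs <- vapply(fold_errs, mean, numeric(1))
  ses <- vapply(fold_errs, function(e) sd(e) / sqrt(length(e)), numeric(1))
  i_min <- which.min(errs)
  within <- errs <= errs[i_min] + ses[i_min]
  key <- order(!within,
               vapply(subsets, length, integer(1)),
               errs,
               vapply(subsets, function(s) paste(sort(s), collapse = "|"),
                      character(1)))
  best <- key[1]
  list(selected = sort(subsets[[best]]),
       cv_error = errs[best],
       table = data.frame(
         subset = vapply(subsets, function(s) paste(s, collapse = "+"),
                         character(1)),
         size = vapply(subsets, length, integer(1)),
         cv_error = errs,
         cv_se = ses))
}

#' Train a kernel SVM with cross-validated hyperparameters
#'
#' Standardizes features by the training-set mean/SD, selects (cost,
#' gamma) on a grid by 10-fold CV misclassification error (ties resolved
#' toward the smallest cost, then smallest gamma), and refits on the full
#' training set. Decision scores are oriented so that larger values favor
#' class 1.
#'
#' @param features Numeric matrix/data frame (cases x features).
#' @param labels 0/1 response.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost_grid,gamma_grid Hyperparameter grids; `gamma_grid` is
#'   relative to 1/n_features and ignored for the linear kernel.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return A `trained_model` of kind `"svm"`.
#' @export
train_svm <- function(features, labels, kernel = c("radial", "linear"),
                      cost_grid = 2^seq(-3, 5, by = 2),
                      gamma_grid = 2^seq(-2, 2, by = 2),
                      n_folds = 10, seed = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("single-class training data")
  if (min(table(y)) < n_folds)
    stop("need at least n_folds cases per class")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  folds <- stratified_folds(y, n_folds, seed)
  gam_base <- 1 / ncol(xs)
  grid <- if (kernel == "radial")
    expand.grid(cost = cost_grid, gamma = gamma_grid * gam_base)
  else expand.grid(cost = cost_grid, gamma = gam_base)
  grid_err <- vapply(seq_len(nrow(grid)), function(i) {
    err <- 0
    yf <- factor(y)
    for (k in sort(unique(folds))) {
      tr <- folds != k
      fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = kernel,
                        cost = grid$cost[i], gamma = grid$gamma[i],
                        scale = FALSE)
      err <- err + sum(predict(fit, xs[!tr, , drop = FALSE]) != yf[!tr])
    }
    err / length(y)
  }, numeric(1))
  best <- order(grid_err, grid$cost, grid$gamma)[1]
  fit <- e1071::svm(xs, factor(y), kernel = kernel,
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
  # orient decision scores so larger = class 1
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
  structure(list(kind = "svm",
                 feature_names = colnames(x),
                 kernel = kernel,
                 cost = grid$cost[best],
                 gamma = grid$gamma[best],
                 cv_error = grid_err[best],
                 center = mu, scale = sdev,
                 flip = flip,
                 fit = fit,
                 seed = seed),
            class = "trained_model")
}

#' The clinical threshold rule as a model object
#'
#' @param threshold_mm Decision threshold in mm (default 10).
#' @return A `trained_model` of kind `"clinical_threshold"` whose score
#'   is the long-axis diameter itself.
#' @export
clinical_model <- function(threshold_mm = 10) {
  structure(list(kind = "clinical_threshold",
                 feature_names = "long_axis",
                 threshold_mm = threshold_mm),
            class = "trained_model")
}

#' Predict from a trained model
#'
#' @param object A `trained_model`.
#' @param newdata Data frame/matrix providing the model's named inputs.
#' @param ... Unused.
#' @return List with `score` (continuous, larger favors metastatic) and
#'   `class` (0/1).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (object$kind == "clinical_threshold") {
    la <- if (is.data.frame(newdata)) newdata$long_axis else newdata
    list(score = as.numeric(la),
         class = clinical_classify(la, object$threshold_mm))
  } else {
    x <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                          drop = FALSE])
    xs <- scale(x, center = object$center, scale = object$scale)
    pr <- predict(object$fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1] * object$flip
    list(score = as.numeric(dv), class = as.integer(dv > 0))
  }
}

#' Serialize a trained model to JSON
#'
#' Captures kind, features, standardization, hyperparameters and (for
#' SVMs) the support vectors, dual coefficients and offset, so the
#' decision function can be reconstructed without the fitted object.
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(version = as.character(utils::packageVersion("lnradiomics")),
              kind = model$kind,
              feature_names = model$feature_names)
  if (model$kind == "clinical_threshold") {
    doc$threshold_mm <- model$threshold_mm
  } else {
    doc$kernel <- model$kernel
    doc$cost <- model$cost
    doc$gamma <- model$gamma
    doc$center <- as.list(model$center)
    doc$scale <- as.list(model$scale)
    doc$flip <- model$flip
    doc$rho <- model$fit$rho
    doc$dual_coefs <- as.numeric(model$fit$coefs)
    doc$support_vectors <- unname(apply(model$fit$SV, 1, as.numeric,
                                        simplify = FALSE))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized by [write_model_json()]
#'
#' @param path JSON path.
#' @return A `trained_model` (SVMs are reconstructed from the stored
#'   support data; prediction uses the explicit kernel expansion).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (doc$kind == "clinical_threshold")
    return(clinical_model(doc$threshold_mm))
  sv <- if (is.matrix(doc$support_vectors)) doc$support_vectors
        else do.call(rbind, lapply(doc$support_vectors, as.numeric))
  sv <- matrix(as.numeric(sv), nrow = nrow(sv))
  structure(list(kind = "svm_restored",
                 feature_names = doc$feature_names,
                 kernel = doc$kernel,
                 cost = doc$cost, gamma = doc$gamma,
                 center = unlist(doc$center), scale = unlist(doc$scale),
                 flip = doc$flip, rho = doc$rho,
                 dual_coefs = doc$dual_coefs, SV = sv),
            class = c("restored_model", "trained_model"))
}

#' @rdname read_model_json
#' @param object A restored model.
#' @param newdata New cases.
#' @param ... Unused.
#' @export
predict.restored_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                        drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  k <- if (object$kernel == "radial") {
    d2 <- outer(rowSums(xs^2), rowSums(object$SV^2), "+") -
      2 * xs %*% t(object$SV)
    exp(-object$gamma * pmax(d2, 0))
  } else {
    xs %*% t(object$SV)
  }
  dv <- (as.numeric(k %*% object$dual_coefs) - object$rho) * object$flip
  list(score = dv, class = as.integer(dv > 0))
}
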