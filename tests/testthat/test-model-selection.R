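# Split protocol, clinical rule, LASSO and exhaustive selection, SVM.

test_that("the stratified split reproduces the 312/78 partition", {
  labels <- c(rep(0, 196), rep(1, 194))
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_length(sp$train, 312)
  expect_length(sp$test, 78)
  expect_equal(as.vector(sp$counts$train), c(157, 155))
  expect_equal(as.vector(sp$counts$test), c(39, 39))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))

  sp2 <- stratified_split(labels, 0.8, seed = 1)
  expect_identical(sp, sp2)

  small <- stratified_split(c(0, 0, 1, 1), 0.5, seed = 3)
  expect_length(small$train, 2)
  expect_equal(as.vector(small$counts$train), c(1, 1))

  expect_error(stratified_split(integer(0)), "empty")
})

test_that("the clinical rule is strict at 10 mm", {
  expect_equal(clinical_classify(10.0), 0L)
  expect_equal(clinical_classify(10.1), 1L)
  expect_equal(clinical_classify(17.37), 1L)
  expect_equal(clinical_classify(c(5, 12)), c(0L, 1L))
  expect_error(clinical_classify(0), "positive")
})

test_that("lasso recovers a planted informative feature", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(n, 1, plogis(3 * x[, "f1"]))
    if (min(table(y)) < 10) next
    fit <- lasso_cv_select(x, y, n_folds = 10, seed = s)
    if ("f1" %in% fit$selected_features) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("lasso stays near-empty under null labels", {
  sizes <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(100 * 20), 100,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- rep(c(0, 1), each = 50)
    length(lasso_cv_select(x, y, n_folds = 10,
                           seed = s)$selected_features)
  }, numeric(1))
  expect_lte(median(sizes), 2)
})

test_that("lasso validates inputs and drops constant columns", {
  x <- matrix(rnorm(100 * 3), 100,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_error(lasso_cv_select(x, rep(1, 100)), "constant")
  x2 <- cbind(x, flat = 1)
  y <- rep(c(0, 1), each = 50)
  expect_warning(fit <- lasso_cv_select(x2, y, seed = 2), "constant")
  expect_false("flat" %in% fit$selected_features)
  # degrees of freedom come with the path, one per lambda
  expect_length(fit$df, length(fit$lambda))
  expect_length(fit$cv_mse, length(fit$lambda))
})

test_that("lasso shrinks the synthetic panel far below 146", {
  co <- generate_cohort(cohort_config(60, 60, seed = 21))
  ft <- extract_features(co)
  fit <- suppressWarnings(lasso_cv_select(ft[, feature_registry()$name], ft$label,
                         n_folds = 10, seed = 4))
  expect_gt(length(fit$selected_features), 0)
  expect_lt(length(fit$selected_features), 146 / 2)
  expect_true(all(fit$selected_features %in% feature_registry()$name))
})

test_that("exhaustive search enumerates subsets and honors signal", {
  set.seed(31)
  n <- 120
  demo <- data.frame(
    age = rnorm(n, 62, 12),
    gender = sample(c("M", "F"), n, TRUE),
    histological_grade = sample(c("well", "poor"), n, TRUE),
    tumor_location = sample(c("left", "right"), n, TRUE),
    short_axis = rnorm(n, 8, 2),
    long_axis = rnorm(n, 12, 3))
  y <- rep(c(0, 1), each = n / 2)
  demo$short_axis <- demo$short_axis + 4 * y  # only size carries signal
  res <- exhaustive_search_select(demo, y, n_folds = 10, seed = 5)
  expect_equal(nrow(res$table), 63)
  expect_equal(res$selected, "short_axis")

  single <- exhaustive_search_select(demo["age"], y, seed = 5)
  expect_equal(single$selected, "age")
  expect_error(exhaustive_search_select(demo[0], y), "non-empty")
})

test_that("svm training separates separable data and is deterministic", {
  set.seed(41)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = 50)
  m <- train_svm(x, y, n_folds = 10, seed = 6)
  pr <- predict(m, as.data.frame(x))
  expect_equal(mean(pr$class == y), 1)
  expect_gt(mean(pr$score[y == 1]), mean(pr$score[y == 0]))

  m2 <- train_svm(x, y, n_folds = 10, seed = 6)
  expect_equal(m$cost, m2$cost)
  expect_equal(m$gamma, m2$gamma)
  expect_identical(predict(m2, as.data.frame(x))$score, pr$score)
})

test_that("svm cross-validation is at chance under permuted labels", {
  set.seed(51)
  x <- matrix(rnorm(200 * 4), 200, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(rep(c(0, 1), each = 100))
  m <- train_svm(x, y, cost_grid = 1, gamma_grid = 1,
                 n_folds = 10, seed = 7)
  cv_acc <- 1 - m$cv_error
  expect_gte(cv_acc, 0.40)
  expect_lte(cv_acc, 0.60)
})

test_that("the trained model never sees the test partition", {
  set.seed(61)
  x <- rbind(matrix(rnorm(160, 0), 80, 2), matrix(rnorm(160, 2), 80, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = 80)
  sp <- stratified_split(y, 0.8, seed = 8)
  m <- train_svm(x[sp$train, ], y[sp$train], n_folds = 10, seed = 9)
  scores1 <- predict(m, as.data.frame(x[sp$test, ]))$score
  # shuffling the held-out labels cannot change anything the model does
  y_shuffled <- y
  y_shuffled[sp$test] <- sample(y[sp$test])
  m2 <- train_svm(x[sp$train, ], y_shuffled[sp$train],
                  n_folds = 10, seed = 9)
  scores2 <- predict(m2, as.data.frame(x[sp$test, ]))$score
  expect_identical(scores1, scores2)
})

test_that("svm models survive JSON serialization", {
  set.seed(71)
  x <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 3), 60, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = 60)
  m <- train_svm(x, y, n_folds = 10, seed = 10)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  p1 <- predict(m, as.data.frame(x))
  p2 <- predict(m2, as.data.frame(x))
  expect_equal(p1$score, p2$score, tolerance = 1e-8)
  expect_equal(p1$class, p2$class)

  cl <- clinical_model()
  write_model_json(cl, path)
  cl2 <- read_model_json(path)
  expect_equal(predict(cl2, data.frame(long_axis = c(8, 14)))$class,
               c(0L, 1L))
  unlink(path)
})
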