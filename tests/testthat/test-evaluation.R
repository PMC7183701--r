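# Metrics arithmetic, AUC/DeLong machinery, cohort statistics, overlap.

test_that("confusion metrics reproduce printed training/test rows", {
  m <- confusion_metrics(confusion_counts(tp = 130, fp = 83, tn = 74,
                                          fn = 25))
  expect_equal(unname(m), c(65.38, 83.87, 47.13))

  perfect <- confusion_metrics(confusion_counts(tp = 39, fp = 0, tn = 39,
                                                fn = 0))
  expect_equal(unname(perfect), c(100, 100, 100))

  m2 <- confusion_metrics(confusion_counts(tp = 29, fp = 6, tn = 33,
                                           fn = 10))
  expect_equal(unname(m2["accuracy"]), 79.49)
})

test_that("counts are recovered from printed rates", {
  ct <- counts_from_rates(155, 83.87, 157, 47.13)
  expect_equal(ct$tp, 130)
  expect_equal(ct$tn, 74)
  expect_equal(ct$tp + ct$tn, 204)

  ct2 <- counts_from_rates(39, 100, 39, 100)
  expect_equal(c(ct2$tp, ct2$tn), c(39, 39))

  ct3 <- counts_from_rates(39, 74.36, 39, 84.62)
  expect_equal(ct3$tp + ct3$tn, 62)

  expect_error(counts_from_rates(10, 120, 10, 50), "within")
})

test_that("rate -> count -> rate round-trips to two decimals", {
  set.seed(81)
  for (rep in 1:200) {
    n_pos <- sample(500, 1); n_neg <- sample(500, 1)
    tp <- sample(0:n_pos, 1); tn <- sample(0:n_neg, 1)
    rates <- confusion_metrics(confusion_counts(tp, n_neg - tn, tn,
                                                n_pos - tp))
    back <- counts_from_rates(n_pos, rates["sensitivity"],
                              n_neg, rates["specificity"])
    expect_equal(back$tp, tp)
    expect_equal(back$tn, tn)
    rates2 <- confusion_metrics(back)
    expect_equal(rates, rates2)
  }
})

test_that("AUC equals exhaustive pair counting", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  set.seed(91)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # force some ties
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(101)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(qnorm(plogis(scores)), labels)$auc, a,
               tolerance = 1e-12)
})

test_that("confidence intervals are sane and contain the point estimate", {
  set.seed(111)
  scores <- c(rnorm(40), rnorm(40, 1.2))
  labels <- rep(c(0, 1), each = 40)
  r <- roc_auc(scores, labels)
  expect_gte(r$ci95[1], 0)
  expect_lte(r$ci95[2], 1)
  expect_gte(r$auc, r$ci95[1])
  expect_lte(r$auc, r$ci95[2])
  rl <- roc_auc(scores, labels, ci_scale = "logit")
  expect_gte(rl$ci95[1], 0)
  expect_lte(rl$ci95[2], 1)
})

test_that("paired DeLong test is symmetric and degenerate-safe", {
  set.seed(121)
  labels <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + labels
  b <- rnorm(40) + 0.5 * labels

  same <- delong_paired_test(a, a, labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  d1 <- delong_paired_test(a, b, labels)
  d2 <- delong_paired_test(b, a, labels)
  expect_equal(d1$delta_auc, -d2$delta_auc)
  expect_equal(d1$p, d2$p)

  flipped <- delong_paired_test(a, b, 1 - labels)
  expect_equal(flipped$delta_auc, -d1$delta_auc, tolerance = 1e-12)
  expect_equal(flipped$p, d1$p, tolerance = 1e-12)
})

test_that("cohort statistics flag real differences and not null ones", {
  df <- data.frame(label = rep(c(0, 1), each = 20),
                   x = rep(c(1, 2, 3, 4, 5), 8),
                   g = rep(c("a", "b"), 20),
                   stringsAsFactors = FALSE)
  st <- cohort_stats(df)
  expect_gt(st$p[st$variable == "x"], 0.95)
  expect_gt(st$p[st$variable == "g"], 0.9)

  co <- generate_cohort(cohort_config(157, 155, seed = 33))
  tab <- cohort_table(co)
  st2 <- cohort_stats(tab)
  expect_lt(st2$p[st2$variable == "long_axis"], 0.01)
  expect_true(st2$significant[st2$variable == "long_axis"])
})

test_that("histogram overlap matches hand binning", {
  expect_equal(diameter_histogram_overlap(c(1, 2, 11, 12),
                                          c(0, 0, 1, 1), 0.25), 0)
  expect_equal(diameter_histogram_overlap(c(5, 7, 5, 7),
                                          c(0, 0, 1, 1), 0.25), 100)
  expect_equal(diameter_histogram_overlap(c(10.1, 12.0, 10.2, 30.0),
                                          c(0, 0, 1, 1), 0.25), 50)
  expect_error(diameter_histogram_overlap(numeric(0), integer(0)),
               "empty")
})

test_that("AUC, variance and paired test agree with an independent
          reference implementation", {
  set.seed(131)
  labels <- rep(c(0, 1), each = 35)
  a <- rnorm(70) + 0.9 * labels
  b <- rnorm(70) + 0.4 * labels
  r <- roc_auc(a, labels)
  roc_a <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(roc_a)), tolerance = 1e-12)
  expect_equal(r$variance, pROC::var(roc_a, method = "delong"),
               tolerance = 1e-10)
  dl <- delong_paired_test(a, b, labels)
  ref <- pROC::roc.test(roc_a, pROC::roc(labels, b, quiet = TRUE,
                                         direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-10)
})
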