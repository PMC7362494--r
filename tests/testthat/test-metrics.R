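test_that("the Bayes posterior reproduces its analytic limits", {
  expect_equal(bayes_posterior(0.3, 0.4, 0.3), 0.4)  # independence limit
  expect_equal(bayes_posterior(0.9, 0, 0.5), 0)      # zero prior
  expect_equal(bayes_posterior(0.9, 0.5, 0.6), 0.75)
  expect_error(bayes_posterior(0.5, 0.5, 0), regexp = "positive")
  expect_error(bayes_posterior(1.2, 0.5, 0.6), regexp = "\\[0, 1\\]")
  expect_error(bayes_posterior(0.9, 0.9, 0.1), regexp = "exceed")
})

test_that("confusion metrics match hand-computed contingency tables", {
  y <- c(rep("long", 5), rep("short", 5))
  p <- c("long", "long", "long", "short", "short",
         "long", "short", "short", "short", "short")
  m <- confusion_metrics(y, p, positive = "long")
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, 75)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 80)
  expect_identical(m$accuracy + m$classification_error, 100)

  perfect <- confusion_metrics(y, y, positive = "long")
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$classification_error, 0)

  # all predicted positive: specificity 0 (TN = 0 but its denominator is not)
  allpos <- confusion_metrics(y, rep("long", 10), positive = "long")
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$sensitivity, 100)
  # all predicted negative: precision has a zero denominator
  expect_warning(
    allneg <- confusion_metrics(y, rep("short", 10), positive = "long"),
    regexp = "zero denominator"
  )
  expect_equal(allneg$precision, 0)
  expect_true(allneg$degenerate)
  expect_error(confusion_metrics(y[1:3], p, positive = "long"),
               regexp = "length")
  expect_error(confusion_metrics(rep("long", 4), rep("long", 4), "long"),
               regexp = "both")
})

test_that("trapezoid AUC equals the exhaustive concordant-pair oracle", {
  expect_equal(roc_auc(c("long", "long", "short"), c(3, 2, 1), "long")$auc, 1)
  expect_equal(roc_auc(c("long", "long", "short"), c(1, 2, 3), "long")$auc, 0)
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    y <- sample(c("long", "short"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("long", "short")
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    auc <- roc_auc(y, s, "long")$auc
    pos <- which(y == "long")
    neg <- which(y == "short")
    pairs <- expand.grid(p = pos, q = neg)
    oracle <- mean(ifelse(s[pairs$p] > s[pairs$q], 1,
                          ifelse(s[pairs$p] == s[pairs$q], 0.5, 0)))
    expect_equal(auc, oracle, tolerance = 1e-12)
    # invariance under a strictly monotone transform of the scores
    expect_equal(roc_auc(y, exp(3 * s), "long")$auc, auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(rep("long", 5), 1:5, "long"), regexp = "both")
})

test_that("lift tables conserve positives and normalize correctly", {
  y <- c(rep("long", 3), rep("short", 27))
  s <- 30:1  # perfect ordering
  lt <- lift_table(y, s, "long", n_bins = 10)
  expect_equal(lt$lift[1], 10)
  expect_equal(lt$cum_coverage[1], 100)
  expect_identical(sum(lt$positives), 3L)
  expect_true(all(diff(lt$cum_coverage) >= 0))
  expect_equal(lt$cum_coverage[10], 100)

  one <- lift_table(y, s, "long", n_bins = 1)
  expect_equal(one$lift, 1)
  expect_equal(one$cum_coverage, 100)

  # random scores average to lift about one
  set.seed(11)
  mean_lift <- mean(vapply(1:50, function(i) {
    yy <- sample(c(rep("long", 20), rep("short", 80)))
    mean(lift_table(yy, runif(100), "long", n_bins = 10)$lift)
  }, numeric(1)))
  expect_lt(abs(mean_lift - 1), 0.2)
  expect_error(lift_table(rep("short", 5), 1:5, "long", n_bins = 5),
               regexp = "no positive")
  expect_error(lift_table(y, s, "long", n_bins = 40), regexp = "n_bins")
})

test_that("evaluate_classifier produces the full panel for fitted models", {
  ds <- sep_data(n = 24, d = 8, n_inf = 6, classes = 2, sep = 8, seed = 3)
  sp <- split_stratified(ds, 1 / 3, seed = 2)
  fit <- ins(sp$train)
  panel <- evaluate_classifier(fit, sp$test)
  expect_identical(panel$accuracy + panel$classification_error, 100)
  expect_true(panel$auc >= 0 && panel$auc <= 1)
  expect_true(all(unlist(panel[c("precision", "sensitivity", "specificity")]) >= 0))

  # an oracle model scores a perfect panel
  oracle_model <- structure(list(), class = "qw_oracle_model")
  assign("predict.qw_oracle_model",
         function(object, newdata, type = "class", ...) {
           if (identical(type, "score")) {
             sc <- matrix(0, nrow(newdata), 2,
                          dimnames = list(NULL, c("short", "long")))
             sc[cbind(seq_len(nrow(newdata)),
                      match(as.character(newdata$label), c("short", "long")))] <- 1
             return(sc)
           }
           newdata$label
         }, envir = globalenv())
  withr::defer(rm("predict.qw_oracle_model", envir = globalenv()))
  p2 <- evaluate_classifier(oracle_model, sp$test)
  expect_equal(p2$accuracy, 100)
  expect_equal(p2$auc, 1)

  # macro averaging over three classes stays inside the panel bounds
  ds3 <- sep_data(n = 24, d = 8, n_inf = 6, classes = 3, sep = 8, seed = 4)
  sp3 <- split_stratified(ds3, 1 / 3, seed = 2)
  p3 <- evaluate_classifier(ins(sp3$train), sp3$test, pairing = "macro")
  expect_true(p3$accuracy >= 0 && p3$accuracy <= 100)
})
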