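test_that("the registry partitions components into implemented and stubs", {
  reg <- describe_registry()
  sels <- reg[reg$kind == "selector", ]
  expect_setequal(sels$name[sels$status == "implemented"], c("none", "gwo", "rf"))
  expect_setequal(sels$name[sels$status == "stub"], c("pso", "aco", "abc", "pca"))
  cls <- reg[reg$kind == "classifier", ]
  expect_true(all(c("airs", "clonalg", "ins", "nb", "lr", "dt", "rf", "svm")
                  %in% cls$name[cls$status == "implemented"]))
  expect_identical(cls$name[cls$status == "stub"], "negsel")
  expect_false(anyDuplicated(paste(reg$kind, reg$name)) > 0)
  parsed <- jsonlite::fromJSON(describe_registry(as_json = TRUE))
  expect_identical(nrow(parsed), nrow(reg))
})

test_that("stub components raise uniform not-implemented errors naming the ontology class", {
  ds <- sep_data(n = 12, d = 6, n_inf = 4, classes = 2, sep = 6, seed = 1)
  expect_error(fit_selector("pso", ds, k = 3), class = "qw_not_implemented",
               regexp = "OM_PSO")
  expect_error(train_classifier("negsel", ds), class = "qw_not_implemented",
               regexp = "OM_NgS")
  expect_error(fit_selector("bogus", ds, k = 3), class = "qw_registry_error",
               regexp = "gwo")
})

test_that("every baseline honours the uniform train/predict/score contract", {
  ds <- sep_data(n = 30, d = 8, n_inf = 6, classes = 3, sep = 8, seed = 6)
  sp <- split_stratified(ds, 1 / 3, seed = 3)
  for (name in c("nb", "lr", "dt", "rf", "svm")) {
    fit <- train_classifier(name, sp$train, seed = 4)
    pred <- predict(fit, sp$test)
    expect_s3_class(pred, "factor")
    expect_identical(length(pred), nrow(sp$test))
    sc <- predict(fit, sp$test, type = "score")
    expect_identical(nrow(sc), nrow(sp$test))
    expect_true(all(colnames(sc) %in% c("short", "medium", "long")))
    # strong separation: every engine should beat chance comfortably
    expect_gt(mean(pred == sp$test$label), 0.5)
  }
})

test_that("compare_algorithms crosses selectors with classifiers deterministically", {
  ds <- sep_data(n = 24, d = 10, n_inf = 6, classes = 3, sep = 8, seed = 8)
  cmp <- compare_algorithms(
    ds, selectors = c("none", "gwo"), classifiers = c("nb", "dt", "ins"),
    cv_folds = 3, k = 6, seed = 5,
    selector_args = list(gwo = list(n_wolves = 5, iterations = 4))
  )
  expect_identical(nrow(cmp), 6L)
  expect_true(all(cmp$accuracy + cmp$classification_error == 100))
  expect_false(anyNA(cmp$accuracy))
  cmp2 <- compare_algorithms(
    ds, selectors = c("none", "gwo"), classifiers = c("nb", "dt", "ins"),
    cv_folds = 3, k = 6, seed = 5,
    selector_args = list(gwo = list(n_wolves = 5, iterations = 4))
  )
  expect_equal(as.data.frame(cmp), as.data.frame(cmp2))
  wide <- format_comparison(cmp)
  expect_identical(wide$performance[1], "accuracy")
  expect_identical(ncol(wide), 7L)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("random-forest importance selection recovers marker descriptors", {
  ds <- sep_data(n = 30, d = 20, n_inf = 4, classes = 2, sep = 8, seed = 10)
  idx <- fit_selector("rf", ds, k = 4, seed = 2)
  inf <- informative_indices(generate_synthetic(30, 20, 4, 2, 8, 1, seed = 10))
  expect_gte(length(intersect(idx, inf)), 3)
})
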