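test_that("descriptor CSV round-trips and rejects bad tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- toy_table()
  write_descriptor_csv(ds, path)
  back <- read_descriptor_csv(path)
  expect_equal(as.data.frame(back[c("d1", "d2", "d3", "d4")]),
               as.data.frame(ds[c("d1", "d2", "d3", "d4")]),
               tolerance = 1e-12)
  expect_identical(as.character(back$label), ds$label)
  expect_identical(dim(as.matrix(back[c("d1", "d2", "d3", "d4")])), c(3L, 4L))

  bad <- ds
  bad$label[2] <- "extra-long"
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_descriptor_csv(path2), class = "qw_label_error")

  bad2 <- readr::read_csv(path, show_col_types = FALSE)
  bad2$d1[1] <- NA
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad2, path3)
  expect_error(read_descriptor_csv(path3), class = "qw_load_error",
               regexp = "d1")
})

test_that("min-max normalization maps columns to [0,1] and is idempotent", {
  norm <- minmax_normalize(toy_table())
  expect_equal(norm$d1, c(0, 0.5, 1))
  expect_equal(norm$d2, c(0, 0, 0))        # constant column rule
  expect_equal(norm$d4, c(0, 0.5, 1))
  expect_equal(minmax_normalize(norm), norm)
  # bounds are exact for every non-constant column
  ds <- generate_synthetic(20, 10, 5, 3, 2, seed = 4)
  n2 <- minmax_normalize(ds)
  X <- as.matrix(n2[sprintf("D%04d", 1:10)])
  expect_identical(unname(apply(X, 2, min)), rep(0, 10))
  expect_identical(unname(apply(X, 2, max)), rep(1, 10))
})

test_that("stratified splitting preserves class proportions and is seeded", {
  ds <- generate_synthetic(30, 6, 3, 3, 2, seed = 2)
  sp <- split_stratified(ds, 1 / 3, seed = 7)
  expect_true(nrow(sp$test) %in% 9:10)
  expect_true(all(table(sp$test$label) %in% 3:4))
  expect_identical(sort(c(sp$train$compound_id, sp$test$compound_id)),
                   sort(ds$compound_id))
  sp2 <- split_stratified(ds, 1 / 3, seed = 7)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  # different seeds give different memberships somewhere in 10 tries
  others <- vapply(1:10, function(s) {
    paste(split_stratified(ds, 1 / 3, seed = s)$test$compound_id, collapse = ",")
  }, character(1))
  expect_gt(length(unique(others)), 1)

  tiny <- toy_table()  # one compound per class
  expect_error(split_stratified(tiny, 0.5, seed = 1), regexp = "fewer than 2")
  expect_error(split_stratified(ds, 0, seed = 1), regexp = "strictly between")
})

test_that("synthetic generation has the requested shape and is reproducible", {
  ds <- generate_synthetic(15, 2005, 200, 3, 3, seed = 11)
  X <- as.matrix(ds[descriptor_cols_for_test(ds)])
  expect_identical(dim(X), c(15L, 2005L))
  expect_identical(length(X), 30075L)
  expect_identical(length(informative_indices(ds)), 200L)
  ds2 <- generate_synthetic(15, 2005, 200, 3, 3, seed = 11)
  expect_identical(ds, ds2)  # bitwise
  expect_error(generate_synthetic(10, 5, 6, 2, 1), regexp = "n_informative")
  expect_error(generate_synthetic(10, 5, 2, 4, 1), regexp = "n_classes")
  expect_error(generate_synthetic(10, 5, 2, 2, 1, noise_sd = 0), regexp = "noise_sd")
})

test_that("zero separation leaves informative columns indistinguishable from noise", {
  pvals <- unlist(lapply(1:20, function(s) {
    ds <- generate_synthetic(40, 25, 10, 2, class_separation = 0, seed = s)
    X <- as.matrix(ds[descriptor_cols_for_test(ds)])
    apply(X, 2, function(col) t.test(col[ds$label == "short"],
                                     col[ds$label == "long"])$p.value)
  }))
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("large separation makes informative columns individually separating", {
  ds <- generate_synthetic(15, 20, 1, 2, class_separation = 10, seed = 3)
  X <- as.matrix(ds[descriptor_cols_for_test(ds)])
  j <- informative_indices(ds)
  x <- X[, j]
  # some threshold on the informative column splits the classes perfectly
  short_max <- max(x[ds$label == "short"])
  long_min <- min(x[ds$label == "long"])
  expect_true(short_max < long_min || min(x[ds$label == "short"]) > max(x[ds$label == "long"]))
})

test_that("synthetic metadata sidecar round-trips as JSON", {
  ds <- generate_synthetic(10, 8, 4, 2, 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_meta(ds, path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(meta$informative, informative_indices(ds))
  expect_identical(meta$spec$seed, 1L)
})
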