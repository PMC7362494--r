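test_that("class standards carry a valid singular decomposition", {
  # one-row class: sigma = 1, right vector = the unit row (up to sign)
  one <- tibble::tibble(compound_id = c("a", "b"), label = c("short", "long"),
                        d1 = c(3, 0), d2 = c(4, 1))
  stds <- build_standards(one)
  s1 <- stds[[1]]
  expect_equal(s1$singular_values, 1)
  expect_equal(abs(as.numeric(s1$right_vectors)), c(0.6, 0.8))

  ds <- sep_data(n = 18, d = 6, n_inf = 4, classes = 3, sep = 6, seed = 5)
  for (std in build_standards(ds)) {
    expect_true(all(diff(std$singular_values) <= 1e-12))
    V <- std$right_vectors
    expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8)
    # full-rank energy identity: sum sigma_i^2 equals the Frobenius norm
    expect_equal(sum(std$singular_values^2), sum(std$M^2), tolerance = 1e-8)
  }
  expect_error(build_standards(ds, rank = 100), regexp = "rank")
})

test_that("binding energy follows its closed form and scale invariance", {
  std <- structure(
    list(label = "short", singular_values = c(2, 1),
         right_vectors = cbind(c(1, 0), c(0, 1)),
         rank_used = 2L, descriptors = c("d1", "d2")),
    class = "qw_class_standard"
  )
  expect_equal(binding_energy(std, c(0.6, 0.8)), -2.0)
  # orthogonal query: energy zero
  std1 <- structure(
    list(label = "short", singular_values = 1,
         right_vectors = cbind(c(1, 0)), rank_used = 1L,
         descriptors = c("d1", "d2")),
    class = "qw_class_standard"
  )
  expect_equal(binding_energy(std1, c(0, 5)), 0)
  # query equal to the standard row binds with -sigma1
  one <- tibble::tibble(compound_id = "a", label = "long", d1 = 0.6, d2 = 0.8)
  s <- build_standards(one)[[1]]
  expect_equal(binding_energy(s, c(0.6, 0.8)), -s$singular_values[1])
  # positive rescaling leaves the energy untouched
  ds <- sep_data(n = 12, d = 5, n_inf = 5, classes = 2, sep = 6, seed = 2)
  std2 <- build_standards(ds)[[1]]
  x <- runif(5) + 0.1
  expect_equal(binding_energy(std2, 3.7 * x), binding_energy(std2, x),
               tolerance = 1e-10)
  expect_error(binding_energy(std2, rep(0, 5)), regexp = "non-zero")
})

test_that("minimal binding energy recovers the class, matching the brute-force loop", {
  ds <- sep_data(n = 24, d = 8, n_inf = 6, classes = 3, sep = 6, seed = 9)
  fit <- ins(ds)
  pred <- as.character(predict(fit, ds))
  X <- as.matrix(ds[fit$descriptors])
  oracle <- apply(X, 1, function(x) {
    E <- vapply(fit$standards, function(std) binding_energy(std, x), numeric(1))
    fit$classes[which.min(E)]
  })
  expect_identical(pred, oracle)
  # resubstitution on well-separated classes is perfect
  for (s in 1:3) {
    d2 <- sep_data(n = 21, d = 9, n_inf = 6, classes = 3, sep = 6, seed = s + 20)
    f2 <- ins(d2)
    expect_equal(mean(predict(f2, d2) == d2$label), 1)
  }
})

test_that("exactly tied energies resolve to the lowest class index", {
  fit <- structure(
    list(
      standards = list(
        structure(list(label = "short", singular_values = 1,
                       right_vectors = cbind(c(1, 0)), rank_used = 1L,
                       descriptors = c("d1", "d2")),
                  class = "qw_class_standard"),
        structure(list(label = "long", singular_values = 1,
                       right_vectors = cbind(c(1, 0)), rank_used = 1L,
                       descriptors = c("d1", "d2")),
                  class = "qw_class_standard")
      ),
      classes = c("short", "long"), descriptors = c("d1", "d2"),
      config = list(rank = 1)
    ),
    class = c("qw_ins", "qw_model")
  )
  expect_identical(as.character(predict(fit, c(0.5, 0.5))), "short")
  expect_equal(energy_margin(fit, c(0.5, 0.5)), 0)
})

test_that("energy margins rank confident test compounds first", {
  ds <- sep_data(n = 24, d = 8, n_inf = 6, classes = 3, sep = 6, seed = 14)
  sp <- split_stratified(ds, 1 / 3, seed = 1)
  fit <- ins(sp$train)
  marg <- energy_margin(fit, sp$test)
  expect_true(all(marg >= 0))
  E <- predict(fit, sp$test, type = "energy")
  manual <- apply(E, 1, function(e) diff(sort(e)[1:2]))
  expect_equal(marg, manual)
  td <- tidy(fit)
  expect_identical(names(td), c("label", "component", "singular_value"))
})
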