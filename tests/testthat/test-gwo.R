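test_that("the control scalar ramps linearly from 2 to 0", {
  expect_equal(linear_a(0, 100), 2.0)
  expect_equal(linear_a(100, 100), 0.0)
  expect_equal(linear_a(50, 100), 1.0)
  expect_error(linear_a(1, 0), regexp = "T_max")
  expect_error(linear_a(-1, 10))
})

test_that("coefficient vectors respect their analytic bounds", {
  cf <- gwo_coefficients(0, 5)
  expect_equal(cf$A, rep(0, 5))
  cf2 <- gwo_coefficients(1.5, 4, r2 = rep(1, 4))
  expect_equal(cf2$C, rep(2, 4))
  cf3 <- gwo_coefficients(2, 3, r1 = rep(1, 3))
  expect_equal(cf3$A, rep(2, 3))
  set.seed(1)
  for (a in c(0.5, 1, 2)) {
    cf <- gwo_coefficients(a, 50)
    expect_true(all(cf$A >= -a & cf$A <= a))
    expect_true(all(cf$C >= 0 & cf$C <= 2))
  }
  expect_error(gwo_coefficients(3, 2), regexp = "\\[0, 2\\]")
})

test_that("the leader update reduces correctly in its limit cases", {
  zero <- function(d) list(A = rep(0, d), C = rep(1, d))
  # A = 0 and identical leaders: the wolf lands exactly on the leader
  x_star <- c(0.2, 0.7, 0.4)
  out <- leader_update(c(0.9, 0.1, 0.5), x_star, x_star, x_star,
                       zero(3), zero(3), zero(3))
  expect_equal(out, x_star)
  # identical moved positions average to themselves
  v <- c(0.3, 0.6)
  expect_equal(
    leader_update(v, v, v, v, zero(2), zero(2), zero(2)), v
  )
  # scalar hand case: D = (0.4, 0.4, 0), X = (0.7, 0.3, 0.5), mean = 0.5
  out2 <- leader_update(
    0.5, 0.9, 0.1, 0.5,
    list(A = 0.5, C = 1), list(A = -0.5, C = 1), list(A = 0, C = 1)
  )
  expect_equal(out2, 0.5)
  expect_error(
    leader_update(c(0.1, 0.2), c(0.1, 0.2, 0.3), c(0.1, 0.2), c(0.1, 0.2),
                  zero(2), zero(2), zero(2)),
    regexp = "dimension"
  )
  # results are clipped to the unit cube
  big <- list(A = rep(-5, 2), C = rep(2, 2))
  out3 <- leader_update(c(0, 0), c(1, 1), c(1, 1), c(1, 1), big, big, big)
  expect_true(all(out3 >= 0 & out3 <= 1))
})

test_that("top-k thresholding breaks ties to the lower index", {
  expect_identical(subset_from_weights(c(0.1, 0.9, 0.5), 2), c(2L, 3L))
  expect_identical(subset_from_weights(rep(0.5, 4), 2), c(1L, 2L))
  expect_identical(subset_from_weights(c(0.3, 0.1, 0.6), 3), 1:3)
  expect_error(subset_from_weights(c(1, 2), 3), regexp = "k")
})

test_that("the wrapper fitness behaves as a penalized CV accuracy", {
  sep <- sep_data(n = 30, d = 12, n_inf = 8, classes = 2, sep = 10, seed = 5)
  inf <- informative_indices(
    generate_synthetic(30, 12, 8, 2, 10, 1, seed = 5)
  )
  f <- gwo_fitness(sep, inf, size_penalty = 0.01, margin_weight = 0, seed = 1)
  expect_gte(f, 1 - 0.01 * length(inf) / 12 - 0.01)
  # with no penalty and no margin the fitness is the plain CV accuracy
  all_cols <- seq_len(12)
  f0 <- gwo_fitness(sep, all_cols, size_penalty = 0, margin_weight = 0, seed = 3)
  expect_gte(f0, 0)
  expect_lte(f0, 1)
  f_pen <- gwo_fitness(sep, all_cols, size_penalty = 0.5, margin_weight = 0, seed = 3)
  expect_equal(f0 - f_pen, 0.5)
  expect_error(gwo_fitness(sep, integer(0)), regexp = "non-empty")
})

test_that("pure-noise subsets score near chance on balanced binary data", {
  accs <- vapply(1:20, function(s) {
    ds <- sep_data(n = 24, d = 10, n_inf = 2, classes = 2, sep = 8, seed = s)
    noise <- setdiff(seq_len(10),
                     informative_indices(generate_synthetic(24, 10, 2, 2, 8, 1, seed = s)))
    gwo_fitness(ds, noise, size_penalty = 0, margin_weight = 0, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("gwo_select is elitist, clipped and bitwise reproducible", {
  ds <- sep_data(n = 24, d = 20, n_inf = 6, classes = 3, sep = 6, seed = 9)
  sel <- gwo_select(ds, k = 6, n_wolves = 8, iterations = 10, seed = 21)
  expect_true(all(diff(sel$fitness_trace) >= 0))
  expect_true(all(sel$weights >= 0 & sel$weights <= 1))
  expect_identical(length(sel$selected_indices), 6L)
  expect_identical(sel$selected_indices, sort(sel$selected_indices))
  sel2 <- gwo_select(ds, k = 6, n_wolves = 8, iterations = 10, seed = 21)
  expect_identical(sel, sel2)
  expect_error(gwo_select(ds, k = 6, n_wolves = 3, iterations = 5),
               regexp = "n_wolves")
  # reduced table carries exactly the selected descriptor columns
  red <- apply_selection(ds, sel)
  expect_identical(setdiff(names(red), c("compound_id", "label")),
                   sel$selected_descriptors)
})

test_that("tidy, glance and autoplot summarise a selection run", {
  ds <- sep_data(n = 18, d = 10, n_inf = 4, classes = 2, sep = 6, seed = 2)
  sel <- gwo_select(ds, k = 3, n_wolves = 6, iterations = 5, seed = 1)
  td <- tidy(sel)
  expect_identical(nrow(td), 10L)
  expect_identical(sum(td$selected), 3L)
  gl <- glance(sel)
  expect_identical(gl$k, 3)
  expect_equal(gl$best_fitness, max(sel$fitness_trace))
  expect_s3_class(autoplot(sel), "ggplot")
})
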