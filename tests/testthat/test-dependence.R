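test_that("align_activity interpolates the slow trace onto the rate grid", {
  const <- poremap:::activity_trace(0:10, rep(3, 11), "breaking")
  expect_equal(align_activity(const, seq(0.5, 9.5, 1)), rep(3, 10))
  ramp <- poremap:::activity_trace(c(0, 1), c(0, 2), "breaking")
  expect_equal(align_activity(ramp, 0.5), 1.0)
  same <- poremap:::activity_trace(0:5, c(0, 1, 4, 9, 16, 25), "breaking")
  expect_equal(align_activity(same, 0:5), same$a)
  expect_error(align_activity(ramp, c(0.5, 1.5)), "extrapolation error")
})

test_that("pearson_dependence clamps the noise floor at zero", {
  set.seed(5)
  x <- rnorm(100)
  expect_equal(pearson_dependence(x, x), 1.0)
  expect_equal(pearson_dependence(c(1, 2, 3), c(3, 2, 1)), 0)  # raw -1
  r <- c(1, 2, 4); a <- c(1, 3, 2)
  expect_equal(pearson_dependence(r, a), max(0, oracle_pearson(r, a)),
               tolerance = 1e-14)
  expect_equal(pearson_dependence(rep(2, 10), rnorm(10)), 0)   # zero variance
  expect_error(pearson_dependence(1:4, 1:5), "dimension error")
})

test_that("mutual_information guards its domain", {
  set.seed(6)
  expect_warning(mi <- mutual_information(rnorm(20), rnorm(20)),
                 "fewer than 50")
  expect_equal(mi, 0)
  expect_error(mutual_information(c(rnorm(99), NA), rnorm(100)),
               "domain error")
  expect_equal(mutual_information(rep(1, 100), rnorm(100)), 0)
})

test_that("MI estimator is symmetric and invariant under affine rescaling", {
  g <- make_gaussian_pair(1500, 0.6, seed = 8)
  m0 <- mutual_information(g$x, g$y)
  expect_lt(abs(m0 - mutual_information(g$y, g$x)), 1e-10)
  # standardization is internal: affine maps of either input change nothing
  expect_lt(abs(mutual_information(5 + 13 * g$x, g$y) - m0), 0.02)
  expect_lt(abs(mutual_information(g$x, -2 * g$y + 100) - m0), 0.02)
  # determinism: same inputs, same estimate, bit for bit
  expect_identical(m0, mutual_information(g$x, g$y))
})

test_that("MI adapts to zero-inflated activities (the motivating regime)", {
  a <- make_zero_inflated_activity(1500, 0.5, seed = 9)
  set.seed(10)
  r_ind <- abs(rnorm(1500))
  r_cpy <- a * (1 + 0.01 * rnorm(1500))
  mi_ind <- mutual_information(r_ind, a)
  mi_cpy <- mutual_information(r_cpy, a)
  expect_lt(mi_ind, 0.1)
  expect_gte(mi_cpy, 10 * mi_ind)
  expect_gt(mi_cpy, 0.5)
})

planted_rates <- function(n_t, sig, noise_pairs, seed = 1) {
  # one pair whose rate IS the activity, the rest independent noise
  set.seed(seed)
  r <- cbind(sig, matrix(abs(rnorm(n_t * noise_pairs)), n_t))
  structure(list(times = seq_len(n_t) - 0.5,
                 i = rep(1L, noise_pairs + 1L), j = 2L:(noise_pairs + 2L),
                 r = r), class = "RateSeries")
}

test_that("dependence_matrix satisfies the positive-symmetric contract", {
  n_t <- 200
  act <- poremap:::activity_trace(0:n_t, c(0, abs(sin(1:n_t / 9))), "breaking")
  sig <- align_activity(act, seq_len(n_t) - 0.5)
  rates <- planted_rates(n_t, sig, noise_pairs = 10, seed = 2)
  dm <- dependence_matrix(rates, act, "pearson")
  expect_true(isSymmetric(dm$R))
  expect_true(all(dm$R >= 0))
  expect_equal(diag(dm$R), rep(0, dm$n))
  expect_true(all(dm$R[!dm$mask] == 0))
  # the planted pair dominates; noise pairs sit near the floor
  expect_equal(dm$R[1, 2], 1.0, tolerance = 1e-12)
  expect_lt(max(dm$R[1, 3:12]), 0.25)
  # constant rates carry no information
  rates0 <- rates; rates0$r[] <- 3
  expect_equal(max(dependence_matrix(rates0, act, "pearson")$R), 0)
  expect_error(dependence_matrix(structure(list(times = 1, i = integer(),
                                                j = integer(),
                                                r = matrix(0, 1, 0)),
                                           class = "RateSeries"),
                                 act, "pearson"), "empty-matrix")
})

test_that("MI dependence_matrix finds the planted pair too", {
  n_t <- 400
  act <- poremap:::activity_trace(0:n_t, c(0, abs(sin(1:n_t / 20))), "breaking")
  sig <- align_activity(act, seq_len(n_t) - 0.5)
  rates <- planted_rates(n_t, sig * (1 + 0.02 * rnorm(n_t)), 6, seed = 3)
  dm <- dependence_matrix(rates, act, "mutual_information")
  expect_true(isSymmetric(dm$R))
  expect_true(all(dm$R >= 0))
  expect_gt(dm$R[1, 2], 3 * max(dm$R[1, 3:8]))
})

test_that("dependence matrix writers round-trip the computed entries", {
  rates <- planted_rates(100, abs(rnorm(100)), 4, seed = 11)
  act <- poremap:::activity_trace(0:100, abs(rnorm(101)), "breaking")
  dm <- dependence_matrix(rates, act, "pearson")
  dense <- withr::local_tempfile(fileext = ".txt")
  trip <- withr::local_tempfile(fileext = ".tsv")
  write_dependence_matrix(dm, dense)
  write_dependence_triplets(dm, trip)
  expect_match(readLines(dense, n = 1), "n=6 method=pearson")
  got <- utils::read.table(dense, skip = 1)
  expect_equal(as.matrix(got), dm$R, ignore_attr = TRUE, tolerance = 1e-15)
  tt <- utils::read.table(trip, sep = "\t", comment.char = "#")
  expect_equal(nrow(tt), sum(dm$mask) / 2)
  expect_equal(tt[[3]], dm$R[cbind(tt[[1]], tt[[2]])])
})
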