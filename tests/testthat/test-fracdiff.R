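test_that("half-order weights match the documented sequence", {
  expect_equal(gl_weights(0.5, 3), c(1, -0.5, -0.125, -0.0625))
  expect_equal(gl_weights(1, 3), c(1, -1, 0, 0))
  expect_equal(gl_weights(2, 4), c(1, -2, 1, 0, 0))
})

test_that("recurrence weights agree with direct Gamma-ratio evaluation", {
  for (nu in c(0.2, 0.5, 1.5, 1, 2)) {
    expect_equal(gl_weights(nu, 50), gl_weights_gamma(nu, 50),
                 tolerance = 1e-12, label = sprintf("nu = %g", nu))
  }
})

test_that("the backward sum matches a brute-force evaluation", {
  set.seed(3)
  x <- runif(20)
  for (nu in c(0.4, 1.3)) {
    got <- fractional_derivative(x, fracdiff_spec(nu))
    expect_equal(got, gl_derivative_bruteforce(x, nu), tolerance = 1e-10)
  }
})

test_that("order 0 is the identity and orders 1/2 are adjacent differences", {
  set.seed(1)
  x <- cumsum(rnorm(30))
  expect_equal(fractional_derivative(x, fracdiff_spec(0)), x)
  d1 <- fractional_derivative(x, fracdiff_spec(1))
  expect_identical(d1[-1], diff(x))
  d2 <- fractional_derivative(x, fracdiff_spec(2))
  expect_equal(d2[-(1:2)], diff(diff(x)))
})

test_that("the transform is linear in its input", {
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  sp <- fracdiff_spec(0.7)
  lhs <- fractional_derivative(2.5 * x - 1.3 * y, sp)
  rhs <- 2.5 * fractional_derivative(x, sp) -
    1.3 * fractional_derivative(y, sp)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("step scaling divides by h^nu", {
  x <- runif(10)
  a <- fractional_derivative(x, fracdiff_spec(0.5, step = 2))
  b <- fractional_derivative(x, fracdiff_spec(0.5, step = 1))
  expect_equal(a, b / 2^0.5)
})

test_that("finite memory truncates the backward sum", {
  x <- runif(12)
  sp <- fracdiff_spec(0.5, memory = 3)
  got <- fractional_derivative(x, sp)
  w <- gl_weights(0.5, 3)
  manual <- vapply(seq_along(x), function(k) {
    m <- 0:min(k - 1, 3)
    sum(w[m + 1] * x[k - m])
  }, numeric(1))
  expect_equal(got, manual)
})

test_that("mark_invalid blanks the incomplete leading stencil", {
  x <- runif(8)
  d2 <- fractional_derivative(x, fracdiff_spec(2, boundary = "mark_invalid"))
  expect_true(all(is.na(d2[1:2])))
  expect_false(anyNA(d2[-(1:2)]))
})

test_that("transform_cube differentiates every pixel and respects the mask", {
  set.seed(4)
  arr <- array(runif(3 * 3 * 10), c(3, 3, 10))
  mask <- matrix(TRUE, 3, 3); mask[2, 2] <- FALSE
  cube <- hyper_cube(arr, seq(450, 900, length.out = 10), mask = mask)
  out <- transform_cube(cube, fracdiff_spec(1.5))
  expect_equal(out$wavelengths, cube$wavelengths)
  expect_true(all(is.na(out$data[2, 2, ])))
  expect_equal(out$data[1, 3, ],
               fractional_derivative(arr[1, 3, ], fracdiff_spec(1.5)))
})

test_that("invalid differentiation parameters are rejected", {
  expect_error(fracdiff_spec(-1), "order")
  expect_error(fracdiff_spec(1, step = 0), "step")
  expect_error(fractional_derivative(numeric(0), fracdiff_spec(1)), "empty")
})
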