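test_that("kernel parameters enforce the open interval and derive alpha", {
  p <- kernel_params(0.75, 4)
  expect_equal(p$alpha, log(3))
  expect_equal(p$L, 4L)
  expect_error(kernel_params(0.5, 4), "strictly inside")
  expect_error(kernel_params(1, 4), "strictly inside")
  expect_error(kernel_params(0.3, 4), "strictly inside")
  expect_error(kernel_params(0.75, 0), "positive integer")
  # alpha > 0 across the admissible range
  for (lam in c(0.5001, 0.6, 0.9, 0.9999))
    expect_gt(kernel_params(lam, 1)$alpha, 0)
})

test_that("Hamming distance counts disagreements and matches the inner-product form", {
  expect_identical(hamming_distance(c(1, 0, 1), c(1, 0, 1)), 0L)
  expect_identical(hamming_distance(c(1, 0, 1), c(1, 1, 0)), 2L)
  expect_identical(hamming_distance(c(1, 1, 1, 1), c(0, 0, 0, 0)), 4L)
  set.seed(7)
  for (k in 1:50) {
    L <- sample(1:40, 1)
    x <- random_bits(1, L)[1, ]
    y <- random_bits(1, L)[1, ]
    d <- hamming_distance(x, y)
    expect_identical(d, hamming_distance(y, x))
    expect_equal(d, sum(x * x) - 2 * sum(x * y) + sum(y * y))
    expect_true(d >= 0 && d <= L)
  }
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)), "same length")
  expect_error(hamming_distance(c(1, 2), c(1, 0)), "0/1")
})

test_that("AA kernel matches its closed form, peaks at identity and decays in d", {
  p <- kernel_params(0.75, 2)
  expect_equal(aa_kernel(c(1, 0), c(1, 0), p), 0.5625)
  expect_equal(aa_kernel(c(1, 0), c(1, 1), p), 0.1875)
  expect_equal(aa_kernel(c(1, 0), c(0, 1), p), 0.0625)
  # symmetry and agreement with the brute-force form on random pairs
  set.seed(11)
  for (k in 1:100) {
    L <- sample(1:30, 1)
    lam <- runif(1, 0.51, 0.99)
    pp <- kernel_params(lam, L)
    x <- random_bits(1, L)[1, ]
    y <- random_bits(1, L)[1, ]
    kxy <- aa_kernel(x, y, pp)
    expect_equal(kxy, aa_kernel(y, x, pp), tolerance = 1e-14)
    expect_equal(kxy, oracle_kernel(x, y, lam), tolerance = 1e-13)
    expect_equal(aa_kernel(x, y, pp, log = TRUE), log(kxy), tolerance = 1e-12)
  }
  # strict monotone decay in the Hamming distance (lambda > 0.5)
  pp <- kernel_params(0.8, 6)
  y <- rep(0, 6)
  vals <- sapply(0:6, function(d) aa_kernel(c(rep(1, d), rep(0, 6 - d)), y, pp))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 0.8^6)
})

test_that("the kernel is a probability mass function on {0,1}^L", {
  for (lam in c(0.55, 0.75, 0.9)) {
    L <- 3
    pp <- kernel_params(lam, L)
    E <- enumerate_bits(L)
    y <- c(1, 0, 1)
    s <- sum(apply(E, 1, function(x) aa_kernel(x, y, pp)))
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("the exponential factorization is algebraically identical to the kernel", {
  set.seed(23)
  for (k in 1:1000) {
    L <- sample(1:30, 1)
    lam <- runif(1, 0.505, 0.995)
    pp <- kernel_params(lam, L)
    x <- random_bits(1, L)[1, ]
    y <- random_bits(1, L)[1, ]
    a <- aa_kernel(x, y, pp)
    b <- aa_kernel_factorized(x, y, pp)
    expect_lt(abs(a - b) / a, 1e-12)
  }
  pp <- kernel_params(0.75, 2)
  expect_equal(aa_kernel_factorized(c(0, 0), c(0, 0), pp), 0.75^2)
})

test_that("series coefficients reproduce the exponential expansion", {
  expect_equal(series_coefficient(0, 2.5), 1)
  expect_equal(series_coefficient(1, log(3)), 2 * log(3))
  expect_equal(series_coefficient(3, 1), 8 / 6)
  expect_error(series_coefficient(-1, 1), "non-negative")
  expect_error(series_coefficient(2, -1), "positive")
  # partial sums converge to exp(2 alpha t); order 60 suffices while the
  # series argument 2 alpha t stays below ~24 (the order-60 Taylor
  # remainder of exp(w) is only ~1e-10 relative up to there)
  alpha <- 0.5
  for (t in c(1, 5, 12, 20)) {
    s <- sum(series_coefficient(0:60, alpha) * t^(0:60))
    expect_lt(abs(s - exp(2 * alpha * t)) / exp(2 * alpha * t), 1e-10)
  }
})

test_that("tail factor matches its closed form, limits and log-scale regime", {
  expect_equal(tail_factor(0, 1), 2)
  expect_equal(tail_factor(1, 1), 4 * (exp(1) - 2), tolerance = 1e-14)
  expect_equal(tail_factor(1e-10, 1), 2, tolerance = 1e-8)
  # mid regime: oracle by the defining series 4 a^2 sum_j mu^j / (j+2)!
  # (the naive exp(mu)-mu-1 form cancels catastrophically at small mu)
  for (mu in c(0.01, 0.5, 3, 12)) {
    alpha <- 0.7
    oracle <- 4 * alpha^2 * sum(mu^(0:60) / factorial(2:62))
    expect_equal(tail_factor(mu, alpha), oracle, tolerance = 1e-13)
    expect_equal(tail_factor(mu, alpha, log = TRUE),
                 log(tail_factor(mu, alpha)), tolerance = 1e-12)
  }
  # large arguments: the exponential dominates, no cancellation left
  expect_equal(tail_factor(50, 0.7), 4 * 0.7^2 * (exp(50) - 51) / 2500,
               tolerance = 1e-12)
  # strictly increasing in mu, continuous across regime boundaries
  mus <- c(0, 1e-6, 9e-5, 1.1e-4, 0.01, 1, 10, 100, 699, 701, 800)
  vals <- tail_factor(mus, 1, log = TRUE)
  expect_true(all(diff(vals) > 0))
  expect_equal(tail_factor(1.0000001e-4, 1), tail_factor(0.9999999e-4, 1),
               tolerance = 1e-9)
  # large-mu log form: exp(mu) dominates
  expect_equal(tail_factor(800, 2, log = TRUE),
               800 - 2 * log(800) + log(16), tolerance = 1e-10)
  expect_error(tail_factor(-1, 1), "non-negative")
})
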