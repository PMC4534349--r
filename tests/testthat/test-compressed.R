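test_that("class summaries accumulate a, z, z', Q as defined", {
  p <- kernel_params(0.75, 2) # alpha = log 3, so beta = 1/3 for popcount 1
  s <- compress_class(c(1, 0), p)
  expect_equal(s$n_omega, 1L)
  expect_equal(s$a, 1 / 3)
  expect_equal(unname(s$z), c(1, 0))
  expect_equal(s$z_prime, c(1 / 3, 0))
  expect_equal(as.matrix(s$Q), matrix(c(1 / 3, 0, 0, 0), 2), ignore_attr = TRUE)

  # all-zero prototypes: beta = 1, everything else collapses
  s0 <- compress_class(matrix(0, 5, 3), kernel_params(0.8, 3))
  expect_equal(s0$a, 5)
  expect_equal(unname(s0$z), c(0, 0, 0))
  expect_equal(s0$z_prime, c(0, 0, 0))
  expect_equal(sum(abs(s0$Q)), 0)

  # duplicated prototypes double every accumulator
  x <- c(1, 1, 0)
  p3 <- kernel_params(0.7, 3)
  s1 <- compress_class(x, p3)
  s2 <- compress_class(rbind(x, x), p3)
  expect_equal(s2$a, 2 * s1$a)
  expect_equal(s2$z, 2 * s1$z)
  expect_equal(s2$z_prime, 2 * s1$z_prime)
  expect_equal(as.matrix(s2$Q), 2 * as.matrix(s1$Q))

  expect_error(compress_class(matrix(0, 0, 2), p), "at least one")
})

test_that("summaries are additive over prototype sets", {
  set.seed(53)
  for (k in 1:20) {
    L <- sample(3:30, 1)
    p <- kernel_params(runif(1, 0.55, 0.95), L)
    P1 <- random_bits(sample(1:10, 1), L, p = 0.4)
    P2 <- random_bits(sample(1:10, 1), L, p = 0.4)
    s12 <- compress_class(rbind(P1, P2), p)
    ssum <- compress_class(P1, p) + compress_class(P2, p)
    expect_equal(s12$n_omega, ssum$n_omega)
    expect_equal(s12$a, ssum$a, tolerance = 1e-14)
    expect_equal(s12$z, ssum$z)
    expect_equal(s12$z_prime, ssum$z_prime, tolerance = 1e-14)
    expect_equal(as.matrix(s12$Q), as.matrix(ssum$Q), tolerance = 1e-14)
  }
})

test_that("summary invariants hold: bounds, symmetry, positive semidefiniteness", {
  set.seed(59)
  for (k in 1:10) {
    L <- sample(4:20, 1)
    n <- sample(1:25, 1)
    p <- kernel_params(runif(1, 0.55, 0.95), L)
    s <- compress_class(random_bits(n, L, 0.5), p)
    expect_true(s$a > 0 && s$a <= s$n_omega)
    expect_true(all(s$z_prime <= s$z + 1e-12) && all(s$z_prime >= 0))
    expect_true(all(s$z <= s$n_omega))
    Qd <- as.matrix(s$Q)
    expect_equal(Qd, t(Qd))
    expect_true(all(diag(Qd) <= s$z_prime + 1e-12))
    expect_true(min(eigen(Qd, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  }
})

test_that("the compressed density is exact for single-prototype classes", {
  set.seed(61)
  grid <- expand.grid(lam = c(0.55, 0.75, 0.95), L = c(4, 16, 64))
  for (g in seq_len(nrow(grid))) {
    lam <- grid$lam[g]; L <- grid$L[g]
    p <- kernel_params(lam, L)
    for (k in 1:15) {
      proto <- random_bits(1, L)
      x <- random_bits(1, L)[1, ]
      s <- compress_class(proto, p)
      lc <- class_conditional_compressed(x, s, p, log = TRUE)
      le <- class_conditional_exact(
        x, labeled_dataset(proto, "A"), "A", p, log = TRUE)
      expect_lt(rel_err_log(lc, le), 1e-9)
    }
  }
})

test_that("an all-zero query keeps only the zeroth-order term", {
  set.seed(67)
  p <- kernel_params(0.8, 10)
  s <- compress_class(random_bits(12, 10), p)
  expect_equal(class_conditional_compressed(rep(0, 10), s, p),
               0.8^10 * s$a / 12, tolerance = 1e-14)
})

test_that("compressed density is non-negative and lambda mismatches are refused", {
  set.seed(71)
  p <- kernel_params(0.75, 8)
  s <- compress_class(random_bits(10, 8), p)
  for (k in 1:20) {
    x <- random_bits(1, 8)[1, ]
    expect_gte(class_conditional_compressed(x, s, p), 0)
  }
  expect_error(class_conditional_compressed(rep(0, 8), s, kernel_params(0.8, 8)),
               "lambda")
})

test_that("the truncated series grows with order and converges to the exact density", {
  set.seed(73)
  p <- kernel_params(0.75, 16)
  X <- random_bits(20, 16)
  x <- random_bits(1, 16)[1, ]
  d <- labeled_dataset(X, rep("A", 20))
  # r_max = 0 keeps only B * a
  s <- compress_class(X, p)
  B <- 0.75^16 * exp(-p$alpha * sum(x)) / 20
  expect_equal(class_conditional_truncated(x, X, p, 0), B * s$a,
               tolerance = 1e-12)
  vals <- sapply(c(0, 1, 2, 5, 10, 30, 60),
                 function(r) class_conditional_truncated(x, X, p, r))
  expect_true(all(diff(vals) >= 0))
  exact <- class_conditional_exact(x, d, "A", p)
  expect_lt(abs(vals[length(vals)] - exact) / exact, 1e-10)
})

test_that("dropping the tail reproduces the first-order truncated estimator", {
  set.seed(79)
  for (k in 1:25) {
    L <- sample(4:24, 1)
    n <- sample(2:30, 1)
    p <- kernel_params(runif(1, 0.55, 0.95), L)
    X <- random_bits(n, L, 0.4)
    x <- random_bits(1, L)[1, ]
    s <- compress_class(X, p)
    low <- class_conditional_compressed(x, s, p, tail = FALSE)
    tr1 <- class_conditional_truncated(x, X, p, 1)
    expect_lt(abs(low - tr1) / tr1, 1e-13)
  }
})

test_that("summary storage tracks bit support, not prototype count", {
  set.seed(83)
  p <- kernel_params(0.75, 40)
  X <- random_bits(15, 40, p = 0.15)
  s1 <- compress_class(X, p)
  s10 <- compress_class(X[rep(1:15, 10), ], p)
  nz <- function(s) length(parzenfp:::summary_triplets(s$Q)$x)
  # identical stored-element counts after 10x duplication
  expect_identical(nz(s1), nz(s10))
  expect_identical(length(s1$z), length(s10$z))
  # nnz(Q) is bounded by the distinct co-occurring bit pairs (i <= j)
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    on <- which(X[i, ] == 1)
    if (!length(on)) return(NULL)
    as.matrix(expand.grid(on, on))
  })))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  expect_lte(nz(s1), nrow(pairs))
})

test_that("the fidelity report flags the exactness regime and measures the rest", {
  p2 <- kernel_params(0.75, 6)
  # single prototype per class: compressed is exact, decisions agree
  d <- labeled_dataset(rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 1, 1)),
                       c("A", "B"))
  set.seed(89)
  rep1 <- compression_error_report(d, p2, random_bits(20, 6))
  expect_lt(rep1$summary$max_rel_error, 1e-9)
  expect_equal(rep1$summary$decision_agreement, 1)
  # general multi-prototype classes: finite entries, complete table
  d2 <- labeled_dataset(random_bits(20, 6), rep(c("A", "B"), each = 10))
  rep2 <- compression_error_report(d2, p2, random_bits(10, 6))
  expect_equal(nrow(rep2$table), 10 * 2)
  expect_true(all(is.finite(rep2$table$rel_error)))
  expect_true(all(is.finite(rep2$table$log_ratio)))
  expect_true(all(rep2$table$rel_error >= 0 & rep2$table$rel_error <= 1))
  expect_true(all(rep2$table$compressed >= 0))
})
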