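# Aitchison-Aitken kernel and the scalar pieces of its power-series expansion.

#' Smoothing parameters for the Aitchison--Aitken kernel
#'
#' Bundles the smoothing parameter `lambda`, its log-odds transform
#' `alpha = log(lambda / (1 - lambda))`, and the feature dimension `L`.
#' `lambda` plays the role of a bandwidth: as `lambda` approaches 1 the
#' kernel concentrates on the reference pattern; as it approaches 0.5 it
#' flattens towards the uniform distribution on `{0,1}^L`. Both endpoints
#' are excluded because `alpha` degenerates there (0 and infinity).
#'
#' @param lambda Smoothing parameter, strictly inside (0.5, 1).
#' @param L Feature dimension (number of bits), a positive integer.
#' @return An object of class `"kernel_params"`: a list with elements
#'   `lambda`, `alpha` (> 0) and `L`.
#' @examples
#' kernel_params(0.75, 16)
#' @export
kernel_params <- function(lambda, L) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
    stop("`lambda` must be a single finite number", call. = FALSE)
  if (lambda <= 0.5 || lambda >= 1)
    stop("`lambda` must lie strictly inside (0.5, 1): at 0.5 the kernel is ",
         "uniform and at 1 it is a point mass; alpha = log(lambda/(1-lambda)) ",
         "degenerates at both ends", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stop("`L` must be a positive integer", call. = FALSE)
  structure(
    list(lambda = lambda, alpha = log(lambda / (1 - lambda)), L = as.integer(L)),
    class = "kernel_params"
  )
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("Aitchison-Aitken kernel parameters: lambda = %g, alpha = %g, L = %d\n",
              x$lambda, x$alpha, x$L))
  invisible(x)
}

# validate a 0/1 vector, optionally of prescribed length; returns it as numeric
check_bits <- function(x, L = NULL, arg = "x") {
  if (is.logical(x)) x <- as.numeric(x)
  if (!is.numeric(x))
    stop("`", arg, "` must be a numeric (or logical) vector", call. = FALSE)
  if (anyNA(x) || any(x != 0 & x != 1))
    stop("`", arg, "` must contain only 0/1 entries", call. = FALSE)
  if (!is.null(L) && length(x) != L)
    stop("`", arg, "` has length ", length(x), " but dimension L = ", L,
         " was expected", call. = FALSE)
  as.numeric(x)
}

# validate an n-by-L 0/1 matrix
check_bit_matrix <- function(x, L = NULL, arg = "x") {
  if (is.vector(x) || is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  if (anyNA(x) || any(x != 0 & x != 1))
    stop("`", arg, "` must contain only 0/1 entries", call. = FALSE)
  if (!is.null(L) && ncol(x) != L)
    stop("`", arg, "` has ", ncol(x), " columns but dimension L = ", L,
         " was expected", call. = FALSE)
  x
}

#' Hamming distance between two binary vectors
#'
#' Number of positions at which `x` and `y` disagree. Equals the
#' inner-product form `x'x - 2 x'y + y'y` for 0/1 vectors, which is the
#' identity the kernel factorization rests on.
#'
#' @param x,y Binary 0/1 vectors of equal length.
#' @return A non-negative integer in `0..length(x)`.
#' @examples
#' hamming_distance(c(1, 0, 1), c(1, 1, 0)) # 2
#' @export
hamming_distance <- function(x, y) {
  x <- check_bits(x, arg = "x")
  y <- check_bits(y, arg = "y")
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length (got ", length(x), " and ",
         length(y), ")", call. = FALSE)
  as.integer(sum(x != y))
}

#' The Aitchison--Aitken kernel on binary vectors
#'
#' Evaluates `K(x, y; lambda) = lambda^L * ((1 - lambda)/lambda)^d(x, y)`,
#' where `d` is the Hamming distance. The kernel is a probability mass
#' function in `x` for fixed `y` (it sums to 1 over `{0,1}^L`), peaks at
#' `x == y` with value `lambda^L`, and decays geometrically in `d`.
#'
#' `aa_kernel_factorized()` evaluates the algebraically identical
#' exponential form
#' `lambda^L * exp(-alpha x'x) * exp(2 alpha x'y) * exp(-alpha y'y)`,
#' the factorization that makes the series expansion (and hence the
#' compressed estimator) possible.
#'
#' @param x,y Binary 0/1 vectors of length `params$L`.
#' @param params A [kernel_params()] object.
#' @param log If `TRUE`, return the log kernel value (recommended for
#'   `L` in the hundreds, where `lambda^L` underflows).
#' @return Kernel value in `(0, lambda^L]`, or its log.
#' @examples
#' p <- kernel_params(0.75, 2)
#' aa_kernel(c(1, 0), c(1, 0), p)            # 0.5625 = 0.75^2
#' aa_kernel_factorized(c(1, 0), c(0, 1), p) # 0.0625
#' @export
aa_kernel <- function(x, y, params, log = FALSE) {
  stopifnot(inherits(params, "kernel_params"))
  d <- hamming_distance(check_bits(x, params$L, "x"), check_bits(y, params$L, "y"))
  lk <- params$L * base::log(params$lambda) +
    d * base::log((1 - params$lambda) / params$lambda)
  if (log) lk else exp(lk)
}

#' @rdname aa_kernel
#' @export
aa_kernel_factorized <- function(x, y, params, log = FALSE) {
  stopifnot(inherits(params, "kernel_params"))
  x <- check_bits(x, params$L, "x")
  y <- check_bits(y, params$L, "y")
  a <- params$alpha
  lk <- params$L * base::log(params$lambda) -
    a * sum(x) + 2 * a * sum(x * y) - a * sum(y)
  if (log) lk else exp(lk)
}

#' Coefficients of the exponential power series
#'
#' The expansion `exp(2 alpha t) = sum_r gamma_r t^r` has coefficients
#' `gamma_r = (2 alpha)^r / r!`. These weight the inner-product powers
#' `(x'x_i)^r` in the series form of the kernel.
#'
#' @param r Non-negative integer order(s); vectorized.
#' @param alpha Positive log-odds parameter.
#' @return `gamma_r`, computed on the log scale internally so large `r`
#'   does not overflow intermediates.
#' @examples
#' series_coefficient(0:3, alpha = 1) # 1, 2, 2, 4/3
#' @export
series_coefficient <- function(r, alpha) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r != floor(r)))
    stop("`r` must contain non-negative integers", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  exp(r * base::log(2 * alpha) - lgamma(r + 1))
}

#' Closed-form tail of the kernel series
#'
#' The compressed estimator replaces the series terms of order r >= 2 by
#' `g(mu) = 4 alpha^2 (exp(mu) - mu - 1) / mu^2` with `mu = 2 alpha x'z`.
#' `g` is continuous and strictly increasing in `mu >= 0`, with the
#' analytic limit `g(0) = 2 alpha^2`.
#'
#' Evaluation is three-regime for numerical stability: a Taylor expansion
#' `2 alpha^2 (1 + mu/3 + mu^2/12)` below `mu = 1e-4` (naive evaluation
#' cancels catastrophically there), `expm1`-based arithmetic in the middle,
#' and -- since `exp(mu)` overflows past `mu ~ 709` -- a log-scale form
#' `log g = log(4 alpha^2) + mu + log1p(-(mu + 1) exp(-mu)) - 2 log(mu)`
#' for large `mu`. In linear scale the value is `Inf` once `exp(mu)`
#' overflows; use `log = TRUE` there.
#'
#' @param mu Non-negative scalar or vector, `mu = 2 alpha x'z`.
#' @param alpha Positive log-odds parameter.
#' @param log If `TRUE`, return `log g(mu)`.
#' @return `g(mu)` (or its log), vectorized over `mu`.
#' @examples
#' tail_factor(0, 1)  # 2 = 2 alpha^2
#' tail_factor(1, 1)  # 4 * (e - 2)
#' @export
tail_factor <- function(mu, alpha, log = FALSE) {
  if (!is.numeric(mu) || anyNA(mu) || any(mu < 0))
    stop("`mu` must be non-negative (x'z >= 0 for binary data)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  out <- numeric(length(mu))
  small <- mu < 1e-4
  large <- mu > 700
  mid <- !small & !large
  c0 <- 4 * alpha^2
  if (log) {
    # series: 2a^2 (1 + mu/3 + mu^2/12)
    out[small] <- base::log(c0 / 2) + log1p(mu[small] / 3 + mu[small]^2 / 12)
    if (any(mid))
      out[mid] <- base::log(c0) + base::log(expm1(mu[mid]) - mu[mid]) -
        2 * base::log(mu[mid])
    if (any(large))
      out[large] <- base::log(c0) + mu[large] +
        log1p(-(mu[large] + 1) * exp(-mu[large])) - 2 * base::log(mu[large])
  } else {
    out[small] <- (c0 / 2) * (1 + mu[small] / 3 + mu[small]^2 / 12)
    if (any(mid))
      out[mid] <- c0 * (expm1(mu[mid]) - mu[mid]) / mu[mid]^2
    if (any(large))
      out[large] <- exp(base::log(c0) + mu[large] - 2 * base::log(mu[large]))
  }
  out
}

# log(sum(exp(lx))) guarded against overflow; -Inf inputs are handled
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(lx - m)))
}
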