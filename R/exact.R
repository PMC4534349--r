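# Brute-force Parzen Window estimator, priors, posteriors and the Bayes rule.

#' Class prior probabilities
#'
#' Empirical priors are the class frequencies `N_omega / N`; the uniform
#' alternative assigns `1/J` to each class present in the dataset.
#'
#' @param dataset A [labeled_dataset()].
#' @param mode `"empirical"` (class frequency) or `"uniform"`.
#' @return A named numeric vector over `dataset$classes`, summing to 1,
#'   with attribute `"mode"`.
#' @examples
#' d <- labeled_dataset(matrix(0, 10, 2), rep(c("A", "B"), c(3, 7)))
#' class_priors(d)            # A = 0.3, B = 0.7
#' class_priors(d, "uniform") # 0.5 each
#' @export
class_priors <- function(dataset, mode = c("empirical", "uniform")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  mode <- match.arg(mode)
  if (mode == "empirical") {
    p <- as.numeric(table(factor(dataset$labels, levels = dataset$classes))) /
      dataset$N
  } else {
    p <- rep(1 / dataset$J, dataset$J)
  }
  structure(stats::setNames(p, dataset$classes), mode = mode)
}

#' Exact Parzen Window class-conditional density
#'
#' The brute-force estimate: the mean Aitchison--Aitken kernel value of
#' the query over all prototypes of the class,
#' `p(x | omega) = (1/N_omega) sum_i K(x, x_i; lambda)`.
#' Because each kernel is a probability mass function, so is the mean;
#' the estimate lies in `(0, lambda^L]` and attains `lambda^L` only when
#' every prototype equals the query.
#'
#' Computation runs in the log domain throughout (kernel logs combined by
#' log-sum-exp), so `L` in the hundreds does not underflow.
#'
#' @param x Binary query vector of length `dataset$L`.
#' @param dataset A [labeled_dataset()].
#' @param class A class label present in the dataset.
#' @param params A [kernel_params()] with `L = dataset$L`.
#' @param log If `TRUE`, return the log density.
#' @return The density estimate (or its log).
#' @examples
#' d <- labeled_dataset(rbind(c(1, 0), c(0, 1)), c("A", "A"))
#' p <- kernel_params(0.75, 2)
#' class_conditional_exact(c(1, 0), d, "A", p) # (0.5625 + 0.0625)/2 = 0.3125
#' @export
class_conditional_exact <- function(x, dataset, class, params, log = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(params, "kernel_params"))
  if (params$L != dataset$L)
    stop("kernel params have L = ", params$L, " but the dataset has L = ",
         dataset$L, call. = FALSE)
  x <- check_bits(x, dataset$L, "x")
  X <- class_patterns(dataset, class)
  d <- rowSums(X) + sum(x) - 2 * as.numeric(X %*% x)
  lk <- params$L * base::log(params$lambda) +
    d * base::log((1 - params$lambda) / params$lambda)
  ld <- logsumexp(lk) - base::log(nrow(X))
  if (log) ld else exp(ld)
}

# posteriors from per-class log densities and priors; the shared core of
# every backend.  Max-subtraction inside logsumexp keeps this stable when
# all densities underflow linearly.
posterior_from_log <- function(log_dens, priors) {
  lp <- log_dens + base::log(priors)
  if (all(!is.finite(lp)))
    stop("evidence underflowed to zero even in the log domain; all ",
         "class-conditional log densities are -Inf for this query",
         call. = FALSE)
  log_evidence <- logsumexp(lp)
  p <- exp(lp - log_evidence)
  attributes(p) <- list(names = names(p))
  p
}

#' Posterior class probabilities for one query
#'
#' Bayes' rule `p(omega | x) = p(x | omega) p(omega) / p(x)` with the
#' evidence `p(x) = sum_j p(x | omega_j) p(omega_j)`. Densities come from
#' whichever backend the model was fitted with (exact, compressed, or
#' truncated series). All arithmetic is in the log domain with
#' max-subtraction, so posteriors are well defined even when every linear
#' density underflows.
#'
#' @param x Binary query vector.
#' @param model A [parzen_fit()] model.
#' @return An object of class `"posterior_result"`: a list with
#'   `class_conditionals` (linear scale), `log_class_conditionals`,
#'   `priors`, `log_evidence`, `posteriors` (summing to 1) and
#'   `predicted` (the argmax class; ties go to the lexicographically
#'   smallest label).
#' @examples
#' d <- labeled_dataset(rbind(c(1, 0), c(0, 1)), c("A", "B"))
#' m <- parzen_fit(d, lambda = 0.75, backend = "exact")
#' parzen_posterior(c(1, 0), m)$predicted # "A"
#' @export
parzen_posterior <- function(x, model) {
  stopifnot(inherits(model, "parzen_model"))
  ld <- log_density_vector(model, x)
  post <- posterior_from_log(ld, model$priors)
  # classes are stored sorted, so the first maximum is the lexicographic tie-break
  predicted <- model$classes[which.max(post)]
  structure(
    list(class_conditionals = exp(ld),
         log_class_conditionals = ld,
         priors = model$priors,
         log_evidence = logsumexp(ld + base::log(model$priors)),
         posteriors = post,
         predicted = predicted),
    class = "posterior_result"
  )
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("Posterior class probabilities:\n")
  print(round(x$posteriors, 6))
  cat("predicted class:", x$predicted, "\n")
  invisible(x)
}

#' Classify a query pattern
#'
#' Assigns `x` to the class with the maximal posterior probability
#' (minimum-error rule under equal misclassification costs). Exact
#' posterior ties are broken in favour of the lexicographically smallest
#' class label.
#'
#' @inheritParams parzen_posterior
#' @return A class label.
#' @export
parzen_classify <- function(x, model) {
  parzen_posterior(x, model)$predicted
}
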