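# Fitted classifier object and prediction across the three backends.

#' Fit a Parzen Window classifier on binary fingerprints
#'
#' Builds a classifier from labeled binary patterns using the
#' Aitchison--Aitken kernel. Three interchangeable density backends are
#' available:
#'
#' * `"exact"` -- the brute-force Parzen estimate, averaging the kernel
#'   over every stored prototype of the class;
#' * `"compressed"` -- the summary-statistic estimator: each class is
#'   reduced to a scalar `a`, vectors `z`, `z'` and a sparse matrix `Q`,
#'   after which prototypes are discarded (see [compress_class()]);
#' * `"truncated"` -- the power series truncated at order `r_max`,
#'   evaluated from stored prototypes; mainly a verification bridge
#'   between the other two.
#'
#' @param dataset A [labeled_dataset()].
#' @param lambda Kernel smoothing parameter in (0.5, 1). Default 0.75.
#' @param prior `"empirical"` (class frequencies) or `"uniform"`.
#' @param backend `"compressed"`, `"exact"` or `"truncated"`.
#' @param r_max Truncation order for the `"truncated"` backend.
#' @return An object of class `"parzen_model"`.
#' @examples
#' d <- labeled_dataset(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 1)),
#'                      c("A", "A", "B", "B"))
#' m <- parzen_fit(d, lambda = 0.75)
#' predict(m, c(1, 0, 0))
#' @export
parzen_fit <- function(dataset, lambda = 0.75,
                       prior = c("empirical", "uniform"),
                       backend = c("compressed", "exact", "truncated"),
                       r_max = 60L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  prior <- match.arg(prior)
  backend <- match.arg(backend)
  params <- kernel_params(lambda, dataset$L)
  priors <- class_priors(dataset, prior)
  model <- list(params = params, priors = priors, prior_mode = prior,
                backend = backend, classes = dataset$classes,
                L = dataset$L, J = dataset$J, r_max = as.integer(r_max))
  if (backend == "compressed") {
    model$summaries <- stats::setNames(
      lapply(dataset$classes, function(cl)
        compress_class(class_patterns(dataset, cl), params)),
      dataset$classes)
  } else {
    model$prototypes <- stats::setNames(
      lapply(dataset$classes, function(cl) class_patterns(dataset, cl)),
      dataset$classes)
  }
  structure(model, class = "parzen_model")
}

#' @export
print.parzen_model <- function(x, ...) {
  cat(sprintf("Parzen Window classifier (%s backend)\n", x$backend))
  cat(sprintf("  lambda = %g (alpha = %g), L = %d, J = %d classes, %s priors\n",
              x$params$lambda, x$params$alpha, x$L, x$J, x$prior_mode))
  if (x$backend == "compressed") {
    for (cl in x$classes) {
      s <- x$summaries[[cl]]
      cat(sprintf("  class %s: N = %d, nnz(Q) = %d\n", cl, s$n_omega,
                  length(summary_triplets(s$Q)$x)))
    }
  }
  invisible(x)
}

# per-class log densities for one query, dispatching on the backend
log_density_vector <- function(model, x) {
  x <- check_bits(x, model$L, "x")
  vapply(model$classes, function(cl) {
    switch(model$backend,
      exact = {
        X <- model$prototypes[[cl]]
        d <- rowSums(X) + sum(x) - 2 * as.numeric(X %*% x)
        lk <- model$L * base::log(model$params$lambda) +
          d * base::log((1 - model$params$lambda) / model$params$lambda)
        logsumexp(lk) - base::log(nrow(X))
      },
      compressed = class_conditional_compressed(x, model$summaries[[cl]],
                                                model$params, log = TRUE),
      truncated = class_conditional_truncated(x, model$prototypes[[cl]],
                                              model$params, model$r_max,
                                              log = TRUE)
    )
  }, numeric(1))
}

#' Class-conditional densities for a batch of queries
#'
#' @param model A [parzen_fit()] model.
#' @param newdata An `m x L` binary matrix (or one vector) of queries.
#' @param log If `TRUE`, return log densities.
#' @return An `m x J` matrix of densities, columns named by class.
#' @export
parzen_density <- function(model, newdata, log = FALSE) {
  stopifnot(inherits(model, "parzen_model"))
  X <- check_bit_matrix(newdata, model$L, "newdata")
  out <- t(apply(X, 1L, function(row) log_density_vector(model, row)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(NULL, model$classes))
  colnames(out) <- model$classes
  if (log) out else exp(out)
}

#' Predict classes or posteriors for new patterns
#'
#' @param object A [parzen_fit()] model.
#' @param newdata An `m x L` binary matrix (or one vector) of queries.
#' @param type `"class"` for predicted labels, `"posterior"` for the
#'   `m x J` posterior probability matrix, `"density"` for the raw
#'   class-conditional densities.
#' @param log For `type = "density"`, return log densities.
#' @param ... Unused.
#' @return A character vector of labels, or an `m x J` matrix.
#' @export
predict.parzen_model <- function(object, newdata,
                                 type = c("class", "posterior", "density"),
                                 log = FALSE, ...) {
  type <- match.arg(type)
  X <- check_bit_matrix(newdata, object$L, "newdata")
  if (type == "density") return(parzen_density(object, X, log = log))
  post <- t(apply(X, 1L, function(row) {
    posterior_from_log(log_density_vector(object, row), object$priors)
  }))
  if (nrow(X) == 1L) post <- matrix(post, nrow = 1L)
  colnames(post) <- object$classes
  if (type == "posterior") return(post)
  object$classes[apply(post, 1L, which.max)]
}
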