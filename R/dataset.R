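# Labeled binary fingerprint datasets.

#' Construct a labeled fingerprint dataset
#'
#' The training container for all estimators: an `N x L` binary pattern
#' matrix together with one class label per row. Labels are opaque
#' strings; no numeric coercion is applied.
#'
#' @param patterns An `N x L` matrix (or a single vector, taken as one
#'   row) with entries in `{0, 1}`.
#' @param labels Character vector of length `N` of class labels.
#' @param ids Optional character vector of per-pattern identifiers;
#'   defaults to `p1..pN`.
#' @return An object of class `"labeled_dataset"`: a list with elements
#'   `patterns`, `labels`, `ids`, `L`, `N`, `J` and `classes` (the sorted
#'   unique labels).
#' @examples
#' d <- labeled_dataset(rbind(c(1, 0, 1), c(1, 1, 0), c(0, 1, 1)),
#'                      c("A", "A", "B"))
#' d$J # 2
#' @export
labeled_dataset <- function(patterns, labels, ids = NULL) {
  patterns <- check_bit_matrix(patterns, arg = "patterns")
  if (nrow(patterns) < 1L)
    stop("the dataset must contain at least one pattern", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(patterns))
    stop("`labels` must have one entry per pattern row (got ",
         length(labels), " labels for ", nrow(patterns), " patterns)",
         call. = FALSE)
  if (anyNA(labels))
    stop("`labels` must not contain NA", call. = FALSE)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(patterns)))
  ids <- as.character(ids)
  if (length(ids) != nrow(patterns))
    stop("`ids` must have one entry per pattern row", call. = FALSE)
  classes <- sort(unique(labels))
  structure(
    list(patterns = patterns, labels = labels, ids = ids,
         L = ncol(patterns), N = nrow(patterns),
         J = length(classes), classes = classes),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled fingerprint dataset: N = %d patterns, L = %d bits, J = %d classes\n",
              x$N, x$L, x$J))
  tab <- table(x$labels)
  cat("  class sizes:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# rows of the pattern matrix belonging to one class (always a matrix)
class_patterns <- function(dataset, class) {
  if (!class %in% dataset$classes)
    stop("class '", class, "' is not present in the dataset", call. = FALSE)
  dataset$patterns[dataset$labels == class, , drop = FALSE]
}
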