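#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric, non-negative condition-by-condition matrix with a
#' zero diagonal and condition labels in its dimnames. It is the central
#' currency of the pipeline: behavioural distance judgments, stimulus-property
#' models and neural pattern distances all take this form.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param labels optional character vector of condition labels; defaults to
#'   existing row names or `cond1..condN`.
#' @return an object of class `rdm` (a labelled numeric matrix).
#' @export
rdm <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("an RDM must be a square matrix", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("cond", seq_len(nrow(values)))
  }
  dimnames(values) <- list(labels, labels)
  class(values) <- c("rdm", "matrix", "array")
  validate_rdm(values)
  values
}

#' Validate RDM invariants
#'
#' Checks symmetry, a zero diagonal, finiteness and non-negativity, stopping
#' with an informative error on the first violation.
#'
#' @param x matrix to validate.
#' @param tol numeric tolerance for symmetry and diagonal checks.
#' @return `x`, invisibly.
#' @export
validate_rdm <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("an RDM must be a square matrix", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("RDM entries must be finite", call. = FALSE)
  if (max(abs(x - t(x))) > tol) stop("RDM must be symmetric", call. = FALSE)
  if (max(abs(diag(x))) > tol) stop("RDM diagonal must be zero", call. = FALSE)
  if (min(x) < -tol) stop("RDM entries must be non-negative", call. = FALSE)
  invisible(x)
}

rdm_labels <- function(x) rownames(x)

#' Element-wise average of a list of RDMs
#'
#' @param rdms non-empty list of `rdm` objects with identical shape and label
#'   order.
#' @return the element-wise arithmetic mean as an `rdm`.
#' @export
average_rdms <- function(rdms) {
  if (!is.list(rdms) || length(rdms) == 0) {
    stop("'rdms' must be a non-empty list", call. = FALSE)
  }
  labs <- rdm_labels(rdms[[1]])
  n <- nrow(rdms[[1]])
  for (r in rdms) {
    if (nrow(r) != n || !identical(rdm_labels(r), labs)) {
      stop("all RDMs must share shape and label order", call. = FALSE)
    }
  }
  rdm(Reduce(`+`, lapply(rdms, unclass)) / length(rdms), labels = labs)
}

#' Vectorize the lower triangle of an RDM
#'
#' Returns the off-diagonal lower-triangle entries in fixed column-major order
#' (row index > column index), the order used for every RDM correlation in the
#' package. A 90-condition RDM yields 90*89/2 = 4005 values.
#'
#' @param x an `rdm`.
#' @return numeric vector of length `n*(n-1)/2`.
#' @export
vectorize_rdm <- function(x) {
  validate_rdm(x)
  x[lower.tri(x)]
}

#' Spearman similarity between two RDMs
#'
#' Spearman rank correlation of the two vectorized lower triangles, with
#' average ranks for ties.
#'
#' @param a,b `rdm` objects with identical labels and order.
#' @return correlation scalar in `[-1, 1]`.
#' @export
rdm_similarity <- function(a, b) {
  if (!identical(rdm_labels(a), rdm_labels(b)) || nrow(a) != nrow(b)) {
    stop("RDMs must share shape and label order", call. = FALSE)
  }
  va <- vectorize_rdm(a)
  vb <- vectorize_rdm(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: an RDM vector has zero variance", call. = FALSE)
  }
  stats::cor(rank(va), rank(vb))
}

#' Binary categorical RDM from a cluster assignment
#'
#' Entry 0 for same-cluster condition pairs, 1 otherwise; the categorical
#' benchmark model used in the RSA stage.
#'
#' @param assignment a `category_assignment` (see [cluster_words()]) or an
#'   integer vector of cluster ids, optionally named.
#' @return an `rdm`.
#' @export
categorical_rdm <- function(assignment) {
  if (inherits(assignment, "category_assignment")) {
    labels <- names(assignment$labels)
    ids <- assignment$labels
  } else {
    ids <- assignment
    labels <- names(ids)
  }
  n <- length(ids)
  if (is.null(labels)) labels <- paste0("cond", seq_len(n))
  m <- 1 - outer(ids, ids, `==`)
  storage.mode(m) <- "double"
  rdm(m, labels = labels)
}

#' Principal submatrix of an RDM
#'
#' @param x an `rdm`.
#' @param keep character vector of labels to retain, without duplicates; the
#'   result follows the order of `keep`.
#' @return an `rdm` over `keep`.
#' @export
subset_rdm <- function(x, keep) {
  validate_rdm(x)
  if (anyDuplicated(keep)) stop("'keep' contains duplicate labels", call. = FALSE)
  missing <- setdiff(keep, rdm_labels(x))
  if (length(missing)) {
    stop("unknown labels: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rdm(unclass(x)[keep, keep, drop = FALSE], labels = keep)
}

#' Read / write an RDM as delimited text
#'
#' Square tab-separated matrix with a header row (and first column) of
#' condition labels.
#'
#' @param x an `rdm`.
#' @param path file path.
#' @return `read_rdm` returns an `rdm`; `write_rdm` returns `path` invisibly.
#' @export
write_rdm <- function(x, path) {
  validate_rdm(x)
  df <- data.frame(label = rdm_labels(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rdm(m, labels = labs)
}
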