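# internal validation helpers ------------------------------------------------

.check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(what, " must be a square numeric matrix", call. = FALSE)
  invisible(m)
}

.check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  .check_square(m, what)
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale)
    stop(what, " is not symmetric", call. = FALSE)
  invisible(m)
}

.default_ids <- function(n, ids = NULL) {
  if (is.null(ids)) sprintf("s%d", seq_len(n)) else as.character(ids)
}

# values handed around internally are plain matrices; user-facing containers
# are light S3 lists in the style of ape's "pcoa" objects

#' Construct a dissimilarity matrix object
#'
#' Wraps an `n x n` matrix of pairwise dissimilarities, enforcing symmetry,
#' a zero diagonal, and non-negative entries.
#'
#' @param values square numeric matrix, a [stats::dist] object, or an
#'   existing `pare_dist`.
#' @param metric_name label recording which dissimilarity was used.
#' @param sample_ids sample identifiers; defaults to `rownames(values)`.
#' @return An object of class `pare_dist` with elements `values`,
#'   `metric_name` and `sample_ids`.
#' @export
as_dissimilarity <- function(values, metric_name = "unknown", sample_ids = NULL) {
  if (inherits(values, "pare_dist")) return(values)
  if (inherits(values, "dist")) values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  .check_symmetric(values, what = "dissimilarity matrix")
  if (any(!is.finite(values)))
    stop("dissimilarity matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("dissimilarities must be non-negative", call. = FALSE)
  if (max(abs(diag(values))) > 1e-12 * max(abs(values), 1))
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  diag(values) <- 0
  ids <- .default_ids(nrow(values), sample_ids)
  dimnames(values) <- list(ids, ids)
  structure(
    list(values = values, metric_name = metric_name, sample_ids = ids),
    class = "pare_dist"
  )
}

#' @export
print.pare_dist <- function(x, ...) {
  cat(sprintf("Dissimilarity matrix: %d samples, metric = %s\n",
              nrow(x$values), x$metric_name))
  if (!is.null(x$correction) && x$correction$constant > 0)
    cat(sprintf("  non-Euclidean correction: %s, constant = %.6g\n",
                x$correction$method, x$correction$constant))
  invisible(x)
}

#' @export
print.pare_gram <- function(x, ...) {
  cat(sprintf("%s Gram matrix: %d samples\n",
              if (isTRUE(x$is_adjusted)) "Covariate-adjusted" else "Doubly-centered",
              nrow(x$values)))
  invisible(x)
}

#' @export
print.pare_coords <- function(x, ...) {
  cat(sprintf("Principal coordinates: %d samples x %d axes (%d non-positive eigenvalues dropped)\n",
              nrow(x$coords), ncol(x$coords), x$n_dropped_nonpositive))
  if (length(x$eigenvalues))
    cat("  leading eigenvalues:",
        paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

# coerce any accepted dissimilarity input to a plain matrix
.dist_values <- function(D) {
  if (inherits(D, "pare_dist")) return(D$values)
  if (inherits(D, "dist")) return(as.matrix(D))
  .check_symmetric(D, what = "dissimilarity matrix")
  D
}

.gram_values <- function(G) {
  if (inherits(G, "pare_gram")) return(G$values)
  .check_symmetric(G, what = "Gram matrix")
  G
}
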