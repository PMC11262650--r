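# Pairwise geometry: dissimilarities, double-centering, principal coordinates,
# and the additive-constant correction for non-Euclidean inputs.

.register_builtin_metrics <- function() {
  .pare_registry$metrics <- new.env(parent = emptyenv())
  for (m in c("euclidean", "manhattan", "maximum", "canberra"))
    assign(m, m, envir = .pare_registry$metrics)
}

#' Register a dissimilarity metric
#'
#' Adds a user-defined dissimilarity so it can be named in
#' [pairwise_distances()]. The function must be symmetric and non-negative
#' with `fn(x, x) = 0`.
#'
#' @param name metric name.
#' @param fn function of two numeric vectors returning a scalar
#'   dissimilarity.
#' @param overwrite replace an existing registration?
#' @return Invisibly, `name`.
#' @export
register_metric <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (!overwrite && exists(name, envir = .pare_registry$metrics, inherits = FALSE))
    stop("metric '", name, "' is already registered", call. = FALSE)
  assign(name, fn, envir = .pare_registry$metrics)
  invisible(name)
}

#' Pairwise dissimilarities between samples
#'
#' Computes the `n x n` matrix of dissimilarities `d(y_i, y_j)` among the
#' rows of a feature matrix. Euclidean distance is the default and is the
#' metric under which partial embeddings have an exact coordinate
#' representation (see [pare_embed()]).
#'
#' @param data numeric matrix, samples in rows.
#' @param metric name of a built-in [stats::dist] method
#'   (`"euclidean"`, `"manhattan"`, `"maximum"`, `"canberra"`) or of a
#'   metric added via [register_metric()].
#' @return A [as_dissimilarity()] object.
#' @examples
#' D <- pairwise_distances(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
#' D$values[1, 2]  # 5: the 3-4-5 triangle
#' @export
pairwise_distances <- function(data, metric = "euclidean") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("feature matrix must be numeric", call. = FALSE)
  n <- nrow(data)
  if (n < 2) stop("need at least 2 samples to compute distances", call. = FALSE)
  bad <- which(!apply(is.finite(data), 1, all))
  if (length(bad))
    stop("non-finite feature values in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!exists(metric, envir = .pare_registry$metrics, inherits = FALSE))
    stop("unknown metric '", metric, "'; register it with register_metric()",
         call. = FALSE)
  fn <- get(metric, envir = .pare_registry$metrics, inherits = FALSE)
  if (is.character(fn)) {
    values <- as.matrix(stats::dist(data, method = fn))
  } else {
    values <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        values[i, j] <- values[j, i] <- fn(data[i, ], data[j, ])
      }
    }
  }
  as_dissimilarity(values, metric_name = metric,
                   sample_ids = .default_ids(n, rownames(data)))
}

#' Double-center a dissimilarity matrix
#'
#' Forms `A = -d_ij^2 / 2` and projects out row and column means,
#' `G = J A J` with the Gower centering matrix `J = I - (1/n) 11'`. When
#' the dissimilarities are Euclidean distances of a data matrix `Y`, `G`
#' equals the Gram matrix of the column-centered `Y`, i.e. `G = Yc Yc'`.
#'
#' @param D dissimilarities: a `pare_dist`, [stats::dist], or square matrix.
#' @return An object of class `pare_gram` (`values`, `is_adjusted`,
#'   `sample_ids`); every row and column of `values` sums to zero.
#' @export
double_center <- function(D) {
  v <- .dist_values(D)
  A <- -0.5 * v * v
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm) + mean(A)
  G <- (G + t(G)) / 2
  ids <- if (inherits(D, "pare_dist")) D$sample_ids else .default_ids(nrow(v), rownames(v))
  structure(list(values = G, is_adjusted = FALSE, sample_ids = ids),
            class = "pare_gram")
}

# relative eigenvalue tolerance: max(n,1) * eps * lambda_max
.eig_tol <- function(values, n) {
  max(n, 1) * .Machine$double.eps * max(values, 0)
}

#' Principal coordinates from a Gram matrix
#'
#' Classical multidimensional scaling: eigendecompose `G = U L U'` and
#' scale eigenvectors by the square roots of their (positive) eigenvalues,
#' `Z = U L^(1/2)`. Non-positive eigenvalues (at relative tolerance
#' `max(n,1) * eps * lambda_max`) are dropped and counted; each coordinate
#' column's sign is fixed so its largest-magnitude entry is positive.
#'
#' For Euclidean input dissimilarities the full-rank coordinates reproduce
#' the original pairwise distances exactly.
#'
#' @param G a `pare_gram` (from [double_center()] or [adjusted_gram()]) or
#'   symmetric matrix.
#' @param k optional maximum number of coordinates to retain.
#' @return An object of class `pare_coords` with elements `coords`
#'   (`n x k`), `eigenvalues` (non-increasing, positive),
#'   `n_dropped_nonpositive`, and `sample_ids`.
#' @export
principal_coordinates <- function(G, k = NULL) {
  v <- .gram_values(G)
  n <- nrow(v)
  ids <- if (inherits(G, "pare_gram")) G$sample_ids else .default_ids(n, rownames(v))
  e <- eigen(v, symmetric = TRUE)
  tol <- .eig_tol(e$values, n)
  keep <- which(e$values > tol)
  n_dropped <- n - length(keep)
  if (!length(keep)) {
    warning("all eigenvalues are non-positive; returning an empty coordinate set")
    coords <- matrix(0, n, 0, dimnames = list(ids, NULL))
    return(structure(list(coords = coords, eigenvalues = numeric(0),
                          n_dropped_nonpositive = n_dropped, sample_ids = ids),
                     class = "pare_coords"))
  }
  if (!is.null(k)) keep <- keep[seq_len(min(k, length(keep)))]
  lambda <- e$values[keep]
  U <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  Z <- sweep(U, 2, sqrt(lambda), `*`)
  dimnames(Z) <- list(ids, sprintf("PCo%d", seq_along(keep)))
  structure(list(coords = Z, eigenvalues = lambda,
                 n_dropped_nonpositive = n_dropped, sample_ids = ids),
            class = "pare_coords")
}

#' Additive-constant correction for non-Euclidean dissimilarities
#'
#' A dissimilarity matrix whose doubly-centered form has negative
#' eigenvalues cannot be represented exactly in Euclidean space; adding a
#' constant to every off-diagonal dissimilarity restores representability.
#' Two classical variants are provided: the Cailliez correction adds the
#' smallest constant `c` to the dissimilarities themselves
#' (`d_ij + c`, `i != j`), while the Lingoes correction adds `2c` to the
#' squared dissimilarities (`sqrt(d_ij^2 + 2c)`). Euclidean input is
#' returned unchanged with a recorded constant of zero.
#'
#' @param D dissimilarities (`pare_dist`, `dist`, or square matrix).
#' @param method `"cailliez"` (default) or `"lingoes"`.
#' @return A `pare_dist` whose double-centered matrix is positive
#'   semi-definite; the element `correction` records the method and the
#'   constant applied.
#' @export
euclidify <- function(D, method = c("cailliez", "lingoes")) {
  method <- match.arg(method)
  D <- if (inherits(D, "pare_dist")) D else as_dissimilarity(.dist_values(D))
  v <- D$values
  n <- nrow(v)
  G <- double_center(D)$values
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  tol <- .eig_tol(ev, n)
  if (min(ev) >= -tol) {
    D$correction <- list(method = method, constant = 0)
    return(D)
  }
  if (method == "cailliez") {
    # smallest c with d_ij + c Euclidean: largest real eigenvalue of the
    # 2n x 2n companion-style block matrix built from the centered -d^2/2
    # and -d/2 matrices
    J <- diag(n) - matrix(1 / n, n, n)
    A2 <- J %*% (-0.5 * v * v) %*% J
    A1 <- J %*% (-0.5 * v) %*% J
    B <- rbind(cbind(matrix(0, n, n), 2 * A2),
               cbind(-diag(n), -4 * A1))
    const <- max(Re(eigen(B, only.values = TRUE)$values))
    new_v <- v + const
  } else {
    const <- -min(ev)
    new_v <- sqrt(v * v + 2 * const)
  }
  diag(new_v) <- 0
  out <- as_dissimilarity(new_v, metric_name = paste0(D$metric_name, "+", method),
                          sample_ids = D$sample_ids)
  out$correction <- list(method = method, constant = const)
  out
}
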