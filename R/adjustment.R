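# Nuisance design matrix, hat matrix, and the adjusted-PCoA step that
# residualizes principal coordinates against covariates.

#' Build a nuisance-covariate design matrix
#'
#' Assembles the `n x p` design matrix `X` from a per-sample metadata
#' table. Categorical covariates are one-hot encoded with the first
#' (lexicographically smallest) level dropped as reference; continuous
#' covariates are mean-centered; an intercept column is always included.
#' The result must be full column rank: rank-deficient specifications
#' (e.g. a donor factor nested exactly inside batch) are rejected rather
#' than silently pseudo-inverted.
#'
#' @param metadata data frame of per-sample covariates. Sample identifiers
#'   are taken from a `sample_id` column if present, else from row names.
#' @param covariates character vector of metadata column names to adjust
#'   for.
#' @param types optional named character vector overriding the inferred
#'   type per covariate, values `"continuous"` or `"categorical"`
#'   (numeric columns default to continuous, everything else to
#'   categorical).
#' @return An object of class `pare_design`: `values` (the matrix `X`),
#'   `column_names`, `encoding_map` (per categorical covariate the
#'   level-to-column mapping), `covariates`, and `sample_ids`.
#' @examples
#' md <- data.frame(batch = c("A", "A", "B", "B"), age = c(1, 2, 3, 4))
#' build_design(md, "batch")$values
#' @export
build_design <- function(metadata, covariates, types = NULL) {
  metadata <- as.data.frame(metadata)
  n <- nrow(metadata)
  ids <- if ("sample_id" %in% names(metadata)) as.character(metadata$sample_id)
         else .default_ids(n, rownames(metadata))
  missing_cov <- setdiff(covariates, names(metadata))
  if (length(missing_cov))
    stop("covariate(s) not found in metadata: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)

  cols <- list(`(Intercept)` = rep(1, n))
  encoding_map <- list()
  for (cv in covariates) {
    vals <- metadata[[cv]]
    na <- which(is.na(vals))
    if (length(na))
      stop("covariate '", cv, "' has missing values for sample(s): ",
           paste(ids[na], collapse = ", "), call. = FALSE)
    type <- if (!is.null(types) && cv %in% names(types)) {
      match.arg(types[[cv]], c("continuous", "categorical"))
    } else if (is.numeric(vals)) "continuous" else "categorical"
    if (type == "continuous") {
      cols[[cv]] <- as.numeric(vals) - mean(as.numeric(vals))
    } else {
      f <- factor(as.character(vals))
      if (nlevels(f) < 2)
        stop("categorical covariate '", cv,
             "' has a single level and carries no information", call. = FALSE)
      lv <- levels(f)  # sorted lexicographically by factor()
      map <- c(stats::setNames("(reference)", lv[1]))
      for (l in lv[-1]) {
        cn <- paste0(cv, l)
        cols[[cn]] <- as.numeric(f == l)
        map[l] <- cn
      }
      encoding_map[[cv]] <- map
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; column(s) ",
         paste(dep, collapse = ", "),
         " are collinear with the remaining columns ",
         "(e.g. nested batch/donor factors); revise the covariate set",
         call. = FALSE)
  }
  structure(list(values = X, column_names = colnames(X),
                 encoding_map = encoding_map,
                 covariates = covariates, sample_ids = ids),
            class = "pare_design")
}

#' @export
print.pare_design <- function(x, ...) {
  cat(sprintf("Nuisance design: %d samples x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

.design_values <- function(X) {
  if (inherits(X, "pare_design")) X$values else as.matrix(X)
}

#' Projection (hat) matrix of a design
#'
#' Computes `H = X (X'X)^-1 X'`, the orthogonal projector onto the column
#' space of `X`, via the QR decomposition for numerical stability. `H` is
#' symmetric and idempotent with `trace(H) = rank(X)`.
#'
#' @param X a `pare_design` from [build_design()] or a full-column-rank
#'   numeric matrix.
#' @return An object of class `pare_projection` with elements `values`
#'   (the `n x n` matrix `H`) and `rank`.
#' @export
hat_matrix <- function(X) {
  Xv <- .design_values(X)
  qrX <- qr(Xv)
  if (qrX$rank < ncol(Xv))
    stop("design matrix is rank deficient; build it with build_design()",
         call. = FALSE)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  H <- tcrossprod(Q)
  H <- (H + t(H)) / 2
  structure(list(values = H, rank = qrX$rank), class = "pare_projection")
}

.proj_values <- function(H) {
  if (inherits(H, "pare_projection")) H$values else .check_symmetric(as.matrix(H), what = "projection matrix")
}

#' Residualize principal coordinates against nuisance covariates
#'
#' The adjusted-PCoA step: `E = (I - H) Z` regresses every principal
#' coordinate on the design and keeps the residuals, which are orthogonal
#' to the design columns (`X'E = 0`). Because the Gram matrix is doubly
#' centered, coordinates are already column-centered and the intercept
#' part of the projection is inert.
#'
#' @param Z a `pare_coords` from [principal_coordinates()] or a numeric
#'   coordinate matrix.
#' @param H a `pare_projection` from [hat_matrix()] or projection matrix.
#' @return An object of class `pare_adjusted_coords`: `coords` (the
#'   matrix `E`), `source_eigenvalues` (eigenvalues of the coordinates
#'   that were adjusted), and `sample_ids`.
#' @export
adjust_coordinates <- function(Z, H) {
  Zc <- if (inherits(Z, "pare_coords")) Z$coords else as.matrix(Z)
  ev <- if (inherits(Z, "pare_coords")) Z$eigenvalues else rep(NA_real_, ncol(Zc))
  ids <- if (inherits(Z, "pare_coords")) Z$sample_ids else .default_ids(nrow(Zc), rownames(Zc))
  Hv <- .proj_values(H)
  if (nrow(Hv) != nrow(Zc))
    stop("projection and coordinates disagree on the number of samples",
         call. = FALSE)
  E <- Zc - Hv %*% Zc
  dimnames(E) <- dimnames(Zc)
  structure(list(coords = E, source_eigenvalues = ev, sample_ids = ids),
            class = "pare_adjusted_coords")
}

#' Covariate-adjusted Gram matrix
#'
#' Projects the nuisance subspace out of the doubly-centered matrix on
#' both sides: `Delta = (I - H) G (I - H)`. This equals `E E'` where `E`
#' are the adjusted coordinates, so `Delta` is the inner-product matrix of
#' the residual geometry.
#'
#' @param G a `pare_gram` or symmetric matrix.
#' @param H a `pare_projection` or projection matrix.
#' @return A `pare_gram` with `is_adjusted = TRUE`.
#' @export
adjusted_gram <- function(G, H) {
  Gv <- .gram_values(G)
  Hv <- .proj_values(H)
  if (nrow(Hv) != nrow(Gv))
    stop("projection and Gram matrix disagree on the number of samples",
         call. = FALSE)
  M <- Gv - Hv %*% Gv
  Delta <- M - M %*% Hv
  Delta <- (Delta + t(Delta)) / 2
  ids <- if (inherits(G, "pare_gram")) G$sample_ids else .default_ids(nrow(Gv), rownames(Gv))
  structure(list(values = Delta, is_adjusted = TRUE, sample_ids = ids),
            class = "pare_gram")
}

#' Pairwise distances implied by an adjusted Gram matrix
#'
#' Converts the covariate-adjusted inner-product matrix back to genuine
#' pairwise dissimilarities via
#' `d_ij = sqrt(Delta_ii + Delta_jj - 2 Delta_ij)`, which equals the
#' Euclidean distances among the rows of the adjusted coordinates `E`.
#' This is the form any distance-based method can consume. Small negative
#' values under the square root (numerical noise, or an indefinite input)
#' are clamped to zero with a warning.
#'
#' @param Delta a `pare_gram` (typically from [adjusted_gram()]) or
#'   symmetric matrix, positive semi-definite within tolerance.
#' @return A `pare_dist` of the adjusted geometry.
#' @export
adjusted_distances <- function(Delta) {
  Dv <- .gram_values(Delta)
  n <- nrow(Dv)
  d <- diag(Dv)
  sq <- outer(d, rep(1, n)) + outer(rep(1, n), d) - 2 * Dv
  tol <- 1e-8 * max(abs(Dv), 1)
  if (min(sq) < -tol)
    warning("negative squared distances beyond tolerance were clamped to 0; ",
            "the input Gram matrix is not positive semi-definite")
  sq[sq < 0] <- 0
  out <- sqrt(sq)
  out <- (out + t(out)) / 2
  diag(out) <- 0
  ids <- if (inherits(Delta, "pare_gram")) Delta$sample_ids else .default_ids(n, rownames(Dv))
  as_dissimilarity(out, metric_name = "adjusted-euclidean", sample_ids = ids)
}
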