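# Affinity constructors: the Gaussian perplexity-calibrated kernel used by
# t-SNE (and by LISI) and the locally adaptive exponential kernel used by
# UMAP. These realize the general (precomputed-dissimilarity) route of the
# partial-embedding framework.

# Calibrate a Gaussian kernel on one row of squared dissimilarities so the
# conditional distribution p_{j|i} has Shannon entropy log2(perplexity).
# Bisection on beta = 1/(2 sigma^2); returns p, beta and achieved entropy.
# The tight default tolerance makes the calibrated weights invariant (to
# ~1e-10) under uniform rescaling of the dissimilarities.
.calibrate_gaussian <- function(d2, perplexity, tol = 1e-10, max_iter = 300L) {
  target <- log2(perplexity)
  d2s <- d2 - min(d2)
  beta <- 1
  beta_lo <- 0
  beta_hi <- Inf
  p <- NULL
  h <- NA_real_
  for (iter in seq_len(max_iter)) {
    w <- exp(-d2s * beta)
    sw <- sum(w)
    p <- w / sw
    nz <- p > 0
    h <- -sum(p[nz] * log2(p[nz]))
    if (abs(h - target) < tol) break
    if (h > target) {         # too flat: narrow the kernel
      beta_lo <- beta
      beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
    } else {                  # too peaked: widen the kernel
      beta_hi <- beta
      beta <- (beta + beta_lo) / 2
    }
  }
  list(p = p, beta = beta, entropy = h, converged = abs(h - target) < tol)
}

#' Perplexity-calibrated Gaussian affinities (t-SNE input similarities)
#'
#' For each sample `i` the conditional probabilities
#' `p_{j|i} = exp(-d_ij^2 / 2 sigma_i^2) / sum_k exp(-d_ik^2 / 2 sigma_i^2)`
#' are computed with the per-sample bandwidth `sigma_i` chosen by bisection
#' so that the Shannon entropy of the row equals `log2(perplexity)` (well
#' within `1e-5` bits). Rows are then symmetrized as
#' `p_ij = (p_{j|i} + p_{i|j}) / (2n)`, so all entries sum to one.
#'
#' @param D dissimilarities (`pare_dist`, `dist`, or square matrix).
#' @param perplexity effective neighborhood size, `1 < perplexity < n`.
#' @return An object of class `pare_affinity` with `values` (symmetric,
#'   zero diagonal, summing to 1), `kind = "tsne_p"`, and `bandwidths`
#'   (the per-sample `sigma_i`).
#' @export
tsne_affinities <- function(D, perplexity) {
  v <- .dist_values(D)
  n <- nrow(v)
  if (!(perplexity > 1 && perplexity < n))
    stop("perplexity must satisfy 1 < perplexity < n", call. = FALSE)
  P <- matrix(0, n, n)
  beta <- numeric(n)
  ids <- if (inherits(D, "pare_dist")) D$sample_ids else .default_ids(n, rownames(v))
  for (i in seq_len(n)) {
    d2 <- v[i, -i]^2
    cal <- .calibrate_gaussian(d2, perplexity)
    if (!cal$converged)
      stop("perplexity ", perplexity, " is infeasible for sample '", ids[i],
           "' (entropy range collapsed, e.g. duplicated points)", call. = FALSE)
    P[i, -i] <- cal$p
    beta[i] <- cal$beta
  }
  V <- (P + t(P)) / (2 * n)
  diag(V) <- 0
  dimnames(V) <- list(ids, ids)
  structure(list(values = V, kind = "tsne_p",
                 bandwidths = list(sigma = sqrt(1 / (2 * beta))),
                 perplexity = perplexity, sample_ids = ids),
            class = "pare_affinity")
}

#' Locally adaptive exponential affinities (UMAP input similarities)
#'
#' For each sample `i`, `rho_i` is the dissimilarity to its nearest
#' neighbor (ties broken by index order) and
#' `v_{j|i} = exp(-(d_ij - rho_i) / tau_i)` over the `n_neighbors` nearest
#' neighbors (zero elsewhere), with `tau_i` calibrated by bisection so the
#' sum of `v_{j|i}` over those neighbors equals `log2(n_neighbors)` — the
#' standard smooth-kNN calibration. The matrix is symmetrized by the fuzzy
#' union `v_ij = v_{j|i} + v_{i|j} - v_{j|i} v_{i|j}`.
#'
#' When `input = "gram"` the entries of a covariate-adjusted Gram matrix
#' are plugged directly into the kernel in place of dissimilarities. This
#' literal form is provided for completeness only: Gram entries are inner
#' products (possibly negative, nonzero diagonal), and the canonical route
#' is to convert the adjusted Gram matrix to distances with
#' [adjusted_distances()] first.
#'
#' @param D dissimilarities (`pare_dist`, `dist`, square matrix), or with
#'   `input = "gram"` a `pare_gram` / symmetric matrix.
#' @param n_neighbors neighborhood size, `1 <= n_neighbors < n`.
#' @param input `"distances"` (default) or `"gram"` (literal kernel on
#'   Gram entries).
#' @return An object of class `pare_affinity` with `values` (symmetric,
#'   in `[0, 1]`, zero diagonal), `kind = "umap_v"`, and `bandwidths`
#'   (`rho`, `tau`).
#' @export
umap_affinities <- function(D, n_neighbors, input = c("distances", "gram")) {
  input <- match.arg(input)
  v <- if (input == "gram") .gram_values(D) else .dist_values(D)
  n <- nrow(v)
  k <- as.integer(n_neighbors)
  if (!(k >= 1 && k < n))
    stop("n_neighbors must satisfy 1 <= n_neighbors < n", call. = FALSE)
  ids <- if (inherits(D, c("pare_dist", "pare_gram"))) D$sample_ids
         else .default_ids(n, rownames(v))
  Vc <- matrix(0, n, n)
  rho <- numeric(n)
  tau <- numeric(n)
  target <- log2(k)  # only read when k >= 2; k = 1 short-circuits below
  for (i in seq_len(n)) {
    d <- v[i, ]
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[others])]  # order() breaks ties by index
    nb <- ord[seq_len(k)]
    rho[i] <- d[nb[1]]
    excess <- pmax(d[nb] - rho[i], 0)
    if (all(excess == 0) || k == 1) {
      tau[i] <- 0
      Vc[i, nb] <- as.numeric(excess == 0)
    } else {
      lo <- 0
      hi <- max(excess)
      # row sum increases with tau; expand hi until it brackets the target
      while (sum(exp(-excess / hi)) < target) hi <- hi * 2
      for (iter in 1:100) {
        mid <- (lo + hi) / 2
        s <- if (mid == 0) sum(excess == 0) else sum(exp(-excess / mid))
        if (abs(s - target) < 1e-6) break
        if (s > target) hi <- mid else lo <- mid
      }
      tau[i] <- mid
      Vc[i, nb] <- if (mid == 0) as.numeric(excess == 0) else exp(-excess / mid)
    }
  }
  V <- Vc + t(Vc) - Vc * t(Vc)
  diag(V) <- 0
  dimnames(V) <- list(ids, ids)
  structure(list(values = V, kind = "umap_v",
                 bandwidths = list(rho = rho, tau = tau),
                 n_neighbors = k, sample_ids = ids),
            class = "pare_affinity")
}

#' @export
print.pare_affinity <- function(x, ...) {
  cat(sprintf("Affinity matrix (%s): %d samples\n", x$kind, nrow(x$values)))
  invisible(x)
}
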