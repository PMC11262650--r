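# Partial embeddings: run any registered distance-based embedder on
# covariate-adjusted coordinates (Euclidean route) or covariate-adjusted
# distances (general route).

#' Embedding specification
#'
#' Collects the parameters handed to an embedder. Defaults follow common
#' practice for exploratory biology: perplexity 10 for t-SNE, 15 nearest
#' neighbors for UMAP, two output dimensions, and a fixed seed so runs are
#' reproducible.
#'
#' @param method name of a registered embedder (`"tsne"`, `"umap"`,
#'   `"pcoa"`, or one added via [register_embedder()]).
#' @param perplexity t-SNE perplexity (must be `< n`).
#' @param n_neighbors UMAP neighborhood size (must be `< n`).
#' @param output_dim embedding dimension, default 2.
#' @param seed integer seed controlling all randomness in the embedder.
#' @param n_coords optional cap on the number of (adjusted) principal
#'   coordinates handed to the embedder; `NULL` keeps all.
#' @param truncate_before_adjust if `TRUE`, keep the top `n_coords`
#'   principal coordinates first and residualize those; the default
#'   residualizes the full set and then truncates.
#' @return An object of class `pare_spec`.
#' @export
embedding_spec <- function(method = "umap", perplexity = 10, n_neighbors = 15L,
                           output_dim = 2L, seed = 0L, n_coords = NULL,
                           truncate_before_adjust = FALSE) {
  stopifnot(perplexity > 0, n_neighbors >= 1, output_dim >= 1)
  if (!is.null(n_coords)) stopifnot(n_coords >= 1)
  structure(list(method = method, perplexity = perplexity,
                 n_neighbors = as.integer(n_neighbors),
                 output_dim = as.integer(output_dim), seed = as.integer(seed),
                 n_coords = if (is.null(n_coords)) NULL else as.integer(n_coords),
                 truncate_before_adjust = isTRUE(truncate_before_adjust)),
            class = "pare_spec")
}

#' Register a dimension-reduction backend
#'
#' An embedder is a function `fn(input, spec)` returning an
#' `n x output_dim` numeric matrix. `input` is a list with exactly one of
#' `coords` (an `n x k` coordinate matrix) or `distances` (an `n x n`
#' dissimilarity matrix) non-`NULL`; `spec` is an [embedding_spec()]. The
#' function must honor `spec$seed` for any internal randomness.
#'
#' @param name embedder name used in `embedding_spec(method = )`.
#' @param fn the backend function.
#' @param supports which input forms the backend accepts; used to give an
#'   informative error when a coordinate-only method is requested with
#'   precomputed dissimilarities.
#' @param overwrite replace an existing registration?
#' @return Invisibly, `name`.
#' @export
register_embedder <- function(name, fn, supports = c("coords", "distances"),
                              overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  supports <- match.arg(supports, several.ok = TRUE)
  if (!overwrite && exists(name, envir = .pare_registry$embedders, inherits = FALSE))
    stop("embedder '", name, "' is already registered", call. = FALSE)
  assign(name, list(fn = fn, supports = supports),
         envir = .pare_registry$embedders)
  invisible(name)
}

#' List registered embedders
#' @return Character vector of embedder names.
#' @export
list_embedders <- function() sort(ls(.pare_registry$embedders))

.get_embedder <- function(name) {
  if (!exists(name, envir = .pare_registry$embedders, inherits = FALSE))
    stop("unknown embedding method '", name, "'; see list_embedders()",
         call. = FALSE)
  get(name, envir = .pare_registry$embedders, inherits = FALSE)
}

.register_builtin_embedders <- function() {
  .pare_registry$embedders <- new.env(parent = emptyenv())

  register_embedder("tsne", function(input, spec) {
    set.seed(spec$seed)
    if (!is.null(input$coords)) {
      fit <- Rtsne::Rtsne(input$coords, dims = spec$output_dim,
                          perplexity = spec$perplexity, pca = FALSE,
                          check_duplicates = FALSE, num_threads = 1)
    } else {
      fit <- Rtsne::Rtsne(input$distances, is_distance = TRUE,
                          dims = spec$output_dim, perplexity = spec$perplexity,
                          num_threads = 1)
    }
    fit$Y
  })

  register_embedder("umap", function(input, spec) {
    set.seed(spec$seed)
    x <- if (!is.null(input$coords)) input$coords else stats::as.dist(input$distances)
    uwot::umap(x, n_neighbors = spec$n_neighbors,
               n_components = spec$output_dim,
               n_threads = 1, n_sgd_threads = 0)
  })

  # deterministic reference embedder: top principal coordinates
  register_embedder("pcoa", function(input, spec) {
    if (!is.null(input$coords)) {
      D <- pairwise_distances(input$coords)
    } else {
      D <- as_dissimilarity(input$distances)
    }
    Z <- principal_coordinates(double_center(D), k = spec$output_dim)
    Z$coords
  })
}

# resolve x into either a feature matrix or a dissimilarity object
.resolve_input <- function(x) {
  if (inherits(x, "pare_dist")) return(list(kind = "dist", D = x))
  if (inherits(x, "dist")) return(list(kind = "dist", D = as_dissimilarity(x)))
  list(kind = "features", data = as.matrix(x))
}

#' Partial embedding: confounder-adjusted dimension reduction
#'
#' Runs a distance-based embedder on covariate-adjusted geometry. With a
#' feature matrix (the Euclidean route): principal coordinates `Z` are
#' computed from the Euclidean distance matrix, residualized against the
#' nuisance design to `E = (I - H) Z`, optionally truncated to
#' `spec$n_coords` columns, and `E` is handed to the embedder as input
#' data. With precomputed dissimilarities (the general route): the
#' covariate-adjusted matrix `Delta = (I - H) G (I - H)` is converted to
#' genuine distances via [adjusted_distances()] and the embedder is run in
#' precomputed-distance mode. With `design = NULL` the result is the
#' ordinary, unadjusted embedding.
#'
#' Both routes produce the same embedder input when the original
#' dissimilarities are Euclidean, since the principal coordinates preserve
#' pairwise distances exactly.
#'
#' @param x numeric feature matrix (samples in rows), or precomputed
#'   dissimilarities as a `pare_dist` / [stats::dist] object.
#' @param design a `pare_design` from [build_design()], or `NULL` for no
#'   adjustment.
#' @param spec an [embedding_spec()].
#' @return An object of class `pare_embedding`: `coords`
#'   (`n x output_dim`), `spec`, `adjusted_for` (covariate names, empty if
#'   unadjusted), `sample_ids`, `eigenvalues` and
#'   `n_dropped_nonpositive` of the principal-coordinate step, and
#'   `embedder_input` (list with `coords` or `distances`, exactly what the
#'   backend received — useful for testing and auditing).
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_per_cell = 10, n_features = 20))
#' des <- build_design(sim$metadata, "batch")
#' emb <- pare_embed(sim$features, des, embedding_spec(method = "pcoa"))
#' head(emb$coords)
#' @export
pare_embed <- function(x, design = NULL, spec = embedding_spec()) {
  input <- .resolve_input(x)
  backend <- .get_embedder(spec$method)
  H <- if (!is.null(design)) hat_matrix(design) else NULL
  adjusted_for <- if (!is.null(design)) design$covariates else character(0)

  if (input$kind == "features") {
    D <- pairwise_distances(input$data)
    G <- double_center(D)
    n <- nrow(G$values)
    if (!is.null(spec$n_coords) && spec$truncate_before_adjust) {
      Z <- principal_coordinates(G, k = spec$n_coords)
    } else {
      Z <- principal_coordinates(G)
    }
    if (!is.null(spec$n_coords) && spec$n_coords > ncol(Z$coords) &&
        !spec$truncate_before_adjust)
      spec$n_coords <- ncol(Z$coords)
    E <- if (!is.null(H)) adjust_coordinates(Z, H)$coords else Z$coords
    if (!is.null(spec$n_coords) && !spec$truncate_before_adjust)
      E <- E[, seq_len(min(spec$n_coords, ncol(E))), drop = FALSE]
    emb_input <- list(coords = E, distances = NULL)
    eigenvalues <- Z$eigenvalues
    n_dropped <- Z$n_dropped_nonpositive
    ids <- Z$sample_ids
  } else {
    if (!is.null(spec$n_coords))
      stop("n_coords applies to the Euclidean (feature-matrix) route; ",
           "with precomputed dissimilarities pass coordinates instead",
           call. = FALSE)
    D <- input$D
    G <- double_center(D)
    if (!is.null(H)) {
      Delta <- adjusted_gram(G, H)
      Dt <- adjusted_distances(Delta)
    } else {
      Dt <- D
    }
    if (!("distances" %in% backend$supports))
      stop("method '", spec$method, "' does not support precomputed ",
           "dissimilarities; supply a feature matrix instead", call. = FALSE)
    emb_input <- list(coords = NULL, distances = Dt$values)
    eigenvalues <- NULL
    n_dropped <- NA_integer_
    ids <- D$sample_ids
  }

  n <- length(ids)
  if (spec$method == "tsne" && 3 * spec$perplexity > n - 1)
    stop("perplexity ", spec$perplexity, " too large for n = ", n, call. = FALSE)
  if (spec$n_neighbors >= n && spec$method == "umap")
    stop("n_neighbors must be < n", call. = FALSE)

  coords <- backend$fn(emb_input, spec)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || any(!is.finite(coords)))
    stop("embedder '", spec$method, "' returned an invalid coordinate matrix",
         call. = FALSE)
  dimnames(coords) <- list(ids, sprintf("dim%d", seq_len(ncol(coords))))
  structure(list(coords = coords, spec = spec, adjusted_for = adjusted_for,
                 sample_ids = ids, eigenvalues = eigenvalues,
                 n_dropped_nonpositive = n_dropped,
                 embedder_input = emb_input),
            class = "pare_embedding")
}

#' @export
print.pare_embedding <- function(x, ...) {
  adj <- if (length(x$adjusted_for))
    paste("adjusted for", paste(x$adjusted_for, collapse = ", "))
  else "unadjusted"
  cat(sprintf("Partial embedding (%s, %s): %d samples x %d dims, seed %d\n",
              x$spec$method, adj, nrow(x$coords), ncol(x$coords), x$spec$seed))
  invisible(x)
}
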