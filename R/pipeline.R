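# End-to-end orchestration: read inputs, adjust, embed, score, write.

#' Pipeline configuration
#'
#' @param features feature matrix, `pare_synth` dataset, or a file path
#'   accepted by [read_features()].
#' @param metadata data frame or file path; must carry `sample_id`.
#' @param adjust character vector of nuisance covariates (empty = no
#'   adjustment).
#' @param covariate_types optional named type overrides, as in
#'   [build_design()].
#' @param method,perplexity,n_neighbors,output_dim,seed,n_coords passed to
#'   [embedding_spec()].
#' @param metrics list of metric requests, each a list with `label`
#'   (metadata column), `metric` (`"lisi"` or `"silhouette"`), optional
#'   `perplexity` vector (LISI), optional `label_role`.
#' @param baseline also compute the unadjusted embedding side by side?
#' @param out_dir output directory.
#' @return An object of class `pare_run_config`.
#' @export
run_config <- function(features, metadata, adjust = character(0),
                       covariate_types = NULL, method = "umap",
                       perplexity = 10, n_neighbors = 15L, output_dim = 2L,
                       seed = 0L, n_coords = NULL, metrics = list(),
                       baseline = TRUE, out_dir = ".") {
  structure(list(features = features, metadata = metadata, adjust = adjust,
                 covariate_types = covariate_types, method = method,
                 perplexity = perplexity, n_neighbors = n_neighbors,
                 output_dim = output_dim, seed = seed, n_coords = n_coords,
                 metrics = metrics, baseline = baseline, out_dir = out_dir),
            class = "pare_run_config")
}

.load_features <- function(x) {
  if (inherits(x, "pare_synth")) return(x$features)
  if (is.character(x)) return(read_features(x))
  as.matrix(x)
}

.load_metadata <- function(x, features) {
  if (inherits(x, "pare_synth")) x <- x$metadata
  if (is.character(x)) return(read_metadata(x, features))
  md <- as.data.frame(x)
  if (!("sample_id" %in% names(md)))
    md$sample_id <- rownames(features)
  md$sample_id <- as.character(md$sample_id)
  miss <- setdiff(rownames(features), md$sample_id)
  if (length(miss))
    stop("metadata is missing sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  md[match(rownames(features), md$sample_id), , drop = FALSE]
}

#' Run the full partial-embedding pipeline
#'
#' Reads (or takes) the feature matrix and metadata, builds the nuisance
#' design, computes the adjusted embedding (and optionally the unadjusted
#' baseline with identical sample ordering), evaluates any requested
#' metrics on each embedding, and writes: one CSV per embedding with JSON
#' sidecars, a `metrics.json`, and a `manifest.json` recording the seed,
#' spec, covariates, data size, eigenvalue summary and software versions.
#' All randomness flows from the single configured seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the embeddings, metric reports, manifest
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pare_run_config"))
  features <- .load_features(config$features)
  md <- .load_metadata(config$metadata, features)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- embedding_spec(method = config$method,
                         perplexity = config$perplexity,
                         n_neighbors = config$n_neighbors,
                         output_dim = config$output_dim, seed = config$seed,
                         n_coords = config$n_coords)
  design <- if (length(config$adjust))
    build_design(md, config$adjust, config$covariate_types) else NULL

  embeddings <- list()
  if (!is.null(design)) embeddings$adjusted <- pare_embed(features, design, spec)
  if (config$baseline || is.null(design))
    embeddings$unadjusted <- pare_embed(features, NULL, spec)

  paths <- list()
  for (nm in names(embeddings)) {
    p <- file.path(config$out_dir,
                   sprintf("embedding_%s_%s.csv", config$method, nm))
    write_embedding(embeddings[[nm]], p)
    paths[[nm]] <- p
  }

  metric_out <- list()
  for (req in config$metrics) {
    lab <- md[[req$label]]
    if (is.null(lab)) stop("metric label '", req$label,
                           "' not in metadata", call. = FALSE)
    role <- if (is.null(req$label_role)) "none" else req$label_role
    for (nm in names(embeddings)) {
      key <- paste(req$metric, req$label, nm, sep = ".")
      if (req$metric == "lisi") {
        perp <- if (is.null(req$perplexity)) 30 else req$perplexity
        for (p in perp) {
          r <- lisi(embeddings[[nm]], lab, perplexity = p,
                    label_name = req$label, label_role = role)
          metric_out[[paste0(key, ".perp", p)]] <-
            list(per_sample = r$per_sample, summary = as.list(r$summary),
                 perplexity = p, better = r$better)
        }
      } else if (req$metric == "silhouette") {
        r <- silhouette_width(embeddings[[nm]], lab, label_name = req$label,
                              label_role = role)
        metric_out[[key]] <- list(per_sample = r$per_sample,
                                  summary = as.list(r$summary),
                                  better = r$better)
      } else stop("unknown metric '", req$metric, "'", call. = FALSE)
    }
  }
  if (length(metric_out)) {
    paths$metrics <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(metric_out, paths$metrics, digits = NA,
                         auto_unbox = TRUE)
  }

  ref <- embeddings[[1]]
  manifest <- list(
    seed = config$seed,
    spec = unclass(spec),
    adjusted_for = config$adjust,
    n_samples = nrow(features),
    n_features = ncol(features),
    n_retained_coords = length(ref$eigenvalues),
    n_dropped_nonpositive = ref$n_dropped_nonpositive,
    eigenvalue_top = utils::head(ref$eigenvalues, 10),
    correction_constant = 0,
    versions = list(pare = as.character(utils::packageVersion("pare")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(list(embeddings = embeddings, metrics = metric_out,
                 manifest = manifest, paths = paths))
}
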