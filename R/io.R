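# Readers and writers: dense CSV/TSV feature matrices, MatrixMarket
# triplets with sidecar name files, metadata tables, precomputed
# dissimilarities, and embedding/metric outputs.

#' Read a feature matrix
#'
#' Dense CSV/TSV files must have a header row of feature names and sample
#' identifiers in the first column. MatrixMarket (`.mtx`) triplet files
#' are paired with two plain-text files of row (sample) and column
#' (feature) names, one per line, following the single-cell convention;
#' by default these are looked up next to the `.mtx` file as
#' `<stem>_rows.txt` and `<stem>_cols.txt`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"mtx"`.
#' @param row_names_file,col_names_file name-file paths for MatrixMarket
#'   input; defaults derived from `path`.
#' @return Numeric matrix with sample IDs as row names, in file order.
#' @export
read_features <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                          row_names_file = NULL, col_names_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(row_names_file)) row_names_file <- paste0(stem, "_rows.txt")
    if (is.null(col_names_file)) col_names_file <- paste0(stem, "_cols.txt")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names_file)
    cn <- readLines(col_names_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("name files do not match matrix dimensions", call. = FALSE)
    dimnames(m) <- list(rn, cn)
  } else {
    df <- if (format == "csv") utils::read.csv(path, check.names = FALSE)
          else utils::read.delim(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  m
}

#' Read a sample metadata table and align it to a feature matrix
#'
#' The table must contain a `sample_id` column. When `features` is given,
#' the metadata is reordered to match the feature-matrix row order
#' (alignment is by ID, never by position) and any mismatch in either
#' direction is an error listing the offending samples.
#'
#' @param path CSV/TSV file path.
#' @param features optional feature matrix whose row names define the
#'   sample order.
#' @return A data frame, one row per sample.
#' @export
read_metadata <- function(path, features = NULL) {
  ext <- tolower(tools::file_ext(path))
  md <- if (ext %in% c("tsv", "txt")) utils::read.delim(path, check.names = FALSE)
        else utils::read.csv(path, check.names = FALSE)
  if (!("sample_id" %in% names(md)))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  md$sample_id <- as.character(md$sample_id)
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!is.null(features)) {
    want <- rownames(features)
    miss <- setdiff(want, md$sample_id)
    if (length(miss))
      stop("metadata is missing sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    extra <- setdiff(md$sample_id, want)
    if (length(extra))
      stop("metadata has sample(s) absent from the feature matrix: ",
           paste(extra, collapse = ", "), call. = FALSE)
    md <- md[match(want, md$sample_id), , drop = FALSE]
    rownames(md) <- NULL
  }
  md
}

#' Read a precomputed dissimilarity matrix
#'
#' Square CSV/TSV with identical row and column identifiers in identical
#' order (first column = IDs, header = IDs).
#'
#' @param path file path.
#' @return A `pare_dist`.
#' @export
read_distances <- function(path) {
  m <- read_features(path)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("precomputed dissimilarity file must be square with matching ",
         "row and column IDs", call. = FALSE)
  as_dissimilarity(m, metric_name = "precomputed", sample_ids = rownames(m))
}

#' Write a synthetic dataset to disk
#'
#' Emits the feature matrix in both dense CSV and MatrixMarket triplet
#' form (with `_rows.txt` / `_cols.txt` name files), the metadata as CSV,
#' and the generating truth as JSON, so both readers can be exercised on
#' identical content.
#'
#' @param dataset a `pare_synth`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"features"`.
#' @return Invisibly, a named list of the paths written.
#' @export
write_dataset <- function(dataset, dir, name = "features") {
  stopifnot(inherits(dataset, "pare_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  y <- dataset$features
  paths <- list(
    csv = file.path(dir, paste0(name, ".csv")),
    mtx = file.path(dir, paste0(name, ".mtx")),
    rows = file.path(dir, paste0(name, "_rows.txt")),
    cols = file.path(dir, paste0(name, "_cols.txt")),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(data.frame(sample_id = rownames(y), y,
                              check.names = FALSE),
                   paths$csv, row.names = FALSE, quote = FALSE)
  Matrix::writeMM(Matrix::Matrix(y, sparse = TRUE), paths$mtx)
  writeLines(rownames(y), paths$rows)
  writeLines(colnames(y), paths$cols)
  utils::write.csv(dataset$metadata, paths$metadata, row.names = FALSE,
                   quote = FALSE)
  truth <- dataset$truth
  truth$interaction <- NULL  # arrays don't survive JSON faithfully; omit
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Write an embedding with its JSON sidecar
#'
#' The CSV holds `sample_id` plus one column per embedding dimension; the
#' sidecar (`<path>.json`) records the spec, the adjusted covariates, the
#' eigenvalue spectrum and the dropped-eigenvalue count, enough to audit
#' or reproduce the run.
#'
#' @param embedding a `pare_embedding`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar?
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(embedding, path, sidecar = TRUE) {
  stopifnot(inherits(embedding, "pare_embedding"))
  df <- data.frame(sample_id = embedding$sample_ids, embedding$coords,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(spec = unclass(embedding$spec),
                 adjusted_for = embedding$adjusted_for,
                 eigenvalues = embedding$eigenvalues,
                 n_dropped_nonpositive = embedding$n_dropped_nonpositive,
                 package_version = as.character(utils::packageVersion("pare")))
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}
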