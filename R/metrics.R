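# Embedding-quality metrics: the local inverse Simpson's index (LISI) and
# silhouette widths, with the median / 2.5% / 97.5% quantile summaries used
# to compare adjusted and unadjusted embeddings.

.metric_report <- function(per_sample, metric, label_name, parameters = NULL,
                           label_role = "none", n_categories = NA_integer_) {
  qs <- stats::quantile(per_sample, c(0.5, 0.025, 0.975), names = FALSE)
  better <- switch(label_role,
    integration = if (metric == "lisi") "higher" else "lower",
    separation  = if (metric == "lisi") "lower" else "higher",
    "unspecified")
  structure(list(per_sample = per_sample, metric = metric,
                 label_name = label_name,
                 summary = c(median = qs[1], quantile_2.5 = qs[2],
                             quantile_97.5 = qs[3]),
                 parameters = parameters, label_role = label_role,
                 better = better, n_categories = n_categories),
            class = "pare_metric_report")
}

#' @export
print.pare_metric_report <- function(x, ...) {
  cat(sprintf("%s for label '%s' (%d categories)\n",
              toupper(x$metric), x$label_name, x$n_categories))
  cat(sprintf("  median %.4f  [2.5%%: %.4f, 97.5%%: %.4f]\n",
              x$summary["median"], x$summary["quantile_2.5"],
              x$summary["quantile_97.5"]))
  if (x$better != "unspecified")
    cat(sprintf("  %s is better (%s label)\n", x$better, x$label_role))
  invisible(x)
}

.check_labels <- function(labels, n) {
  f <- factor(labels)
  if (length(f) != n)
    stop("labels must have one entry per sample", call. = FALSE)
  if (any(is.na(f))) stop("labels contain missing values", call. = FALSE)
  f
}

#' Local inverse Simpson's index
#'
#' For each sample, neighbor weights over all other samples are
#' Gaussian-calibrated to the given perplexity (same bisection contract as
#' [tsne_affinities()]), summed into per-category probabilities `p_c`
#' (self excluded), and the index is `1 / sum_c p_c^2` — the effective
#' number of categories in the sample's local neighborhood. Values range
#' from 1 (a pure neighborhood) to the number of categories (perfect
#' mixing). For a nuisance label such as batch, higher values mean better
#' integration; for a biological label, lower values mean better
#' separation.
#'
#' @param embedding `n x d` coordinate matrix (or a `pare_embedding`).
#' @param labels per-sample categorical labels.
#' @param perplexity neighborhood size for the Gaussian calibration,
#'   `1 < perplexity < n`; default 30.
#' @param label_name name recorded in the report.
#' @param label_role `"integration"` if the label should mix (batch,
#'   site), `"separation"` if it should separate (cell type, diagnosis);
#'   controls the direction annotation in the report.
#' @return A `pare_metric_report` with per-sample values and the
#'   median / 2.5% / 97.5% quantile summary.
#' @export
lisi <- function(embedding, labels, perplexity = 30,
                 label_name = deparse(substitute(labels)),
                 label_role = c("none", "integration", "separation")) {
  label_role <- match.arg(label_role)
  coords <- if (inherits(embedding, "pare_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  f <- .check_labels(labels, n)
  if (nlevels(f) == 1) {
    return(.metric_report(rep(1, n), "lisi", label_name,
                          parameters = list(perplexity = perplexity),
                          label_role = label_role, n_categories = 1L))
  }
  if (!(perplexity > 1 && perplexity < n))
    stop("perplexity must satisfy 1 < perplexity < n", call. = FALSE)
  d2 <- as.matrix(stats::dist(coords))^2
  vals <- numeric(n)
  for (i in seq_len(n)) {
    cal <- .calibrate_gaussian(d2[i, -i], perplexity)
    p_c <- vapply(split(cal$p, f[-i]), sum, numeric(1))
    vals[i] <- 1 / sum(p_c^2)
  }
  .metric_report(vals, "lisi", label_name,
                 parameters = list(perplexity = perplexity),
                 label_role = label_role, n_categories = nlevels(f))
}

#' LISI across a range of perplexities
#'
#' Recomputes [lisi()] for each perplexity, capturing neighborhood sizes
#' from local to global.
#'
#' @inheritParams lisi
#' @param perplexities numeric vector of perplexity values.
#' @return A data frame with one row per perplexity (`perplexity`,
#'   `median`, `quantile_2.5`, `quantile_97.5`); the full reports are
#'   attached as the `"reports"` attribute.
#' @export
lisi_sweep <- function(embedding, labels, perplexities = c(10, 30, 100),
                       label_name = deparse(substitute(labels)),
                       label_role = c("none", "integration", "separation")) {
  label_role <- match.arg(label_role)
  reports <- lapply(perplexities, function(p)
    lisi(embedding, labels, perplexity = p, label_name = label_name,
         label_role = label_role))
  out <- data.frame(perplexity = perplexities,
                    t(vapply(reports, function(r) r$summary, numeric(3))))
  names(out) <- c("perplexity", "median", "quantile_2.5", "quantile_97.5")
  attr(out, "reports") <- reports
  out
}

#' Silhouette widths for a label vector
#'
#' Standard silhouette on Euclidean distances in the supplied coordinate
#' space: `a_i` is the mean distance to samples sharing `i`'s label
#' (excluding `i`), `b_i` the smallest mean distance to any other label,
#' and `s_i = (b_i - a_i) / max(a_i, b_i)`. Samples whose label has no
#' other member get `s_i = 0`. For a nuisance label, a median near zero
#' indicates good integration; for a biological label, a high median
#' indicates good separation.
#'
#' @inheritParams lisi
#' @return A `pare_metric_report` with per-sample silhouette widths in
#'   `[-1, 1]` and the quantile summary.
#' @export
silhouette_width <- function(embedding, labels,
                             label_name = deparse(substitute(labels)),
                             label_role = c("none", "integration", "separation")) {
  label_role <- match.arg(label_role)
  coords <- if (inherits(embedding, "pare_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  f <- .check_labels(labels, n)
  if (nlevels(f) < 2)
    stop("silhouette requires at least 2 categories", call. = FALSE)
  dmat <- as.matrix(stats::dist(coords))
  # mean distance from every sample to every category, computed blockwise
  sums <- vapply(levels(f), function(l) rowSums(dmat[, f == l, drop = FALSE]),
                 numeric(n))
  counts <- as.vector(table(f))
  vals <- numeric(n)
  for (i in seq_len(n)) {
    li <- as.integer(f[i])
    if (counts[li] == 1) { vals[i] <- 0; next }
    a <- sums[i, li] / (counts[li] - 1)
    b <- min((sums[i, -li]) / counts[-li])
    m <- max(a, b)
    vals[i] <- if (m > 0) (b - a) / m else 0
  }
  .metric_report(vals, "silhouette", label_name, label_role = label_role,
                 n_categories = nlevels(f))
}
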