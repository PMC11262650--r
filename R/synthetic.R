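# Synthetic datasets with known group, batch, and continuous-confounder
# structure: clustered group means, additive batch shifts, and Gaussian
# noise, so the adjustment machinery can be validated against ground truth.

#' Configuration for the synthetic-data generator
#'
#' The generative model is
#' `y_i = mu_group(i) + gamma_batch(i) + beta * c_i + epsilon_i`, with the
#' group means `mu_g ~ N(0, group_effect^2 I)`, batch shifts
#' `gamma_b ~ N(0, batch_effect^2 I)`, confounder loadings
#' `beta ~ N(0, confounder_slope^2 I)`, a standard-normal per-sample
#' confounder `c_i`, and noise `epsilon_i ~ N(0, noise_sd^2 I)`. Group and
#' batch assignments are fully crossed (no group-by-batch interaction by
#' default, so linear residualization is exactly correct); the optional
#' `interaction_effect` adds cell-specific shifts to probe
#' misspecification.
#'
#' @param n_per_cell samples per (group x batch) cell.
#' @param n_groups number of biological groups.
#' @param n_batches number of nuisance batches.
#' @param n_features feature dimension.
#' @param group_effect scale of group mean separation.
#' @param batch_effect scale of additive batch shifts.
#' @param confounder_slope scale of the continuous-confounder loadings
#'   (0 disables the confounder term).
#' @param noise_sd residual standard deviation.
#' @param interaction_effect scale of group-by-batch interaction shifts
#'   (default 0: the additive model holds exactly).
#' @param seed integer seed; the dataset is fully determined by it.
#' @return An object of class `pare_synth_config`.
#' @export
synthetic_config <- function(n_per_cell = 30L, n_groups = 5L, n_batches = 4L,
                             n_features = 50L, group_effect = 1,
                             batch_effect = 1, confounder_slope = 0,
                             noise_sd = 1, interaction_effect = 0, seed = 0L) {
  stopifnot(n_per_cell >= 1, n_groups >= 1, n_batches >= 1, n_features >= 1,
            group_effect >= 0, batch_effect >= 0, confounder_slope >= 0,
            noise_sd >= 0, interaction_effect >= 0)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 n_groups = as.integer(n_groups),
                 n_batches = as.integer(n_batches),
                 n_features = as.integer(n_features),
                 group_effect = group_effect, batch_effect = batch_effect,
                 confounder_slope = confounder_slope, noise_sd = noise_sd,
                 interaction_effect = interaction_effect,
                 seed = as.integer(seed)),
            class = "pare_synth_config")
}

#' Named synthetic presets
#'
#' `"batchy"` is the standard demonstration condition used throughout the
#' package: 5 groups x 4 batches x 30 samples (n = 600), 50 features,
#' batch shifts three times the group separation
#' (`group_effect = 1`, `batch_effect = 3`, `noise_sd = 1`) — a strong
#' but realistic confounding regime where batch dominates the unadjusted
#' leading coordinates. `"clean"` is the same design with the batch
#' effect switched off.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("batchy", "clean"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
    batchy = synthetic_config(group_effect = 1, batch_effect = 3,
                              noise_sd = 1, seed = seed),
    clean  = synthetic_config(group_effect = 1, batch_effect = 0,
                              noise_sd = 1, seed = seed))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic dataset
#'
#' Draws features, metadata (`sample_id`, `group`, `batch`, `confounder`)
#' and the generating truth (`mu`, `gamma`, `beta`, per-sample confounder,
#' and noise-free components) from a [synthetic_config()]. Identical
#' configurations produce byte-identical datasets.
#'
#' @param config a [synthetic_config()] or [synthetic_preset()].
#' @return An object of class `pare_synth`: list with `features`
#'   (`n x n_features` matrix), `metadata` (data frame), `truth` (list of
#'   generating parameters), and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "pare_synth_config"))
  .with_seed(config$seed, {
    g <- config$n_groups; b <- config$n_batches; m <- config$n_features
    n <- config$n_per_cell * g * b
    grid <- expand.grid(rep_id = seq_len(config$n_per_cell),
                        group = seq_len(g), batch = seq_len(b))
    mu <- matrix(rnorm(g * m, sd = config$group_effect), g, m)
    gamma <- matrix(rnorm(b * m, sd = config$batch_effect), b, m)
    beta <- rnorm(m, sd = config$confounder_slope)
    inter <- if (config$interaction_effect > 0)
      array(rnorm(g * b * m, sd = config$interaction_effect), c(g, b, m))
    else NULL
    confounder <- rnorm(n)
    eps <- matrix(rnorm(n * m, sd = config$noise_sd), n, m)
    y <- mu[grid$group, , drop = FALSE] + gamma[grid$batch, , drop = FALSE] +
      outer(confounder, beta) + eps
    if (!is.null(inter))
      for (i in seq_len(n)) y[i, ] <- y[i, ] + inter[grid$group[i], grid$batch[i], ]
    ids <- sprintf("s%03d", seq_len(n))
    rownames(y) <- ids
    colnames(y) <- sprintf("f%d", seq_len(m))
    metadata <- data.frame(sample_id = ids,
                           group = factor(sprintf("g%d", grid$group)),
                           batch = factor(sprintf("b%d", grid$batch)),
                           confounder = confounder,
                           stringsAsFactors = FALSE)
    structure(list(features = y, metadata = metadata,
                   truth = list(mu = mu, gamma = gamma, beta = beta,
                                confounder = confounder,
                                group_idx = grid$group, batch_idx = grid$batch,
                                interaction = inter, noise = eps),
                   config = config),
              class = "pare_synth")
  })
}

#' Generate a count-flavored (scRNA-seq-like) synthetic dataset
#'
#' Poisson-log-normal counts with group-specific log-means and
#' batch-specific log-shifts, followed by library-size normalization and
#' a `log1p` transform — mimicking the shape of log-normalized single-cell
#' expression matrices. Defaults mirror a pooled pancreatic-cell setting
#' with 13 cell-type groups and 4 study batches (at desk scale).
#'
#' @param config a [synthetic_config()]; effects are on the log scale.
#' @return A `pare_synth` whose `features` are the log-normalized values;
#'   the raw counts are in `$counts` and the metadata `group` column plays
#'   the role of cell type.
#' @export
simulate_counts <- function(config = synthetic_config(
                              n_groups = 13L, n_batches = 4L, n_per_cell = 10L,
                              n_features = 150L, group_effect = 1,
                              batch_effect = 0.5, noise_sd = 0.3)) {
  stopifnot(inherits(config, "pare_synth_config"))
  .with_seed(config$seed + 1L, {
    g <- config$n_groups; b <- config$n_batches; m <- config$n_features
    n <- config$n_per_cell * g * b
    grid <- expand.grid(rep_id = seq_len(config$n_per_cell),
                        group = seq_len(g), batch = seq_len(b))
    base <- rnorm(m, mean = 0.5, sd = 1)             # per-gene log baseline
    mu <- matrix(rnorm(g * m, sd = config$group_effect), g, m)
    gamma <- matrix(rnorm(b * m, sd = config$batch_effect), b, m)
    eps <- matrix(rnorm(n * m, sd = config$noise_sd), n, m)
    log_lambda <- sweep(mu[grid$group, , drop = FALSE] +
                          gamma[grid$batch, , drop = FALSE] + eps, 2, base, `+`)
    counts <- matrix(rpois(n * m, exp(log_lambda)), n, m)
    ids <- sprintf("c%04d", seq_len(n))
    dimnames(counts) <- list(ids, sprintf("gene%d", seq_len(m)))
    lib <- rowSums(counts)
    lib[lib == 0] <- 1
    sf <- lib / stats::median(lib)                   # size factors
    features <- log1p(counts / sf)
    metadata <- data.frame(sample_id = ids,
                           group = factor(sprintf("g%d", grid$group)),
                           batch = factor(sprintf("b%d", grid$batch)),
                           confounder = rep(0, n),
                           stringsAsFactors = FALSE)
    structure(list(features = features, counts = counts, metadata = metadata,
                   truth = list(base = base, mu = mu, gamma = gamma,
                                group_idx = grid$group, batch_idx = grid$batch,
                                size_factors = sf),
                   config = config),
              class = "pare_synth")
  })
}

#' @export
print.pare_synth <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d samples x %d features, %d groups x %d batches (seed %d)\n",
              nrow(x$features), ncol(x$features), x$config$n_groups,
              x$config$n_batches, x$config$seed))
  invisible(x)
}

#' Remove the generating nuisance terms from synthetic features
#'
#' Returns `y - gamma_batch - beta * c`, the batch- and confounder-free
#' version of a Gaussian synthetic dataset; the oracle against which
#' covariate adjustment is validated.
#'
#' @param dataset a `pare_synth` from [simulate_dataset()].
#' @return Numeric matrix of the same shape as `dataset$features`.
#' @export
denoised_features <- function(dataset) {
  stopifnot(inherits(dataset, "pare_synth"))
  tr <- dataset$truth
  if (is.null(tr$gamma) || is.null(tr$batch_idx))
    stop("dataset does not carry additive-truth components", call. = FALSE)
  out <- dataset$features - tr$gamma[tr$batch_idx, , drop = FALSE]
  if (!is.null(tr$beta)) out <- out - outer(tr$confounder, tr$beta)
  out
}
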