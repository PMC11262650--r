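# deterministic random fixtures shared across test files

rand_data <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("s%d", seq_len(n)), sprintf("f%d", seq_len(m))))
}

rand_metadata <- function(n, n_batches = 2, seed = 1) {
  set.seed(seed + 1000)
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             batch = factor(sample(sprintf("b%d", seq_len(n_batches)), n,
                                   replace = TRUE)),
             age = rnorm(n),
             stringsAsFactors = FALSE)
}

# balanced two-group / two-batch layout used by adjustment tests
crossed_metadata <- function(n_per_cell, n_groups = 2, n_batches = 2) {
  grid <- expand.grid(rep = seq_len(n_per_cell),
                      group = seq_len(n_groups), batch = seq_len(n_batches))
  data.frame(sample_id = sprintf("s%d", seq_len(nrow(grid))),
             group = factor(sprintf("g%d", grid$group)),
             batch = factor(sprintf("b%d", grid$batch)),
             stringsAsFactors = FALSE)
}

max_abs <- function(x) max(abs(x))
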