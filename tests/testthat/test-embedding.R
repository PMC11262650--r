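test_that("the embedder registry enforces its contract", {
  expect_true(all(c("tsne", "umap", "pcoa") %in% list_embedders()))
  expect_error(register_embedder("pcoa", function(input, spec) NULL),
               "already registered")
  expect_error(pare_embed(rand_data(10, 3), spec = embedding_spec(method = "nope")),
               "unknown embedding method")

  # a trivial registered embedder receives exactly the adjusted coordinates
  register_embedder("first2", function(input, spec)
    input$coords[, 1:2, drop = FALSE], supports = "coords", overwrite = TRUE)
  Y <- rand_data(15, 4, seed = 1)
  md <- rand_metadata(15, seed = 1)
  des <- build_design(md, "batch")
  emb <- pare_embed(Y, des, embedding_spec(method = "first2"))
  G <- double_center(pairwise_distances(Y))
  E <- adjust_coordinates(principal_coordinates(G), hat_matrix(des))
  expect_equal(unname(emb$coords), unname(E$coords[, 1:2]), tolerance = 1e-12)
  expect_equal(emb$adjusted_for, "batch")

  # coordinate-only embedders refuse precomputed dissimilarities
  expect_error(pare_embed(pairwise_distances(Y), des,
                          embedding_spec(method = "first2")),
               "does not support precomputed")
})

test_that("an empty design leaves the embedder input geometry unchanged", {
  Y <- rand_data(20, 5, seed = 2)
  D <- pairwise_distances(Y)
  # Euclidean route: distances among the input coordinates equal the originals
  emb <- pare_embed(Y, NULL, embedding_spec(method = "pcoa"))
  expect_lt(max_abs(as.matrix(dist(emb$embedder_input$coords)) - D$values), 1e-8)
  expect_equal(emb$adjusted_for, character(0))
  # general route: the distances handed over are the originals exactly
  emb2 <- pare_embed(D, NULL, embedding_spec(method = "pcoa"))
  expect_equal(emb2$embedder_input$distances, D$values)
})

test_that("additive batch shifts are annihilated in the embedder input", {
  md <- crossed_metadata(5, n_groups = 2, n_batches = 2)
  n <- nrow(md)
  set.seed(3)
  mu <- matrix(rnorm(2 * 10), 2)
  eps <- matrix(rnorm(n * 10), n)
  base <- mu[as.integer(md$group), ] + eps
  des <- build_design(md, "batch")
  spec <- embedding_spec(method = "pcoa")
  input_dist <- function(gamma_scale) {
    set.seed(99)  # same shift pattern at every scale
    gamma <- matrix(rnorm(2 * 10), 2) * gamma_scale
    y <- base + gamma[as.integer(md$batch), ]
    emb <- pare_embed(y, des, spec)
    as.matrix(dist(emb$embedder_input$coords))
  }
  d0 <- input_dist(0)
  d5 <- input_dist(5)
  d50 <- input_dist(50)
  expect_lt(max_abs(d5 - d0), 1e-6)
  expect_lt(max_abs(d50 - d0), 1e-6)
})

test_that("n_coords truncation behaves as documented", {
  Y <- rand_data(18, 6, seed = 4)
  md <- rand_metadata(18, seed = 4)
  des <- build_design(md, "batch")
  full <- pare_embed(Y, des, embedding_spec(method = "pcoa"))
  capped <- pare_embed(Y, des, embedding_spec(method = "pcoa", n_coords = 50))
  expect_equal(capped$embedder_input$coords, full$embedder_input$coords)

  k2 <- pare_embed(Y, des, embedding_spec(method = "pcoa", n_coords = 2))
  expect_equal(ncol(k2$embedder_input$coords), 2L)
  # default order: adjust the full set, then keep the top columns
  expect_equal(k2$embedder_input$coords, full$embedder_input$coords[, 1:2])

  before <- pare_embed(Y, des, embedding_spec(method = "pcoa", n_coords = 2,
                                              truncate_before_adjust = TRUE))
  Z2 <- principal_coordinates(double_center(pairwise_distances(Y)), k = 2)
  E2 <- adjust_coordinates(Z2, hat_matrix(des))
  expect_equal(before$embedder_input$coords, E2$coords, tolerance = 1e-12)
})

test_that("affinities agree between the coordinate and adjusted-distance routes", {
  for (seed in 1:3) {
    Y <- rand_data(30, 6, seed = seed)
    md <- rand_metadata(30, n_batches = 3, seed = seed)
    des <- build_design(md, "batch")
    G <- double_center(pairwise_distances(Y))
    H <- hat_matrix(des)
    E <- adjust_coordinates(principal_coordinates(G), H)
    Dt <- adjusted_distances(adjusted_gram(G, H))
    De <- pairwise_distances(E$coords)

    Pt <- tsne_affinities(Dt, perplexity = 8)
    Pe <- tsne_affinities(De, perplexity = 8)
    expect_lt(max_abs(Pt$values - Pe$values), 1e-8)

    Vt <- umap_affinities(Dt, n_neighbors = 6)
    Ve <- umap_affinities(De, n_neighbors = 6)
    expect_lt(max_abs(Vt$values - Ve$values), 1e-8)
  }
})

test_that("t-SNE and UMAP backends are deterministic under a fixed seed", {
  Y <- rand_data(60, 8, seed = 5)
  for (method in c("tsne", "umap")) {
    spec <- embedding_spec(method = method, perplexity = 8, n_neighbors = 10,
                           seed = 42)
    e1 <- pare_embed(Y, NULL, spec)
    e2 <- pare_embed(Y, NULL, spec)
    expect_identical(e1$coords, e2$coords)
    expect_true(all(is.finite(e1$coords)))
  }
})

test_that("spec feasibility checks fire", {
  Y <- rand_data(12, 3, seed = 6)
  expect_error(pare_embed(Y, NULL, embedding_spec(method = "tsne", perplexity = 10)),
               "perplexity")
  expect_error(pare_embed(pairwise_distances(Y), NULL,
                          embedding_spec(method = "pcoa", n_coords = 2)),
               "n_coords")
})
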