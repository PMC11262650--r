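test_that("build_design encodes covariates as documented", {
  md <- data.frame(sample_id = sprintf("s%d", 1:4),
                   batch = c("A", "A", "B", "B"), age = c(1, 2, 3, 4))
  X <- build_design(md, "batch")
  expect_equal(unname(X$values),
               cbind(rep(1, 4), c(0, 0, 1, 1)))
  expect_equal(X$column_names, c("(Intercept)", "batchB"))
  expect_equal(unname(X$encoding_map$batch["A"]), "(reference)")

  Xc <- build_design(md, "age")
  expect_equal(unname(Xc$values[, 2]), c(-1.5, -0.5, 0.5, 1.5))

  Xm <- build_design(md, c("batch", "age"))
  expect_equal(ncol(Xm$values), 3L)
})

test_that("build_design rejects degenerate specifications with named offenders", {
  md <- data.frame(sample_id = sprintf("s%d", 1:4),
                   batch = c("A", "A", "B", "B"),
                   donor = c("d1", "d1", "d2", "d2"),  # nested exactly in batch
                   const = c("x", "x", "x", "x"),
                   flat = c(2, 2, 2, 2),
                   age = c(1, NA, 3, 4))
  expect_error(build_design(md, c("batch", "donor")), "rank deficient")
  expect_error(build_design(md, c("batch", "donor")), "donor")
  expect_error(build_design(md, "const"), "single level")
  # constant continuous covariate centers to a zero column
  expect_error(build_design(md, "flat"), "rank deficient")
  expect_error(build_design(md, "age"), "s2")
  expect_error(build_design(md, "nope"), "not found")
})

test_that("hat_matrix is the textbook projector", {
  # intercept only: grand-mean averaging
  H1 <- hat_matrix(matrix(1, 4, 1))
  expect_equal(H1$values, matrix(0.25, 4, 4))

  # intercept + two-group indicator projects onto group means
  md <- data.frame(g = rep(c("a", "b"), times = c(3, 5)))
  H <- hat_matrix(build_design(md, "g"))
  set.seed(9)
  y <- rnorm(8)
  means <- ave(y, md$g)
  expect_equal(as.vector(H$values %*% y), means, tolerance = 1e-12)

  # trace == p, symmetric, idempotent for random designs
  for (seed in 1:3) {
    set.seed(seed)
    X <- cbind(1, matrix(rnorm(30 * 3), 30, 3))
    H <- hat_matrix(X)
    expect_equal(sum(diag(H$values)), ncol(X), tolerance = 1e-10)
    expect_lt(max_abs(H$values - t(H$values)), 1e-12)
    expect_lt(max_abs(H$values %*% H$values - H$values), 1e-10)
    expect_lt(max_abs(H$values %*% X - X), 1e-10)
  }
  expect_error(hat_matrix(cbind(1, c(1, 1), c(2, 2))), "rank deficient")
})

test_that("adjust_coordinates residualizes against the design", {
  Y <- rand_data(24, 6, seed = 7)
  md <- rand_metadata(24, n_batches = 3, seed = 7)
  Z <- principal_coordinates(double_center(pairwise_distances(Y)))

  # intercept-only adjustment is a no-op (PCoA coordinates are centered)
  E0 <- adjust_coordinates(Z, hat_matrix(matrix(1, 24, 1)))
  expect_equal(E0$coords, Z$coords, tolerance = 1e-10)

  # residuals orthogonal to the design
  des <- build_design(md, c("batch", "age"))
  E <- adjust_coordinates(Z, hat_matrix(des))
  expect_lt(max_abs(crossprod(des$values, E$coords)),
            1e-8 * sqrt(sum(Z$coords^2)))

  # pure additive group offset on one coordinate vanishes after adjustment
  g <- rep(c(0, 1), each = 6)
  Zoff <- cbind(rnorm(12), g * 5)
  Zoff <- scale(Zoff, scale = FALSE)
  H <- hat_matrix(build_design(data.frame(g = factor(g)), "g"))
  Eoff <- adjust_coordinates(Zoff, H)$coords
  # the offset coordinate lay entirely in the design space: residual is zero
  expect_lt(max_abs(Eoff[, 2]), 1e-10)

  # saturated design removes everything
  Eid <- adjust_coordinates(Z, structure(list(values = diag(24), rank = 24L),
                                         class = "pare_projection"))
  expect_lt(max_abs(Eid$coords), 1e-12)
})

test_that("adjusted_gram equals E E' and composes like a projection", {
  for (seed in 1:5) {
    Y <- rand_data(20 + seed, 5, seed = seed)
    n <- nrow(Y)
    md <- rand_metadata(n, n_batches = 2, seed = seed)
    md$sample_id <- rownames(Y)
    G <- double_center(pairwise_distances(Y))
    des <- build_design(md, "batch")
    H <- hat_matrix(des)
    Delta <- adjusted_gram(G, H)
    E <- adjust_coordinates(principal_coordinates(G), H)
    expect_lt(max_abs(Delta$values - tcrossprod(E$coords)), 1e-10)
    expect_true(Delta$is_adjusted)
  }

  # no projection / full projection
  Y <- rand_data(10, 3)
  G <- double_center(pairwise_distances(Y))
  Hzero <- structure(list(values = matrix(0, 10, 10), rank = 0L),
                     class = "pare_projection")
  expect_equal(adjusted_gram(G, Hzero)$values, G$values)
  Hid <- structure(list(values = diag(10), rank = 10L),
                   class = "pare_projection")
  expect_lt(max_abs(adjusted_gram(G, Hid)$values), 1e-12)

  # nesting: adjusting for S then S' >= S equals adjusting once for S'
  md <- rand_metadata(20, n_batches = 2, seed = 3)
  Z <- principal_coordinates(double_center(pairwise_distances(rand_data(20, 5, 3))))
  H_s <- hat_matrix(build_design(md, "batch"))
  H_sp <- hat_matrix(build_design(md, c("batch", "age")))
  two_step <- adjust_coordinates(adjust_coordinates(Z, H_s)$coords, H_sp)$coords
  one_step <- adjust_coordinates(Z, H_sp)$coords
  expect_lt(max_abs(two_step - one_step), 1e-10)
})

test_that("adjusted_distances converts the adjusted Gram matrix to distances on E", {
  Y <- rand_data(18, 4, seed = 4)
  md <- rand_metadata(18, seed = 4)
  G <- double_center(pairwise_distances(Y))
  H <- hat_matrix(build_design(md, "batch"))
  Delta <- adjusted_gram(G, H)
  E <- adjust_coordinates(principal_coordinates(G), H)
  Dt <- adjusted_distances(Delta)
  expect_lt(max_abs(Dt$values - as.matrix(dist(E$coords))), 1e-10)

  # unadjusted Gram matrix recovers the original distances
  D0 <- pairwise_distances(Y)
  expect_lt(max_abs(adjusted_distances(G)$values - D0$values), 1e-10)

  # zero matrix in, zero distances out
  Gz <- structure(list(values = matrix(0, 5, 5), is_adjusted = TRUE,
                       sample_ids = sprintf("s%d", 1:5)), class = "pare_gram")
  expect_equal(unname(adjusted_distances(Gz)$values), matrix(0, 5, 5))

  # indefinite input clamps with a warning
  bad <- G
  bad$values[1, 1] <- bad$values[1, 1] - 100
  expect_warning(adjusted_distances(bad), "clamped")
})
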