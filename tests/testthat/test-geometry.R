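test_that("pairwise_distances matches hand-computed cases and validates input", {
  # points on a line
  D <- pairwise_distances(matrix(c(0, 3, 4), ncol = 1))
  expect_equal(unname(D$values),
               matrix(c(0, 3, 4, 3, 0, 1, 4, 1, 0), 3), tolerance = 1e-12)
  # 3-4-5 triangle
  D2 <- pairwise_distances(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(D2$values[1, 2], 5)
  expect_equal(diag(D2$values), c(0, 0), ignore_attr = TRUE)

  expect_error(pairwise_distances(matrix(1:3, 1)), "at least 2 samples")
  bad <- matrix(rnorm(10), 5)
  bad[3, 1] <- NA
  expect_error(pairwise_distances(bad), "rows: 3")
  expect_error(pairwise_distances(rand_data(5, 2), metric = "nope"),
               "unknown metric")
})

test_that("registered custom metrics are used and validated as dissimilarities", {
  register_metric("halved_euclid", function(x, y) sqrt(sum((x - y)^2)) / 2,
                  overwrite = TRUE)
  Y <- rand_data(6, 3, seed = 5)
  D <- pairwise_distances(Y, metric = "halved_euclid")
  expect_equal(D$values, as.matrix(dist(Y)) / 2, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(register_metric("halved_euclid", identity), "already registered")
})

test_that("double_center reproduces inner products of centered data", {
  # identical points
  D0 <- as_dissimilarity(matrix(0, 3, 3))
  expect_equal(unname(double_center(D0)$values), matrix(0, 3, 3))

  # two points a unit apart: Gram matrix of centered coordinates {-0.5, 0.5}
  G2 <- double_center(as_dissimilarity(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(unname(G2$values),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2), tolerance = 1e-12)

  # Euclidean D from data: G == Yc Yc'
  Y <- rand_data(10, 4, seed = 2)
  Yc <- scale(Y, scale = FALSE)
  G <- double_center(pairwise_distances(Y))
  expect_equal(G$values, tcrossprod(Yc), ignore_attr = TRUE, tolerance = 1e-10)

  # rows and columns sum to zero; recentring an already-centered G is a no-op
  expect_lt(max_abs(rowSums(G$values)), 1e-9)
  n <- nrow(G$values)
  J <- diag(n) - matrix(1 / n, n, n)
  expect_equal(J %*% G$values %*% J, G$values, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("principal_coordinates recovers geometry from the Gram matrix", {
  # 1-D pair at {-0.5, 0.5}: single axis, eigenvalue 0.5
  G2 <- double_center(as_dissimilarity(matrix(c(0, 1, 1, 0), 2)))
  Z2 <- principal_coordinates(G2)
  expect_equal(Z2$eigenvalues, 0.5, tolerance = 1e-12)
  expect_equal(sort(Z2$coords[, 1]), c(-0.5, 0.5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(Z2$n_dropped_nonpositive, 1L)

  # distance preservation for Euclidean input, several sizes
  for (seed in 1:4) {
    Y <- rand_data(20, 5, seed = seed)
    D <- pairwise_distances(Y)
    Z <- principal_coordinates(double_center(D))
    expect_lt(max_abs(as.matrix(dist(Z$coords)) - D$values), 1e-8)
    # eigenvalues are squared column norms of Z
    expect_equal(colSums(Z$coords^2), Z$eigenvalues, ignore_attr = TRUE,
                 tolerance = 1e-10)
    # sign convention: largest-magnitude entry of each column positive
    expect_true(all(apply(Z$coords, 2, function(z) z[which.max(abs(z))] > 0)))
  }

  # truncation
  Zk <- principal_coordinates(double_center(pairwise_distances(rand_data(12, 6))), k = 3)
  expect_equal(ncol(Zk$coords), 3L)
  expect_true(all(diff(Zk$eigenvalues) <= 0))

  # constant data: all eigenvalues non-positive
  expect_warning(Z0 <- principal_coordinates(double_center(as_dissimilarity(matrix(0, 4, 4)))),
                 "non-positive")
  expect_equal(ncol(Z0$coords), 0L)
  expect_equal(Z0$n_dropped_nonpositive, 4L)
})

test_that("euclidify leaves Euclidean input unchanged and repairs non-Euclidean input", {
  D <- pairwise_distances(rand_data(15, 3, seed = 3))
  for (m in c("cailliez", "lingoes")) {
    De <- euclidify(D, method = m)
    expect_equal(De$values, D$values)
    expect_equal(De$correction$constant, 0)
  }
  # any 2x2 dissimilarity is Euclidean
  D22 <- as_dissimilarity(matrix(c(0, 7, 7, 0), 2))
  expect_equal(euclidify(D22)$correction$constant, 0)

  # break the triangle inequality
  v <- D$values
  v[1, 2] <- v[2, 1] <- v[1, 2] * 10
  Dbad <- as_dissimilarity(v)
  min_eig <- function(dd) min(eigen(double_center(dd)$values, symmetric = TRUE,
                                    only.values = TRUE)$values)
  expect_lt(min_eig(Dbad), -1e-6)
  for (m in c("cailliez", "lingoes")) {
    Dfix <- euclidify(Dbad, method = m)
    expect_gt(Dfix$correction$constant, 0)
    expect_gte(min_eig(Dfix), -1e-8 * max(Dfix$values))
    # corrected geometry supports real coordinates for all samples
    Z <- principal_coordinates(double_center(Dfix))
    expect_true(all(is.finite(Z$coords)))
  }
})

test_that("Cailliez constant agrees with the independent ape implementation", {
  skip_if_not_installed("ape")
  v <- pairwise_distances(rand_data(10, 3, seed = 11))$values
  v[1, 2] <- v[2, 1] <- v[1, 2] * 8
  ours <- euclidify(as_dissimilarity(v), method = "cailliez")$correction$constant
  note <- ape::pcoa(as.dist(v), correction = "cailliez")$note
  nums <- regmatches(note, gregexpr("[0-9]+\\.[0-9]+", note))[[1]]
  theirs <- as.numeric(nums[length(nums)])  # the note quotes the constant last
  expect_equal(ours, theirs, tolerance = 1e-9)
})
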