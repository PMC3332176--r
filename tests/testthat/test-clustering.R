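test_that("k-means separates obvious groupings and respects fixed points", {
  r <- kmeans_cluster(c(0, 0, 10, 10), 2)
  expect_equal(sort(as.numeric(r$centroids)), c(0, 10))
  expect_equal(r$assignment[1], r$assignment[2])
  expect_equal(r$assignment[3], r$assignment[4])
  expect_false(r$assignment[1] == r$assignment[3])

  r <- kmeans_cluster(c(1, 2, 3, 100), 2)
  expect_equal(sort(as.numeric(r$centroids)), c(2, 100))

  # initialization at the true means of a separated set is a fixed point
  x <- c(0, 1, 2, 10, 11, 12)
  r <- kmeans_cluster(x, 2, init_centroids = matrix(c(1, 11), 2))
  expect_equal(as.numeric(r$centroids), c(1, 11))
  expect_lte(r$iterations, 2L)
})

test_that("k-means input contracts are enforced", {
  expect_error(kmeans_cluster(1:3, 4), "exceeds the number of points")
  expect_error(kmeans_cluster(numeric(0), 1), "empty point set")
})

test_that("k-means from all distinct-pair starts attains the enumeration optimum", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    x <- round(runif(n, 0, 20), 2)
    pairs <- utils::combn(n, 2)
    best <- Inf
    for (j in seq_len(ncol(pairs))) {
      init <- matrix(x[pairs[, j]], 2)
      if (init[1] == init[2]) next
      best <- min(best, kmeans_cluster(x, 2, init_centroids = init)$withinss)
    }
    expect_equal(best, exhaustive_kmeans2(x), tolerance = 1e-9)
  }
})

test_that("fcm memberships follow the inverse-distance-ratio form", {
  u <- fcm_membership(0, matrix(c(-1, 1), 2), k = 2)
  expect_equal(as.numeric(u), c(0.5, 0.5))
  u <- fcm_membership(5, matrix(c(5, 0, 9), 3), k = 2)
  expect_equal(as.numeric(u), c(1, 0, 0))     # exact center hit
  u <- fcm_membership(matrix(c(0, 0), 1, 2),
                      matrix(c(1, -1, 0, 0, 0, 1), 3, 2), k = 2)
  expect_equal(u[, 1], rep(1 / 3, 3))         # equidistant from 3 centers
  # columns always sum to 1 and membership decays with distance
  set.seed(22)
  X <- matrix(rnorm(40), 20, 2)
  cen <- matrix(rnorm(6), 3, 2)
  u <- fcm_membership(X, cen, k = 1.7)
  expect_equal(colSums(u), rep(1, 20), tolerance = 1e-9)
})

test_that("fcm center update reduces to plain means for crisp memberships", {
  x <- c(0, 1, 9, 10)
  u_crisp <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(as.numeric(fcm_centers(x, u_crisp, k = 2)), c(0.5, 9.5))
  # uniform memberships collapse every center to the global mean
  u_unif <- matrix(1 / 3, 3, 4)
  expect_equal(as.numeric(fcm_centers(x, u_unif, k = 3)), rep(5, 3))
  expect_equal(as.numeric(fcm_centers(c(0, 2), diag(2), k = 2)), c(0, 2))
})

test_that("fcm objective is the exact weighted double sum", {
  expect_equal(fcm_objective(c(0, 2), matrix(1, 1, 2), matrix(1), k = 2), 2)
  expect_equal(fcm_objective(c(0, 2), diag(2), matrix(c(0, 2), 2), k = 2), 0)
  # doubling all distances quadruples E
  x <- c(0, 1, 3); cen <- matrix(c(0.5, 3), 2)
  u <- fcm_membership(x, cen, 2)
  expect_equal(fcm_objective(2 * x, u, 2 * cen, 2),
               4 * fcm_objective(x, u, cen, 2))
})

test_that("fcm recovers well-separated blobs and degenerates cleanly", {
  set.seed(23)
  x <- c(rnorm(60, 0, 0.3), rnorm(60, 10, 0.3))
  st <- fcm_cluster(x, 2)
  cen <- sort(as.numeric(st$centers))
  expect_lt(abs(cen[1] - mean(x[1:60])), 0.1)
  expect_lt(abs(cen[2] - mean(x[61:120])), 0.1)
  lab <- hard_labels(st$memberships)
  expect_equal(length(unique(lab[1:60])), 1L)
  expect_equal(length(unique(lab[61:120])), 1L)
  expect_false(lab[1] == lab[120])
  # C = 1 converges on the global mean
  st1 <- fcm_cluster(x, 1, k = 2)
  expect_equal(as.numeric(st1$centers), mean(x), tolerance = 1e-8)
})

test_that("fcm runs are deterministic and the objective never increases", {
  set.seed(24)
  x <- runif(200, 0, 255)
  a <- fcm_cluster(x, 3)
  b <- fcm_cluster(x, 3)
  expect_identical(a, b)
  expect_true(all(diff(a$objective_trace) <= 1e-9))
  expect_equal(colSums(a$memberships), rep(1, 200), tolerance = 1e-9)
})

test_that("fcm agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(25)
  x <- c(rnorm(40, 20, 2), rnorm(40, 80, 2))
  init <- matrix(c(30, 70), 2)
  mine <- fcm_cluster(x, 2, k = 2, init_centers = init, tol = 1e-10,
                      max_iter = 500L)
  ref <- e1071::cmeans(matrix(x), centers = matrix(init), m = 2,
                       iter.max = 500, method = "cmeans")
  expect_equal(sort(as.numeric(mine$centers)), sort(as.numeric(ref$centers)),
               tolerance = 1e-4)
  # reference objective computed directly from the reference fit
  ref_obj <- 0
  for (j in 1:2) ref_obj <- ref_obj +
    sum(ref$membership[, j]^2 * (x - ref$centers[j])^2)
  expect_equal(mine$objective, ref_obj, tolerance = 1e-6)
})
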