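test_that("the seed signature is the largest-norm pixel", {
  # a 1x1 cube has only one candidate
  one <- hsi_cube(array(c(1, 2), c(1, 1, 2)), c(500, 600))
  s1 <- select_signatures(one, 1)
  expect_equal(s1$values, matrix(c(1, 2), 1))
  expect_equal(unlist(s1$origin[1, c("row", "col")], use.names = FALSE), c(1L, 1L))

  # zero pixel vs constant pixel: the larger norm wins
  v <- array(0, c(2, 1, 3))
  v[2, 1, ] <- 0.7
  cube <- hsi_cube(v, c(1, 2, 3) * 100)
  sel <- select_signatures(cube, 1)
  expect_equal(drop(sel$values), rep(0.7, 3))

  # first-signature maximality over random cubes
  for (seed in 1:5) {
    cube <- rand_cube(8, 7, 4, seed = seed)
    sel <- select_signatures(cube, 4)
    m <- matrix(aperm(cube$values, c(2, 1, 3)), 56, 4)
    expect_gte(sum(sel$values[1, ]^2) + 1e-12, max(rowSums(m^2)))
  }
})

test_that("hierarchical selection matches the exhaustive brute-force oracle", {
  set.seed(42)
  for (trial in 1:20) {
    rows <- sample(2:9, 1)
    cols <- sample(2:9, 1)
    bands <- sample(2:6, 1)
    k <- sample(1:min(6, rows * cols), 1)
    rule <- sample(c("max_min", "max_sum"), 1)
    cube <- rand_cube(rows, cols, bands)
    sel <- select_signatures(cube, k, rule)
    orc <- oracle_select(cube, k, rule)
    expect_equal(unname(as.matrix(sel$origin[, c("row", "col")])), orc$rc,
                 info = sprintf("trial %d (%dx%dx%d, k=%d, %s)",
                                trial, rows, cols, bands, k, rule))
    expect_equal(sel$values, orc$values)
  }
})

test_that("selection ties break at the smallest (row, col) in row-major order", {
  # two identical maximal pixels; the earlier one in row-major order wins
  v <- array(0.1, c(3, 3, 2))
  v[2, 3, ] <- c(5, 5)
  v[3, 1, ] <- c(5, 5)
  cube <- hsi_cube(v, c(500, 600))
  sel <- select_signatures(cube, 1)
  expect_equal(unlist(sel$origin[1, c("row", "col")], use.names = FALSE), c(2L, 3L))
})

test_that("selection refuses to exceed the number of distinct spectra", {
  v <- array(0.2, c(2, 2, 3))
  v[1, 1, ] <- c(1, 2, 3)
  cube <- hsi_cube(v, c(1, 2, 3) * 100)  # 2 distinct spectra
  expect_error(select_signatures(cube, 3), "distinct")
  expect_equal(n_distinct <- nrow(select_signatures(cube, 2)$values), 2)
})

test_that("the minimum pairwise separation of selected signatures is non-increasing in k", {
  cube <- rand_cube(10, 10, 5, seed = 7)
  sel <- select_signatures(cube, 8, rule = "max_min")
  d2 <- as.matrix(dist(sel$values))^2
  min_sep <- vapply(2:8, function(k) {
    sub <- d2[1:k, 1:k]
    min(sub[upper.tri(sub)])
  }, numeric(1))
  expect_true(all(diff(min_sep) <= 1e-12))
})

test_that("unmixing recovers pure pixels and exact mixtures", {
  # two orthogonal signatures
  mu1 <- c(2, 0, 0, 0)
  mu2 <- c(0, 0, 3, 0)
  sigs <- signature_set(rbind(mu1, mu2))
  v <- array(0, c(1, 3, 4))
  v[1, 1, ] <- mu1                      # pure pixel 1
  v[1, 2, ] <- 0.3 * mu1 + 0.7 * mu2   # known mixture
  v[1, 3, ] <- mu2                      # pure pixel 2
  cube <- hsi_cube(v, (1:4) * 100)
  aff <- unmix_lmm(cube, sigs, constraint = "nonneg")
  expect_equal(aff$values[1, 1, ], c(1, 0), tolerance = 1e-6)
  expect_equal(aff$values[1, 2, ], c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(aff$values[1, 3, ], c(0, 1), tolerance = 1e-6)
  expect_lt(max(aff$residual), 1e-6)
})

test_that("noise-free synthesized cubes are reconstructed with matching abundances", {
  set.seed(8)
  for (constraint in c("nonneg", "nonneg_sum_to_one", "unconstrained")) {
    K <- 3
    B <- 6
    S <- matrix(runif(K * B, 0.1, 1), K, B)
    FF <- matrix(runif(30 * K), 30, K)
    if (constraint == "nonneg_sum_to_one") FF <- FF / rowSums(FF)
    X <- FF %*% S
    v <- aperm(array(t(X), c(B, 6, 5)), c(3, 2, 1))  # 5x6 pixels row-major
    m <- matrix(aperm(v, c(2, 1, 3)), 30, B)
    expect_equal(m, X)  # layout sanity
    cube <- hsi_cube(v, seq(400, by = 20, length.out = B))
    aff <- unmix_lmm(cube, signature_set(S), constraint = constraint)
    rec <- matrix(aff$values, 30 * 1, K)
    recovered <- cbind(as.vector(aff$values[, , 1]),
                       as.vector(aff$values[, , 2]),
                       as.vector(aff$values[, , 3]))
    truth <- cbind(matrix(FF[, 1], 5, 6, byrow = TRUE)[],
                   matrix(FF[, 2], 5, 6, byrow = TRUE)[],
                   matrix(FF[, 3], 5, 6, byrow = TRUE)[])
    expect_equal(as.vector(recovered), as.vector(truth), tolerance = 1e-4)
    expect_lt(max(aff$residual), 1e-6)
  }
})

test_that("sum-to-one abundances agree with a dense grid search over the simplex", {
  set.seed(9)
  K <- 3
  B <- 5
  S <- matrix(runif(K * B, 0.2, 1), K, B)
  cube <- rand_cube(6, 6, B)
  aff <- unmix_lmm(cube, signature_set(S), constraint = "nonneg_sum_to_one")

  # oracle: evaluate the residual at every grid point of the 2-simplex
  step <- 0.01
  g <- expand.grid(f1 = seq(0, 1, step), f2 = seq(0, 1, step))
  g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
  G <- cbind(g$f1, g$f2, 1 - g$f1 - g$f2)
  recon <- G %*% S                       # grid x bands
  m <- matrix(aperm(cube$values, c(2, 1, 3)), 36, B)
  for (p in seq_len(36)) {
    obj <- rowSums((recon - matrix(m[p, ], nrow(recon), B, byrow = TRUE))^2)
    best <- G[which.min(obj), ]
    rr <- (p - 1) %/% 6 + 1
    cc <- (p - 1) %% 6 + 1
    est <- aff$values[rr, cc, ]
    expect_equal(sum(est), 1, tolerance = 1e-6)
    expect_lt(max(abs(est - best)), 0.015)  # within grid resolution
  }
})

test_that("unconstrained unmixing flags rank deficiency and returns the least-norm solution", {
  S <- rbind(c(1, 0, 1), c(2, 0, 2), c(0, 1, 0))  # row 2 = 2 * row 1
  cube <- hsi_cube(array(runif(12, 0.1, 1), c(2, 2, 3)), c(1, 2, 3) * 100)
  expect_warning(aff <- unmix_lmm(cube, signature_set(S),
                                  constraint = "unconstrained"),
                 "rank-deficient")
  # least-norm solution still reconstructs within the column space
  FF <- cbind(as.vector(aff$values[, , 1]), as.vector(aff$values[, , 2]),
              as.vector(aff$values[, , 3]))
  expect_true(all(is.finite(FF)))
})

test_that("posteriors follow the stated softmax of negative squared distances", {
  # hand-computable instance: 4x4x3 cube, 2 signatures, sigma = 1
  set.seed(10)
  cube <- rand_cube(4, 4, 3)
  sigs <- select_signatures(cube, 2)
  post <- posterior_probabilities(cube, sigs, scale = 1)
  for (r in 1:4) for (cc in 1:4) {
    x <- cube$values[r, cc, ]
    d2 <- apply(sigs$values, 1, function(s) sum((x - s)^2))
    expected <- exp(-d2 / 2) / sum(exp(-d2 / 2))
    expect_equal(post$values[r, cc, ], expected, tolerance = 1e-12)
  }
})

test_that("posteriors normalize, are symmetric for equidistant pixels, and concentrate as sigma shrinks", {
  # pixel equidistant from K signatures -> 1/K each
  sigs <- signature_set(rbind(c(1, 0), c(0, 1)))
  v <- array(0, c(1, 1, 2))
  v[1, 1, ] <- c(0.5, 0.5)
  cube <- hsi_cube(v, c(500, 600))
  post <- posterior_probabilities(cube, sigs, scale = 1)
  expect_equal(post$values[1, 1, ], c(0.5, 0.5))

  # pixel equal to signature j -> posterior -> 1 as sigma -> 0
  v[1, 1, ] <- c(0, 1)
  post <- posterior_probabilities(hsi_cube(v, c(500, 600)), sigs,
                                  scale = 1e-3)
  expect_equal(post$values[1, 1, 2], 1, tolerance = 1e-12)

  # normalization within 1e-9 on a random instance
  cube <- rand_cube(6, 5, 4, seed = 11)
  post <- posterior_probabilities(cube, select_signatures(cube, 4))
  expect_true(all(abs(apply(post$values, c(1, 2), sum) - 1) < 1e-9))

  expect_error(posterior_probabilities(cube, select_signatures(cube, 3),
                                       scale = -1), "positive")
})

test_that("maximum-posterior assignment is invariant to the bandwidth sigma", {
  cube <- rand_cube(7, 6, 5, seed = 12)
  sigs <- select_signatures(cube, 4)
  maps <- lapply(c(0.1, 1, 10), function(s)
    assign_clusters(posterior_probabilities(cube, sigs, scale = s))$labels)
  expect_identical(maps[[1]], maps[[2]])
  expect_identical(maps[[2]], maps[[3]])
})

test_that("cluster assignment is the per-pixel argmax with lowest-label ties", {
  # strict maximum everywhere -> unique argmax
  set.seed(13)
  aff <- affinity_maps(array(runif(5 * 5 * 4), c(5, 5, 4)), "abundance")
  expect_identical(assign_clusters(aff)$labels, oracle_assign(aff$values))

  # all-equal affinities -> every pixel gets label 1
  flat <- affinity_maps(array(0.25, c(3, 3, 4)), "posterior")
  expect_true(all(assign_clusters(flat)$labels == 1L))

  # no pixel remains unclassified
  expect_true(all(assign_clusters(aff)$labels >= 1L))
})

test_that("cluster mean profiles equal the per-band means of their pixels", {
  cube <- rand_cube(6, 7, 4, seed = 14)

  # single label -> global per-band mean
  lab1 <- label_image(matrix(1L, 6, 7), n_classes = 1)
  prof <- cluster_mean_profiles(cube, lab1)
  expect_equal(drop(prof$values),
               apply(cube$values, 3, mean))

  # two pixels in a label -> (a + b) / 2
  labels <- matrix(1L, 6, 7)
  labels[2, 3] <- 2L
  labels[5, 1] <- 2L
  prof2 <- cluster_mean_profiles(cube, label_image(labels, n_classes = 2))
  expect_equal(prof2$values[2, ],
               (cube$values[2, 3, ] + cube$values[5, 1, ]) / 2)

  # random labeling matches the loop-based oracle; empty labels are omitted
  labels <- matrix(sample(c(1L, 2L, 4L), 42, replace = TRUE), 6, 7)
  li <- label_image(labels, n_classes = 5)
  expect_message(prof3 <- cluster_mean_profiles(cube, li), "omitting")
  orc <- oracle_cluster_means(cube, labels)
  expect_equal(prof3$origin$label, orc$labels)
  expect_equal(prof3$values, orc$means)

  expect_error(cluster_mean_profiles(cube, label_image(matrix(0L, 6, 7))),
               "nonempty")
})
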