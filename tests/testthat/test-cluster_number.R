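# validity indices and decision fusion

test_that("Dunn index matches hand computation and its invariances", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(dunn_index(X, lab), 9.9 / 0.1, tolerance = 1e-9)
  # scale invariance
  expect_equal(dunn_index(X * 37, lab), dunn_index(X, lab))
  # translation invariance
  expect_equal(dunn_index(X + 5, lab), dunn_index(X, lab))
  # identical clusters at the same location
  X0 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(dunn_index(X0, c(1, 1, 2, 2)), 0)
  # all-singleton clustering -> Inf sentinel
  expect_equal(dunn_index(matrix(1:3, ncol = 1), 1:3), Inf)
})

test_that("Calinski-Harabasz matches its definition and degenerates to Inf", {
  set.seed(10)
  X <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  # independent oracle: direct scatter computation
  grand <- colMeans(X)
  trW <- sum(sapply(1:3, function(k)
    sum(sweep(X[lab == k, ], 2, colMeans(X[lab == k, ]), "-")^2)))
  trB <- sum(sapply(1:3, function(k)
    10 * sum((colMeans(X[lab == k, ]) - grand)^2)))
  expect_equal(calinski_harabasz(X, lab), (trB / 2) / (trW / 27))

  # true labels beat permuted labels on separated blobs
  b <- three_blobs(15, seed = 2)
  set.seed(1)
  expect_gt(calinski_harabasz(b$X, b$labels),
            calinski_harabasz(b$X, sample(b$labels)))

  # W = 0 sentinel
  X0 <- matrix(c(0, 0, 10, 10), ncol = 1)
  expect_equal(calinski_harabasz(X0, c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(X, rep(1, 30)), "2 <= K")
})

test_that("gap statistic finds 1 for a single blob and 3 for three blobs", {
  # single tight Gaussian blob -> k = 1 in >= 90% of seeds
  ks <- vapply(1:10, function(i) {
    set.seed(300 + i)
    gap_statistic(matrix(rnorm(120), 60, 2), 1:6, B = 50,
                  seed = 400 + i)$k
  }, 0L)
  expect_gte(mean(ks == 1L), 0.9)

  b <- three_blobs(25, seed = 3)
  expect_equal(gap_statistic(b$X, 1:6, B = 50, seed = 5)$k, 3L)

  # degenerate duplicated points -> k = 1
  expect_equal(gap_statistic(matrix(1, 20, 2), 1:4, B = 10, seed = 1)$k, 1L)
})

test_that("Laplacian eigengap counts well-separated components", {
  b <- three_blobs(25, seed = 4)
  expect_equal(affinity_eigen_estimate(b$X, 6), 3L)
  two <- b$X[b$labels != 3, ]
  expect_equal(affinity_eigen_estimate(two, 6), 2L)
})

test_that("decision fusion is the rounded mean with halves up", {
  expect_equal(decision_fusion(c(3, 2, 3, 3)), 3L)   # mean 2.75
  expect_equal(decision_fusion(c(2, 2, 1, 3)), 2L)   # mean 2
  expect_equal(decision_fusion(c(4, 4, 4, 4)), 4L)
  expect_equal(decision_fusion(c(2, 3)), 3L)         # half rounds up
  expect_error(decision_fusion(integer(0)), "at least one")
})

test_that("indices are invariant to row permutation of X", {
  b <- three_blobs(12, seed = 6)
  set.seed(2)
  perm <- sample(nrow(b$X))
  expect_equal(dunn_index(b$X[perm, ], b$labels[perm]),
               dunn_index(b$X, b$labels))
  expect_equal(calinski_harabasz(b$X[perm, ], b$labels[perm]),
               calinski_harabasz(b$X, b$labels))
  expect_equal(affinity_eigen_estimate(b$X[perm, ], 6),
               affinity_eigen_estimate(b$X, 6))
})

test_that("estimate_cluster_number fuses the four votes", {
  b <- three_blobs(25, seed = 7)
  rep_ <- estimate_cluster_number(b$X, 1:6, seed = 9, B = 50)
  expect_named(rep_$votes, c("dunn", "calinski_harabasz", "gap",
                             "affinity_eigen"))
  expect_true(all(rep_$votes >= 1 & rep_$votes <= 6))
  expect_equal(rep_$fused_k, 3L)   # all four indices agree on clean blobs
  expect_equal(rep_$fused_k, decision_fusion(rep_$votes))
})
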