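test_that("Davies-Bouldin matches the formula on hand cases", {
  # duplicated points: zero scatter
  expect_equal(davies_bouldin(matrix(c(0, 0, 1, 1)), c(1, 1, 2, 2)), 0)
  # {0,2} vs {10,12}: S = 1 each, centroid distance 10
  X <- matrix(c(0, 2, 10, 12))
  expect_equal(davies_bouldin(X, c(1, 1, 2, 2)), 0.2, tolerance = 1e-9)
  # shrinking the between-cluster gap increases DB
  db_at_gap <- function(g) {
    davies_bouldin(matrix(c(0, 2, g, g + 2)), c(1, 1, 2, 2))
  }
  expect_true(all(diff(vapply(c(20, 10, 5), db_at_gap, numeric(1))) > 0))
  expect_error(davies_bouldin(X, rep(1, 4)), "clusters")
})

test_that("Calinski-Harabasz matches a hand sum-of-squares evaluation", {
  X <- matrix(c(0, 2, 10, 12)); lab <- c(1, 1, 2, 2)
  # B = 2*(1-6)^2 + 2*(11-6)^2 = 100; W = 4; (100/1)/(4/2) = 50
  expect_equal(calinski_harabasz(X, lab), 50, tolerance = 1e-9)
  ch_at_gap <- function(g) {
    calinski_harabasz(matrix(c(0, 2, g, g + 2)), c(1, 1, 2, 2))
  }
  expect_gt(ch_at_gap(20), ch_at_gap(10))
  expect_warning(res <- calinski_harabasz(matrix(c(0, 0, 1, 1)), lab),
                 "infinite")
  expect_identical(res, Inf)
})

test_that("silhouette matches the four-point hand case and cluster::silhouette", {
  X <- matrix(c(0, 1, 10, 11)); lab <- c(1, 1, 2, 2)
  hand <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                 (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(silhouette_score(X, lab), hand, tolerance = 1e-9)
  # label swap leaves the score unchanged
  expect_equal(silhouette_score(X, 3 - lab), silhouette_score(X, lab))
  # deliberately wrong assignment scores negative
  expect_lt(silhouette_score(X, c(1, 2, 1, 2)), 0)
  # agreement with the cluster package on random data
  set.seed(9)
  Z <- matrix(rnorm(60), 30, 2)
  lz <- sample(1:3, 30, replace = TRUE)
  expect_equal(silhouette_score(Z, lz),
               mean(cluster::silhouette(lz, dist(Z))[, "sil_width"]),
               tolerance = 1e-12)
  # fuzz: always within [-1, 1]
  for (i in 1:20) {
    W <- matrix(rnorm(40), 20, 2)
    lw <- sample(1:4, 20, replace = TRUE)
    if (length(unique(lw)) < 2) next
    s <- silhouette_score(W, lw)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("all three indices are invariant to point order and relabeling", {
  set.seed(4)
  X <- matrix(rnorm(50), 25, 2)
  lab <- sample(1:3, 25, replace = TRUE)
  perm <- sample(25)
  relab <- c(30, 10, 20)[lab]
  for (f in list(davies_bouldin, calinski_harabasz, silhouette_score)) {
    expect_equal(f(X, lab), f(X[perm, ], lab[perm]))
    expect_equal(f(X, lab), f(X, relab))
  }
})

test_that("consensus k selection picks the generating k", {
  expect_equal(select_k(data.frame(k = 4, db = 1, ch = 2, silhouette = 0.5)), 4)
  sim <- noisy_shape_series(10, sd = 0.1, seed = 2)
  rep_ <- evaluate_k_grid(sim$y, 2:5, seed = 1, n_init = 3)
  expect_equal(attr(rep_, "chosen_k"), 3)
  # across 10 seeded replicates the true k wins at least 8 times
  hits <- 0
  for (s in 1:10) {
    simr <- noisy_shape_series(8, sd = 0.1, seed = 100 + s)
    kr <- evaluate_k_grid(simr$y, 2:5, seed = s, n_init = 3)
    hits <- hits + (attr(kr, "chosen_k") == 3)
  }
  expect_gte(hits, 8)
})

test_that("classifier validation enforces the class-size and split contract", {
  sim <- noisy_shape_series(10, sd = 0.1, seed = 6)
  labels <- c("a", "b", "c")[sim$labels]
  v <- validate_with_classifier(sim$y, labels, seed = 1)
  expect_equal(v$f1_weighted, 1)
  expect_equal(sum(v$confusion), 9)  # 30% of each 10-member class
  # singleton classes are excluded and absent from the confusion matrix
  y2 <- rbind(sim$y, test_shapes[1, ] + 10)
  l2 <- c(labels, "lonely")
  v2 <- validate_with_classifier(y2, l2, seed = 1)
  expect_equal(v2$excluded_classes, "lonely")
  expect_false("lonely" %in% rownames(v2$confusion))
  # deterministic given the seed
  v3 <- validate_with_classifier(sim$y, labels, seed = 1)
  expect_identical(v$confusion, v3$confusion)
  expect_error(validate_with_classifier(sim$y[1:2, ], c("a", "b")),
               "fewer than two")
})
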