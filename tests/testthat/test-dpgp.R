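t_grid <- c(0, 12, 24, 48, 72)

test_that("the squared-exponential kernel has the stated closed forms", {
  hp <- gp_hyperparams(2, 10, 0.5)
  K <- se_kernel(t_grid, hp)
  expect_equal(diag(K), rep(2, 5))
  expect_true(isSymmetric(K))
  expect_true(all(eigen(K, only.values = TRUE)$values > -1e-10))
  # ell = sqrt(1/2) * |dt| gives sf2 * exp(-1)
  hp2 <- gp_hyperparams(2, sqrt(1 / 2) * 12, 0.5)
  expect_equal(se_kernel(c(0, 12), hp2)[1, 2], 2 * exp(-1))
  # long lags decay toward zero
  hp3 <- gp_hyperparams(1, 5, 0.1)
  expect_lt(se_kernel(c(0, 72), hp3)[1, 2], 1e-30)
  expect_error(se_kernel(c(0, 0, 12), hp), "strictly increasing")
  expect_error(gp_hyperparams(-1, 1, 1), "positive")
})

test_that("cluster log marginal equals the dense Gaussian evaluation", {
  hp <- gp_hyperparams(1.5, 36, 0.3)
  set.seed(5)
  for (i in 1:20) {
    Y <- matrix(rnorm(sample(1:4, 1) * 5), ncol = 5)
    expect_equal(cluster_log_marginal(Y, t_grid, hp),
                 dense_cluster_lm(Y, t_grid, hp), tolerance = 1e-6)
  }
  # vanishing signal variance reduces to independent noise Gaussians
  y <- rnorm(5)
  hp0 <- gp_hyperparams(1e-10, 36, 0.3)
  expect_equal(cluster_log_marginal(matrix(y, 1), t_grid, hp0),
               sum(dnorm(y, 0, sqrt(0.3), log = TRUE)), tolerance = 1e-5)
  # two near-identical smooth series: sharing a cluster beats splitting
  mu <- c(0, 1, 3, 4, 4)
  a <- mu + rnorm(5, 0, 0.05); b <- mu + rnorm(5, 0, 0.05)
  hp1 <- gp_hyperparams(4, 36, 0.01)
  expect_gt(cluster_log_marginal(rbind(a, b), t_grid, hp1),
            cluster_log_marginal(matrix(a, 1), t_grid, hp1) +
              cluster_log_marginal(matrix(b, 1), t_grid, hp1))
})

test_that("hyperparameter defaults follow the empirical-Bayes rules", {
  expect_warning(hp <- estimate_hyperparams(matrix(1, 3, 5), t_grid),
                 "variance")
  expect_equal(hp$signal_var, 1e-4)
  expect_equal(hp$length_scale, 36)
  set.seed(2)
  lo <- estimate_hyperparams(matrix(rnorm(20, 0, 0.5), 4, 5), t_grid)
  hi <- estimate_hyperparams(matrix(rnorm(20, 0, 3), 4, 5), t_grid)
  expect_lt(lo$signal_var, hi$signal_var)
})

test_that("the DP-GP sampler recovers two separated GP groups", {
  mk <- function(mu, n, sd, seed) {
    set.seed(seed)
    t(replicate(n, mu + rnorm(5, 0, sd)))
  }
  for (s in 1:3) {
    Y <- rbind(mk(c(0, 1, 3, 4, 4), 8, 0.2, s),
               mk(c(4, 3, 1, 0, 0), 8, 0.2, s + 100))
    fc <- dpgp_cluster(Y, t_grid, seed = s, max_num_iterations = 1000)
    expect_equal(ari(fc$partition, rep(1:2, each = 8)), 1)
    # similarity invariants
    expect_true(isSymmetric(fc$similarity))
    expect_true(all(fc$similarity >= 0 & fc$similarity <= 1))
    expect_equal(diag(fc$similarity), rep(1, 16))
    # the returned partition beats all-singletons under the joint score
    hp <- fc$hp
    score <- function(part) {
      crp_log_prior(part, fc$alpha) +
        sum(vapply(split(seq_len(nrow(Y)), part), function(idx) {
          cluster_log_marginal(Y[idx, , drop = FALSE], t_grid, hp)
        }, numeric(1)))
    }
    expect_gt(score(fc$partition), score(seq_len(nrow(Y))))
  }
})

test_that("degenerate and permuted inputs behave predictably", {
  # single trajectory
  fc1 <- dpgp_cluster(matrix(c(1, 2, 3, 2, 1), 1), t_grid, seed = 1,
                      max_num_iterations = 50)
  expect_equal(fc1$partition, 1L)
  expect_equal(fc1$similarity, matrix(1, 1, 1))
  # identical series co-cluster in nearly every kept sweep
  Y <- matrix(rep(c(1, 2, 3, 2, 1), 10), 10, 5, byrow = TRUE)
  fc <- dpgp_cluster(Y, t_grid, seed = 4, max_num_iterations = 400)
  expect_equal(length(unique(fc$partition)), 1L)
  expect_gte(min(fc$similarity), 0.95)
  # permuting input order permutes labels only
  mk2 <- noisy_shape_series(6, sd = 0.1, seed = 9)
  hp <- estimate_hyperparams(mk2$y, t_grid)
  f1 <- dpgp_cluster(mk2$y, t_grid, hp = hp, seed = 7,
                     max_num_iterations = 400)
  perm <- sample(nrow(mk2$y))
  f2 <- dpgp_cluster(mk2$y[perm, ], t_grid, hp = hp, seed = 7,
                     max_num_iterations = 400)
  expect_equal(ari(f1$partition[perm], f2$partition), 1)
  expect_error(dpgp_cluster(Y, t_grid, max_num_iterations = 0), "max_num_iterations")
})
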