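# Independent oracles used across tests; all deliberately brute-force and
# separate from the package's implementation paths.

# soft-DTW by exhaustive enumeration of every monotone alignment path
enum_sdtw <- function(x, y, gamma) {
  n <- length(x); m <- length(y)
  costs <- numeric(0)
  rec <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (i == n && j == m) {
      costs[[length(costs) + 1]] <<- acc
      return(invisible())
    }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  mn <- min(costs)
  mn - gamma * log(sum(exp(-(costs - mn) / gamma)))
}

# classic (hard-minimum) DTW with squared ground cost
hard_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  R <- matrix(Inf, n + 1, m + 1); R[1, 1] <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    R[i + 1, j + 1] <- (x[i] - y[j])^2 +
      min(R[i, j], R[i, j + 1], R[i + 1, j])
  }
  R[n + 1, m + 1]
}

# number of monotone alignment paths (Delannoy recurrence)
n_align_paths <- function(n, m) {
  P <- matrix(0, n, m); P[1, ] <- 1; P[, 1] <- 1
  if (n > 1 && m > 1) {
    for (i in 2:n) for (j in 2:m) {
      P[i, j] <- P[i - 1, j] + P[i, j - 1] + P[i - 1, j - 1]
    }
  }
  P[n, m]
}

# dense multivariate-normal evaluation of the shared-mean GP cluster
# marginal (the O((mT)^3) formula the package avoids)
dense_cluster_lm <- function(Y, t, hp) {
  Y <- as.matrix(Y)
  m <- nrow(Y); Tn <- length(t)
  K <- hp$signal_var * exp(-outer(t, t, "-")^2 / (2 * hp$length_scale^2))
  diag(K) <- diag(K) + 1e-8 * hp$signal_var
  Sig <- kronecker(matrix(1, m, m), K) + diag(hp$noise_var, m * Tn)
  yv <- as.numeric(t(Y))
  -0.5 * m * Tn * log(2 * pi) -
    0.5 * as.numeric(determinant(Sig)$modulus) -
    0.5 * drop(yv %*% solve(Sig, yv))
}

# log CRP partition prior with concentration alpha
crp_log_prior <- function(labels, alpha) {
  sizes <- table(labels)
  length(sizes) * log(alpha) + sum(lgamma(as.numeric(sizes))) -
    sum(log(alpha + seq_along(labels) - 1))
}

# upper-tail hypergeometric p-value by direct factorial summation
factorial_fisher <- function(a, b, c, d) {
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  n_draw <- a + b
  n_white <- a + c
  n_black <- b + d
  ks <- a:min(n_draw, n_white)
  sum(exp(lchoose2(n_white, ks) + lchoose2(n_black, n_draw - ks) -
            lchoose2(n_white + n_black, n_draw)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

shift_categories <- c("A_off_to_dynamic", "B_dynamic_to_off",
                      "C_dynamic_to_dynamic")
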