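#' Gaussian-process hyperparameters
#'
#' @param signal_var signal variance of the squared-exponential kernel
#'   (sigma_f^2), > 0.
#' @param length_scale kernel length scale in hours (ell), > 0.
#' @param noise_var observation noise variance (sigma_n^2), > 0.
#' @return a `gp_hyperparams` list.
#' @export
gp_hyperparams <- function(signal_var, length_scale, noise_var) {
  if (signal_var <= 0 || length_scale <= 0 || noise_var <= 0) {
    stop("GP hyperparameters must be strictly positive")
  }
  structure(list(signal_var = signal_var, length_scale = length_scale,
                 noise_var = noise_var), class = "gp_hyperparams")
}

#' Squared-exponential kernel matrix
#'
#' `K[i,j] = signal_var * exp(-(t_i - t_j)^2 / (2 * length_scale^2))`.
#'
#' @param t strictly increasing time vector (hours).
#' @param hp a [gp_hyperparams()] object.
#' @return symmetric positive semi-definite matrix.
#' @export
se_kernel <- function(t, hp) {
  if (any(diff(t) <= 0)) stop("time vector must be strictly increasing")
  d <- outer(t, t, "-")
  hp$signal_var * exp(-d^2 / (2 * hp$length_scale^2))
}

#' Empirical-Bayes default GP hyperparameters
#'
#' Signal variance = pooled sample variance of all values (floored at 1e-4
#' with a warning for constant input); noise variance = a quarter of the
#' signal variance (same floor); length scale = half the time-grid span.
#'
#' @param members numeric matrix of series (rows) or list of vectors.
#' @param t time vector.
#' @return a [gp_hyperparams()] object.
#' @export
estimate_hyperparams <- function(members, t) {
  Y <- if (is.list(members)) do.call(rbind, members) else as.matrix(members)
  if (nrow(Y) == 0) stop("members must be nonempty")
  sf2 <- stats::var(as.numeric(Y))
  if (!is.finite(sf2) || sf2 < 1e-4) {
    warning("near-zero variance input; flooring signal variance at 1e-4")
    sf2 <- 1e-4
  }
  gp_hyperparams(signal_var = sf2,
                 length_scale = diff(range(t)) / 2,
                 noise_var = max(0.25 * sf2, 1e-4))
}

# Cholesky pieces shared by the marginal computations: jittered kernel,
# its inverse/log-determinant, and A_m = K^{-1} + (m/sn2) I per cluster size.
dpgp_precompute <- function(t, hp, max_size) {
  K <- se_kernel(t, hp)
  diag(K) <- diag(K) + 1e-8 * hp$signal_var
  cK <- tryCatch(chol(K), error = function(e) {
    stop("covariance not positive definite after jitter")
  })
  Kinv <- chol2inv(cK)
  logdetK <- 2 * sum(log(diag(cK)))
  sn2 <- hp$noise_var
  Ainv <- vector("list", max_size)
  logdetA <- numeric(max_size)
  Tn <- length(t)
  for (m in seq_len(max_size)) {
    A <- Kinv + diag(m / sn2, Tn)
    cA <- chol(A)
    Ainv[[m]] <- chol2inv(cA)
    logdetA[m] <- 2 * sum(log(diag(cA)))
  }
  list(K = K, Kinv = Kinv, logdetK = logdetK, Ainv = Ainv,
       logdetA = logdetA, sn2 = sn2)
}

#' Log marginal likelihood of a trajectory cluster
#'
#' Log density of m stacked series under the shared-mean GP model: each
#' cluster has one latent smooth mean drawn from a zero-mean GP with the
#' squared-exponential kernel, and every member series observes it with
#' independent Gaussian noise, i.e.
#' `Cov(y_ai, y_bj) = k_SE(t_i, t_j) + noise_var * 1[a==b, i==j]`.
#' The latent mean is integrated out analytically, so the computation is
#' O(T^3) via triangular (Cholesky) factorizations regardless of cluster
#' size.
#'
#' @param members numeric matrix (series in rows) or list of vectors, all
#'   of length `length(t)`.
#' @param t time vector.
#' @param hp a [gp_hyperparams()] object.
#' @return scalar log marginal likelihood.
#' @export
cluster_log_marginal <- function(members, t, hp) {
  Y <- if (is.list(members)) do.call(rbind, members) else as.matrix(members)
  m <- nrow(Y); Tn <- length(t)
  stopifnot(ncol(Y) == Tn, m >= 1)
  pre <- dpgp_precompute(t, hp, m)
  s <- colSums(Y)
  ssq <- sum(Y^2)
  sn2 <- pre$sn2
  qf <- drop(t(s) %*% pre$Ainv[[m]] %*% s) / sn2^2
  -0.5 * m * Tn * log(2 * pi * sn2) - 0.5 * pre$logdetK -
    0.5 * pre$logdetA[m] - ssq / (2 * sn2) + 0.5 * qf
}

#' Dirichlet-process GP refinement of one trajectory cluster
#'
#' Collapsed Gibbs sampling under a Chinese-restaurant-process prior with
#' concentration `alpha`: each sweep reassigns every trajectory with
#' probability proportional to (sub-cluster size) x exp(change in cluster
#' log marginal) for existing sub-clusters, and alpha x exp(singleton log
#' marginal) for a new one. Post burn-in partitions accumulate a posterior
#' co-clustering similarity matrix; the returned partition is the sampled
#' partition minimizing squared distance to that matrix (least-squares
#' partition selection). Hyperparameters are estimated once per parent
#' cluster and held fixed across sweeps.
#'
#' @param members numeric matrix of series (rows), a list of vectors, or a
#'   `trajectories` object.
#' @param t time vector; taken from `members` when it is a `trajectories`
#'   object.
#' @param alpha CRP concentration parameter (> 0).
#' @param max_num_iterations number of Gibbs sweeps (default 1000).
#' @param burn_frac fraction of sweeps discarded as burn-in (default 0.5).
#' @param hp optional [gp_hyperparams()]; estimated from the data if NULL.
#' @param seed RNG seed; the sampler is deterministic given the seed.
#' @param parent_cluster optional integer recorded in the result (the
#'   initial-clustering label being refined).
#' @return a `fine_clustering` object: list with `partition` (integer
#'   labels, contiguous from 1), `similarity` (co-clustering matrix, unit
#'   diagonal), `n_sweeps_run`, `alpha`, `seed`, `parent_cluster`, `hp`.
#' @export
dpgp_cluster <- function(members, t = NULL, alpha = 1,
                         max_num_iterations = 1000, burn_frac = 0.5,
                         hp = NULL, seed = 1, parent_cluster = NA_integer_) {
  if (inherits(members, "trajectories")) {
    if (is.null(t)) t <- members$time
    members <- members$y
  }
  Y <- if (is.list(members)) do.call(rbind, members) else as.matrix(members)
  if (is.null(t)) stop("time vector t is required")
  if (max_num_iterations < 1) stop("max_num_iterations must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  n <- nrow(Y)
  if (n == 0) stop("members must be nonempty")
  if (is.null(hp)) hp <- estimate_hyperparams(Y, t)
  pre <- dpgp_precompute(t, hp, n)
  n_burn <- floor(burn_frac * max_num_iterations)
  if (n_burn >= max_num_iterations) n_burn <- max_num_iterations - 1
  set.seed(seed)
  res <- dpgp_gibbs_cpp(Y, pre$Ainv, pre$logdetA, pre$logdetK, pre$sn2,
                        alpha, max_num_iterations, n_burn,
                        rep(1L, n))
  # relabel contiguous from 1 in order of first appearance
  raw <- res$labels
  part <- match(raw, unique(raw))
  structure(list(partition = part, similarity = res$similarity,
                 n_sweeps_run = max_num_iterations, alpha = alpha,
                 seed = seed, parent_cluster = parent_cluster, hp = hp,
                 n_kept = res$n_kept),
            class = "fine_clustering")
}

#' @export
print.fine_clustering <- function(x, ...) {
  cat(sprintf("DP-GP refinement of cluster %s: %d sub-clusters over %d trajectories (%d sweeps)\n",
              as.character(x$parent_cluster), length(unique(x$partition)),
              length(x$partition), x$n_sweeps_run))
  invisible(x)
}
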