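#' Soft minimum
#'
#' `-gamma * log(sum_i exp(-v_i / gamma))`, the smoothed minimum underlying
#' soft dynamic time warping. Infinite entries contribute nothing to the
#' sum; the result never exceeds `min(values)`.
#'
#' @param values numeric vector with at least one finite entry (all-infinite
#'   input returns `+Inf`).
#' @param gamma smoothing parameter, strictly positive.
#' @return scalar soft minimum.
#' @export
soft_min <- function(values, gamma = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (length(values) == 0) stop("values must be nonempty")
  m <- min(values)
  if (!is.finite(m)) return(Inf)
  finite <- values[is.finite(values)]
  m - gamma * log(sum(exp(-(finite - m) / gamma)))
}

#' Soft dynamic time warping distance
#'
#' Smoothed DTW between two univariate series: the dynamic program replaces
#' the hard minimum over alignment predecessors with [soft_min()], so the
#' value equals `-gamma * log` of the sum over all monotone alignment paths
#' of `exp(-cost/gamma)`, with squared-difference ground cost. As
#' `gamma -> 0` it approaches classic DTW. Symmetric in its arguments.
#'
#' @param x,y numeric series (need not be the same length).
#' @param gamma smoothing parameter, strictly positive.
#' @return scalar soft-DTW value (may be negative for small costs).
#' @export
soft_dtw <- function(x, y, gamma = 1) {
  if (length(x) == 0 || length(y) == 0) stop("series must be nonempty")
  if (gamma <= 0) stop("gamma must be > 0")
  sdtw_value_cpp(as.numeric(x), as.numeric(y), gamma)
}

#' Soft-DTW barycenter
#'
#' Finds a length-T series minimizing the total soft-DTW to a set of
#' series, by monotone gradient descent with Armijo backtracking (the
#' objective never increases between iterations).
#'
#' @param series numeric matrix (series in rows) or list of equal-length
#'   numeric vectors.
#' @param gamma soft-DTW smoothing parameter.
#' @param init starting series; defaults to the pointwise mean.
#' @param max_iter maximum descent iterations.
#' @param tol stop when the relative objective improvement falls below this.
#' @return numeric vector of length T with attribute `objective` (the final
#'   total soft-DTW) and `trace` (per-iteration objective values).
#' @export
sdtw_barycenter <- function(series, gamma = 1, init = NULL,
                            max_iter = 30, tol = 1e-6) {
  Y <- if (is.list(series)) do.call(rbind, series) else as.matrix(series)
  if (nrow(Y) == 0) stop("series list must be nonempty")
  b <- if (is.null(init)) colMeans(Y) else as.numeric(init)
  stopifnot(length(b) == ncol(Y))
  ob <- sdtw_bary_obj_cpp(b, Y, gamma)
  f <- ob$value
  trace <- f
  step <- 0.5 / nrow(Y)
  for (it in seq_len(max_iter)) {
    g <- ob$gradient
    gn2 <- sum(g^2)
    if (gn2 < 1e-18) break
    t_ <- step
    repeat {
      cand <- b - t_ * g
      oc <- sdtw_bary_obj_cpp(cand, Y, gamma)
      if (oc$value <= f - 1e-4 * t_ * gn2 || t_ < 1e-12) break
      t_ <- t_ / 2
    }
    if (oc$value >= f) break  # no descent direction left at machine scale
    improved <- (f - oc$value) / max(abs(f), 1e-12)
    b <- cand; f <- oc$value; ob <- oc
    trace <- c(trace, f)
    step <- min(t_ * 2, 10)  # mild step-size adaptation
    if (improved < tol) break
  }
  structure(b, objective = f, trace = trace)
}

# k-means++-style seeding under the soft-DTW loss: the first centroid is a
# uniformly sampled trajectory, each further one is sampled with probability
# proportional to its (non-negative) soft-DTW distance to the nearest centroid
# already chosen
kmeanspp_init <- function(Y, k, gamma) {
  n <- nrow(Y)
  picked <- sample.int(n, 1)
  if (k > 1) {
    mind <- pmax(sdtw_cross_cpp(Y, Y[picked, , drop = FALSE], gamma)[, 1], 0)
    for (j in 2:k) {
      mind[picked] <- 0
      nxt <- if (sum(mind) > 0) {
        sample.int(n, 1, prob = mind)
      } else sample.int(n, 1)
      picked <- c(picked, nxt)
      if (j < k) {
        d <- pmax(sdtw_cross_cpp(Y, Y[nxt, , drop = FALSE], gamma)[, 1], 0)
        mind <- pmin(mind, d)
      }
    }
  }
  Y[picked, , drop = FALSE]
}

#' Soft-DTW K-means clustering of trajectories
#'
#' K-means under the soft-DTW loss: alternate nearest-centroid assignment
#' and barycenter centroid updates. Centroid updates start from the current
#' centroid and descend monotonically, so the total inertia is
#' non-increasing across iterations within one initialization. The best of
#' `n_init` restarts is returned, each seeded with distance-weighted
#' (k-means++-style) sampling of k trajectories as initial centroids.
#' Trajectories from both conditions and all
#' replicates are expected pooled, so the resulting labels form one shared
#' label space.
#'
#' @param trajs a `trajectories` object from [build_trajectories()], or a
#'   numeric matrix with one series per row.
#' @param k number of clusters (1 <= k <= number of trajectories).
#' @param gamma soft-DTW smoothing parameter.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_init number of random restarts.
#' @param max_iter maximum assignment/update iterations per restart.
#' @return an `initial_clustering` object: list with `k`, `assignment`
#'   (integer labels in 1..k), `centroids` (k x T matrix), `inertia`,
#'   `inertia_trace`, `gamma`, `seed`.
#' @export
sdtw_kmeans <- function(trajs, k, gamma = 1, seed = 1, n_init = 5, max_iter = 50) {
  Y <- if (inherits(trajs, "trajectories")) trajs$y else as.matrix(trajs)
  n <- nrow(Y)
  if (k < 1 || k > n) stop("k must be between 1 and the number of trajectories")
  set.seed(seed)
  best <- NULL
  for (init_i in seq_len(n_init)) {
    centers <- kmeanspp_init(Y, k, gamma)
    assign_old <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- sdtw_cross_cpp(Y, centers, gamma)
      assign <- max.col(-D, ties.method = "first")
      # empty-cluster repair: reseed with the trajectory farthest from its
      # assigned centroid
      mind <- D[cbind(seq_len(n), assign)]
      for (c_ in which(tabulate(assign, k) == 0)) {
        far <- which.max(mind)
        centers[c_, ] <- Y[far, ]
        assign[far] <- c_
        mind[far] <- -Inf
      }
      D <- sdtw_cross_cpp(Y, centers, gamma)
      assign <- max.col(-D, ties.method = "first")
      inertia <- sum(D[cbind(seq_len(n), assign)])
      trace <- c(trace, inertia)
      if (identical(assign, assign_old)) break
      assign_old <- assign
      for (c_ in seq_len(k)) {
        members <- Y[assign == c_, , drop = FALSE]
        if (nrow(members) > 0) {
          centers[c_, ] <- sdtw_barycenter(members, gamma, init = centers[c_, ])
        }
      }
    }
    if (is.null(best) || inertia < best$inertia) {
      best <- list(k = k, assignment = assign, centroids = centers,
                   inertia = inertia, inertia_trace = trace,
                   gamma = gamma, seed = seed)
    }
  }
  structure(best, class = "initial_clustering")
}

#' @export
print.initial_clustering <- function(x, ...) {
  cat(sprintf("soft-DTW k-means: k = %d, inertia = %.4f (gamma = %g, seed = %d)\n",
              x$k, x$inertia, x$gamma, x$seed))
  cat("cluster sizes:", tabulate(x$assignment, x$k), "\n")
  invisible(x)
}

#' Pairwise soft-DTW distance matrix
#'
#' @param X numeric matrix, one series per row.
#' @param Y optional second matrix; defaults to `X`.
#' @param gamma soft-DTW smoothing parameter.
#' @return `nrow(X)` x `nrow(Y)` matrix of soft-DTW values.
#' @export
sdtw_dist <- function(X, Y = X, gamma = 1) {
  sdtw_cross_cpp(as.matrix(X), as.matrix(Y), gamma)
}
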