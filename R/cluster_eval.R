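check_labels <- function(X, labels, min_clusters = 2) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(X)) stop("one label per row required")
  if (length(unique(labels)) < min_clusters) {
    stop("at least ", min_clusters, " clusters required")
  }
  list(X = X, labels = labels)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio (S_i + S_j) / M_ij, with S the
#' mean member-to-centroid Euclidean distance and M the centroid-to-centroid
#' distance. Lower (closer to zero) indicates a better partition.
#'
#' @param X numeric matrix, one fixed-length series per row.
#' @param labels cluster labels, one per row; at least two clusters.
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(X, labels) {
  cl <- check_labels(X, labels)
  X <- cl$X; labels <- cl$labels
  ks <- sort(unique(labels))
  cents <- matrix(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                         numeric(ncol(X))),
                  nrow = length(ks), ncol = ncol(X), byrow = TRUE)
  S <- vapply(seq_along(ks), function(i) {
    M <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((M - matrix(cents[i, ], nrow(M), ncol(M), byrow = TRUE))^2)))
  }, numeric(1))
  Mij <- as.matrix(dist(cents))
  r <- vapply(seq_along(ks), function(i) {
    max(((S[i] + S[-i]) / Mij[i, -i]))
  }, numeric(1))
  mean(r)
}

#' Calinski-Harabasz index
#'
#' `(B / (k - 1)) / (W / (n - k))` from between- and within-cluster sums of
#' squares about the centroids. Higher means denser, better-separated
#' clusters. Zero within-cluster dispersion returns `+Inf` with a warning.
#'
#' @inheritParams davies_bouldin
#' @return positive scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(X, labels) {
  cl <- check_labels(X, labels)
  X <- cl$X; labels <- cl$labels
  n <- nrow(X); ks <- sort(unique(labels)); k <- length(ks)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (kk in ks) {
    M <- X[labels == kk, , drop = FALSE]
    cent <- colMeans(M)
    B <- B + nrow(M) * sum((cent - grand)^2)
    W <- W + sum(sweep(M, 2, cent)^2)
  }
  if (W == 0) {
    warning("zero within-cluster dispersion; Calinski-Harabasz is infinite")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)` where a is the mean
#' within-cluster distance and b the smallest mean distance to another
#' cluster; in [-1, 1]. Points in singleton clusters score 0. The distance
#' is Euclidean by default, or soft-DTW (symmetrized) on request.
#'
#' @inheritParams davies_bouldin
#' @param metric `"euclidean"` (default) or `"softdtw"`.
#' @param gamma soft-DTW smoothing parameter (softdtw metric only).
#' @return scalar in [-1, 1].
#' @export
silhouette_score <- function(X, labels, metric = c("euclidean", "softdtw"),
                             gamma = 1) {
  metric <- match.arg(metric)
  cl <- check_labels(X, labels)
  X <- cl$X; labels <- cl$labels
  D <- if (metric == "euclidean") {
    as.matrix(dist(X))
  } else {
    M <- sdtw_cross_cpp(X, X, gamma)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  }
  n <- nrow(X)
  ks <- sort(unique(labels))
  sizes <- table(factor(labels, levels = ks))
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[as.character(li)]] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == li]) / (sizes[[as.character(li)]] - 1)
    b <- min(vapply(ks[ks != li], function(kk) mean(D[i, labels == kk]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Consensus k selection from validity indices
#'
#' Ranks every candidate k under each index (Davies-Bouldin ascending,
#' Calinski-Harabasz descending, silhouette descending) and picks the k
#' with the best (smallest) mean rank; ties go to the smallest k.
#'
#' @param report data.frame with columns `k`, `db`, `ch`, `silhouette`.
#' @return the chosen k (integer).
#' @export
select_k <- function(report) {
  stopifnot(all(c("k", "db", "ch", "silhouette") %in% names(report)))
  if (nrow(report) == 0) stop("empty k grid")
  if (nrow(report) == 1) return(report$k[1])
  mean_rank <- (rank(report$db, ties.method = "average") +
                rank(-report$ch, ties.method = "average") +
                rank(-report$silhouette, ties.method = "average")) / 3
  cand <- report$k[mean_rank == min(mean_rank)]
  min(cand)
}

#' Evaluate a grid of k values
#'
#' Runs soft-DTW k-means at every k in the grid and scores the resulting
#' partitions with the three validity indices (on the trajectories as
#' fixed-length Euclidean vectors), then applies [select_k()].
#'
#' @param trajs a `trajectories` object or numeric matrix of series.
#' @param k_grid integer vector of candidate k.
#' @param gamma,seed,n_init,max_iter passed to [sdtw_kmeans()].
#' @return a `k_selection` object: data.frame (`k`, `db`, `ch`,
#'   `silhouette`, `chosen`) with attributes `chosen_k` and `clusterings`
#'   (the fitted clustering per k).
#' @export
evaluate_k_grid <- function(trajs, k_grid, gamma = 1, seed = 1, n_init = 5,
                            max_iter = 50) {
  Y <- if (inherits(trajs, "trajectories")) trajs$y else as.matrix(trajs)
  fits <- list()
  rows <- lapply(seq_along(k_grid), function(i) {
    k <- k_grid[i]
    fit <- sdtw_kmeans(Y, k, gamma = gamma, seed = stage_seed(seed, i),
                       n_init = n_init, max_iter = max_iter)
    fits[[as.character(k)]] <<- fit
    if (length(unique(fit$assignment)) < 2) {
      data.frame(k = k, db = NA_real_, ch = NA_real_, silhouette = NA_real_)
    } else {
      data.frame(k = k,
                 db = davies_bouldin(Y, fit$assignment),
                 ch = calinski_harabasz(Y, fit$assignment),
                 silhouette = silhouette_score(Y, fit$assignment))
    }
  })
  report <- do.call(rbind, rows)
  ok <- stats::complete.cases(report)
  chosen <- select_k(report[ok, , drop = FALSE])
  report$chosen <- report$k == chosen
  structure(report, chosen_k = chosen, clusterings = fits,
            class = c("k_selection", "data.frame"))
}

# stratified train/test split: per class, hold out round(split_frac * n_c)
# members (at least 1, at most n_c - 1)
stratified_split <- function(labels, split_frac, seed) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- min(max(round(split_frac * length(idx)), 1), length(idx) - 1)
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' 1-nearest-neighbour soft-DTW classifier
#'
#' The default, dependency-free sequence classifier for
#' [validate_with_classifier()]: each test series takes the label of its
#' soft-DTW-nearest training series.
#'
#' @param gamma soft-DTW smoothing parameter.
#' @return a classifier function `(train_x, train_y, test_x) -> labels`.
#' @export
sdtw_1nn_classifier <- function(gamma = 1) {
  function(train_x, train_y, test_x) {
    D <- sdtw_cross_cpp(as.matrix(test_x), as.matrix(train_x), gamma)
    train_y[max.col(-D, ties.method = "first")]
  }
}

#' Hold-out validation of trajectory-set labels
#'
#' Checks that the final trajectory labels are learnable from the series
#' themselves: classes with fewer than two members are excluded, the rest
#' are split into train and a stratified hold-out, a sequence classifier is
#' trained, and the confusion matrix plus support-weighted F1 on the
#' hold-out are reported.
#'
#' @param X numeric matrix, one series per row.
#' @param labels class label (trajectory-set id) per row.
#' @param split_frac held-out fraction (default 0.30).
#' @param seed RNG seed for the stratified split.
#' @param classifier function `(train_x, train_y, test_x) -> labels`;
#'   defaults to [sdtw_1nn_classifier()].
#' @return a `validation_report`: list with `confusion` (true x predicted),
#'   `f1_weighted`, `excluded_classes`, `split_frac`, `seed`.
#' @export
validate_with_classifier <- function(X, labels, split_frac = 0.30, seed = 1,
                                     classifier = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(classifier)) classifier <- sdtw_1nn_classifier()
  counts <- table(labels)
  excluded <- names(counts)[counts < 2]
  keep <- !(labels %in% excluded)
  if (!any(keep)) stop("all classes have fewer than two members")
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  test <- stratified_split(labels, split_frac, seed)
  train <- setdiff(seq_along(labels), test)
  pred <- classifier(X[train, , drop = FALSE], labels[train],
                     X[test, , drop = FALSE])
  lev <- sort(unique(labels))
  confusion <- table(factor(labels[test], levels = lev),
                     factor(pred, levels = lev))
  f1 <- weighted_f1(confusion)
  structure(list(confusion = confusion, f1_weighted = f1,
                 excluded_classes = excluded, split_frac = split_frac,
                 seed = seed),
            class = "validation_report")
}

# support-weighted F1 from a true x predicted confusion matrix; classes
# with undefined precision or recall contribute F1 = 0
weighted_f1 <- function(confusion) {
  support <- rowSums(confusion)
  f1s <- vapply(seq_len(nrow(confusion)), function(i) {
    tp <- confusion[i, i]
    prec_den <- sum(confusion[, i])
    rec_den <- support[i]
    if (tp == 0 || prec_den == 0 || rec_den == 0) return(0)
    p <- tp / prec_den; r <- tp / rec_den
    2 * p * r / (p + r)
  }, numeric(1))
  present <- support > 0
  sum(f1s[present] * support[present]) / sum(support[present])
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("hold-out validation: weighted F1 = %.3f over %d classes (%d excluded, split %.0f%%)\n",
              x$f1_weighted, nrow(x$confusion), length(x$excluded_classes),
              100 * x$split_frac))
  invisible(x)
}
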