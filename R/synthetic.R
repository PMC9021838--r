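#' Synthetic-data configuration
#'
#' Defaults emulate a two-condition time course with five time points
#' (0, 12, 24, 48, 72 h) and three biological replicates: a fraction of
#' gene-condition profiles are unexpressed ("off", exact zeros at every
#' time point), the rest follow one of a library of dynamic trajectory
#' shapes on the log2 scale, and condition-dependent pattern shifts
#' (off-to-dynamic A, dynamic-to-off B, dynamic-to-dynamic C) are injected
#' at the configured rates. Replicate discordance swaps a whole replicate
#' to a random other shape, the failure mode replicate sorting is designed
#' to catch.
#'
#' @param n_genes number of genes (default 500).
#' @param time_grid ordered time grid in hours.
#' @param m replicates per condition (default 3).
#' @param n_shapes shapes drawn from [make_shape_library()] (max 7).
#' @param frac_off_control,frac_off_treated target fraction of genes off in
#'   each condition (shift categories A and B count toward these; the
#'   remainder are off in both conditions).
#' @param frac_shift_A,frac_shift_B,frac_shift_C injected shift fractions.
#' @param noise_sd replicate noise standard deviation on the log2 scale.
#' @param replicate_discordance_prob probability a dynamic replicate is
#'   drawn from a random other shape.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500,
                             time_grid = c(0, 12, 24, 48, 72),
                             m = 3, n_shapes = 7,
                             frac_off_control = 0.15, frac_off_treated = 0.15,
                             frac_shift_A = 0.04, frac_shift_B = 0.03,
                             frac_shift_C = 0.03,
                             noise_sd = 0.1,
                             replicate_discordance_prob = 0.05,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, time_grid = time_grid, m = m,
              n_shapes = n_shapes, frac_off_control = frac_off_control,
              frac_off_treated = frac_off_treated,
              frac_shift_A = frac_shift_A, frac_shift_B = frac_shift_B,
              frac_shift_C = frac_shift_C, noise_sd = noise_sd,
              replicate_discordance_prob = replicate_discordance_prob,
              seed = seed)
  fr <- frac_shift_A + frac_shift_B + frac_shift_C +
    max(0, min(frac_off_control - frac_shift_A,
               frac_off_treated - frac_shift_B))
  if (frac_shift_A < 0 || frac_shift_B < 0 || frac_shift_C < 0 ||
      frac_off_control < 0 || frac_off_treated < 0 || fr > 1) {
    stop("fractions must be non-negative and sum to at most 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  structure(cfg, class = "synthetic_config")
}

#' Library of dynamic trajectory shapes
#'
#' Parametric mean trajectories on the log2-expression scale spanning the
#' pattern families seen in real time courses: late rise (48-72 h), early
#' rise (by 12 h), transient peak at 24 h, monotone decline, dip-then-
#' recover, flat-low and flat-high. The families differ in expression level
#' as well as in dynamics, as real pattern families do, so their values
#' rarely collide at any single time point; all pairwise L2 separations
#' exceed four default noise standard deviations.
#'
#' @param n_shapes number of shapes, 2..7.
#' @param time_grid ordered time vector (hours).
#' @param seed accepted for interface stability; the shapes are
#'   deterministic parametric curves.
#' @return matrix `n_shapes` x T, rownames = shape names.
#' @export
make_shape_library <- function(n_shapes = 7, time_grid = c(0, 12, 24, 48, 72),
                               seed = NULL) {
  if (n_shapes < 2) stop("n_shapes must be >= 2")
  t <- time_grid
  u <- (t - min(t)) / diff(range(t))
  shapes <- rbind(
    late_up = 0.5 + 4.5 * u^3,
    early_up = 1.2 + 3.3 * (1 - 2^(-(t - min(t)) / 6)),
    transient_24 = 1.8 + 3.2 * exp(-((t - 24) / 14)^2),
    mono_down = 5.5 - 4.5 * u,
    down_then_up = 4.2 - 3 * exp(-((t - 36) / 20)^2),
    flat_low = rep(2.6, length(t)),
    flat_high = rep(5.9, length(t))
  )
  if (n_shapes > nrow(shapes)) {
    stop("n_shapes exceeds the available parametric shape slots (",
         nrow(shapes), ")")
  }
  shapes[seq_len(n_shapes), , drop = FALSE]
}

#' Generate a synthetic expression matrix with known truth
#'
#' Off gene-conditions emit exact zeros in every replicate at all time
#' points. Dynamic trajectories are shape mean + i.i.d. Gaussian noise on
#' the log2 scale, mapped to an FPKM-like scale by `2^x - 1` (clipped at
#' zero). Shift categories are injected per the configured fractions; the
#' returned truth records the generating shape of every trajectory and the
#' shift category of every gene.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `gem` (an [expression_matrix()] on the fpkm scale) and
#'   `truth` (list: `genes` data.frame with `gene_id`, `control_shape`,
#'   `treated_shape`, `category`; `trajectories` data.frame with the
#'   per-replicate generating shape).
#' @export
generate_gem <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  t <- cfg$time_grid
  Tn <- length(t)
  m <- cfg$m
  shapes <- make_shape_library(cfg$n_shapes, t)
  shape_names <- rownames(shapes)

  n_A <- round(cfg$frac_shift_A * n)
  n_B <- round(cfg$frac_shift_B * n)
  n_C <- round(cfg$frac_shift_C * n)
  n_off_both <- max(0, round(min(cfg$frac_off_control * n - n_A,
                                 cfg$frac_off_treated * n - n_B)))
  n_non <- n - n_A - n_B - n_C - n_off_both
  if (n_non < 0) stop("shift and off fractions exceed the gene count")
  categories <- sample(c(rep("A_off_to_dynamic", n_A),
                         rep("B_dynamic_to_off", n_B),
                         rep("C_dynamic_to_dynamic", n_C),
                         rep("off_both", n_off_both),
                         rep("non_shift", n_non)))
  gene_ids <- sprintf("gene%04d", seq_len(n))

  ctrl_shape <- trt_shape <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    switch(categories[i],
      A_off_to_dynamic = { trt_shape[i] <- sample(shape_names, 1) },
      B_dynamic_to_off = { ctrl_shape[i] <- sample(shape_names, 1) },
      C_dynamic_to_dynamic = {
        pair <- sample(shape_names, 2)
        ctrl_shape[i] <- pair[1]; trt_shape[i] <- pair[2]
      },
      off_both = { },
      non_shift = {
        s <- sample(shape_names, 1)
        ctrl_shape[i] <- s; trt_shape[i] <- s
      })
  }

  conds <- c("control", "treated")
  meta <- expand.grid(replicate = seq_len(m), time = t, condition = conds,
                      stringsAsFactors = FALSE)[, c("condition", "time", "replicate")]
  meta$sample_id <- sprintf("%s_%gh_r%d", meta$condition, meta$time,
                            meta$replicate)
  vals <- matrix(0, n, nrow(meta), dimnames = list(gene_ids, meta$sample_id))

  traj_rows <- list()
  for (cond in conds) {
    gshape <- if (cond == "control") ctrl_shape else trt_shape
    for (i in seq_len(n)) {
      for (r in seq_len(m)) {
        cols <- which(meta$condition == cond & meta$replicate == r)
        cols <- cols[order(meta$time[cols])]
        if (is.na(gshape[i])) {
          vals[i, cols] <- 0
          used <- NA_character_
        } else {
          used <- gshape[i]
          if (runif(1) < cfg$replicate_discordance_prob &&
              length(shape_names) > 1) {
            used <- sample(setdiff(shape_names, gshape[i]), 1)
          }
          ylog <- shapes[used, ] + rnorm(Tn, 0, cfg$noise_sd)
          vals[i, cols] <- pmax(2^ylog - 1, 0)
        }
        traj_rows[[length(traj_rows) + 1]] <- data.frame(
          gene_id = gene_ids[i], condition = cond, replicate = r,
          shape = used, stringsAsFactors = FALSE)
      }
    }
  }

  gem <- expression_matrix(vals, meta[, c("sample_id", "condition", "time",
                                          "replicate")], scale = "fpkm")
  truth <- list(
    genes = data.frame(gene_id = gene_ids, control_shape = ctrl_shape,
                       treated_shape = trt_shape, category = categories,
                       stringsAsFactors = FALSE),
    trajectories = do.call(rbind, traj_rows))
  list(gem = gem, truth = truth)
}

#' Write the synthetic truth tables to TSV
#' @param truth the `truth` element of [generate_gem()].
#' @param path output TSV (gene-level truth).
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth$genes, path, sep = "\t")
  invisible(path)
}
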