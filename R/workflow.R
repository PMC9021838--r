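#' Pipeline run configuration
#'
#' @param gem an [expression_matrix()] on the fpkm scale, or a path to a
#'   GEM TSV readable by [read_gem()].
#' @param annotations optional annotation data.frame or TSV path for
#'   enrichment (see [read_annotations()]).
#' @param outdir optional output directory; when given, every intermediate
#'   table plus a machine-readable summary JSON and a run log are written.
#' @param k_grid candidate k values for the initial clustering (default
#'   `seq(35, 90, 5)`, suited to organism-scale matrices; use a smaller
#'   grid for small inputs).
#' @param gamma soft-DTW smoothing parameter.
#' @param min_agree replicate-agreement threshold (2 or 3 for triplicates).
#' @param n_init,kmeans_max_iter soft-DTW k-means settings.
#' @param dpgp_alpha CRP concentration for the DP-GP refinement.
#' @param dpgp_max_iter Gibbs sweeps per refined cluster (default 1000).
#' @param burn_frac burn-in fraction of the Gibbs sweeps.
#' @param enrich_alpha adjusted-p threshold for enrichment (default 0.001).
#' @param min_zero_replicates all-zero replicates needed to call a gene off.
#' @param split_frac held-out fraction for classifier validation.
#' @param label_pattern sample-name template for [read_gem()].
#' @param set_prefix trajectory-set name prefix.
#' @param eval_after_fine score the k grid on post-refinement composite
#'   labels instead of the initial labels (costlier; default FALSE).
#' @param drop_t0_shifts apply the first-time-point shift filter
#'   (default FALSE).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a validated `run_config` list.
#' @export
run_config <- function(gem, annotations = NULL, outdir = NULL,
                       k_grid = seq(35, 90, 5), gamma = 1, min_agree = 3,
                       n_init = 5, kmeans_max_iter = 50, dpgp_alpha = 1,
                       dpgp_max_iter = 1000, burn_frac = 0.5,
                       enrich_alpha = 0.001, min_zero_replicates = 1,
                       split_frac = 0.30,
                       label_pattern = "{condition}_{time}h_r{rep}",
                       set_prefix = "R", eval_after_fine = FALSE,
                       drop_t0_shifts = FALSE, seed = 1) {
  if (is.character(gem) && !file.exists(gem)) stop("GEM path not found: ", gem)
  if (is.character(annotations) && !file.exists(annotations)) {
    stop("annotation path not found: ", annotations)
  }
  if (!min_agree %in% c(2, 3)) stop("min_agree must be 2 or 3")
  structure(list(gem = gem, annotations = annotations, outdir = outdir,
                 k_grid = k_grid, gamma = gamma, min_agree = min_agree,
                 n_init = n_init, kmeans_max_iter = kmeans_max_iter,
                 dpgp_alpha = dpgp_alpha, dpgp_max_iter = dpgp_max_iter,
                 burn_frac = burn_frac, enrich_alpha = enrich_alpha,
                 min_zero_replicates = min_zero_replicates,
                 split_frac = split_frac, label_pattern = label_pattern,
                 set_prefix = set_prefix, eval_after_fine = eval_after_fine,
                 drop_t0_shifts = drop_t0_shifts, seed = seed),
            class = "run_config")
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full shift-detection pipeline
#'
#' Executes, in order: GEM loading and validation; off-gene extraction per
#' condition on raw FPKM; quantile normalization and log2(x+1) transform;
#' per-replicate trajectory construction (both conditions pooled into one
#' shared label space); soft-DTW k-means over the k grid with consensus
#' validity-index selection of k; DP-GP refinement of every initial
#' cluster; hold-out classifier validation of the composite labels;
#' replicate sorting and shift categorization; trajectory-set grouping;
#' and (when annotations are supplied) Fisher/BH enrichment. Rerunning
#' with the same config and seed reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_result` list: `gem_norm`, `off`, `trajectories`,
#'   `k_report`, `chosen_k`, `initial`, `fine` (per parent cluster),
#'   `labels` (per-replicate label table), `validation`, `shift`
#'   (shift table), `sets`, `enrichment`, `summary`, `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))

  gem <- stage_fail("gem_io", {
    g <- if (is.character(cfg$gem)) {
      read_gem(cfg$gem, label_pattern = cfg$label_pattern)
    } else cfg$gem
    stopifnot(inherits(g, "ExpressionMatrix"), g$scale == "fpkm")
    g
  })

  off <- stage_fail("off_extraction", {
    list(control = extract_off_genes(gem, "control", cfg$min_zero_replicates),
         treated = extract_off_genes(gem, "treated", cfg$min_zero_replicates))
  })

  norm <- stage_fail("normalization", log_transform(quantile_normalize(gem)))

  trajs <- stage_fail("trajectories", {
    tr <- build_trajectories(norm)
    keep <- !((tr$meta$condition == "control" &
                 tr$meta$gene_id %in% off$control$off) |
              (tr$meta$condition == "treated" &
                 tr$meta$gene_id %in% off$treated$off))
    tr$meta <- tr$meta[keep, , drop = FALSE]
    tr$y <- tr$y[keep, , drop = FALSE]
    rownames(tr$meta) <- NULL
    tr
  })
  if (nrow(trajs$y) == 0) stop("pipeline stage 'trajectories' failed: no active trajectories")

  k_grid <- cfg$k_grid[cfg$k_grid <= nrow(trajs$y)]
  if (!length(k_grid)) stop("pipeline stage 'k_selection' failed: grid exceeds trajectory count")
  ksel <- stage_fail("k_selection", {
    if (length(k_grid) == 1 && !cfg$eval_after_fine) {
      NULL
    } else {
      evaluate_k_grid(trajs, k_grid, gamma = cfg$gamma,
                      seed = stage_seed(cfg$seed, 100), n_init = cfg$n_init,
                      max_iter = cfg$kmeans_max_iter)
    }
  })
  chosen_k <- if (is.null(ksel)) k_grid else attr(ksel, "chosen_k")

  initial <- stage_fail("initial_clustering", {
    fits <- attr(ksel, "clusterings")
    if (!is.null(fits) && !is.null(fits[[as.character(chosen_k)]])) {
      fits[[as.character(chosen_k)]]
    } else {
      sdtw_kmeans(trajs, chosen_k, gamma = cfg$gamma,
                  seed = stage_seed(cfg$seed, 100 + match(chosen_k, k_grid)),
                  n_init = cfg$n_init, max_iter = cfg$kmeans_max_iter)
    }
  })

  fine <- stage_fail("dpgp_refinement", {
    noise_var <- replicate_noise_var(trajs)
    out <- vector("list", chosen_k)
    for (kc in seq_len(chosen_k)) {
      idx <- which(initial$assignment == kc)
      if (!length(idx)) next
      members <- trajs$y[idx, , drop = FALSE]
      hp <- gp_hyperparams(
        signal_var = max(stats::var(as.numeric(members)), 1e-4),
        length_scale = diff(range(trajs$time)) / 2,
        noise_var = noise_var)
      out[[kc]] <- dpgp_cluster(members, t = trajs$time,
                                alpha = cfg$dpgp_alpha,
                                max_num_iterations = cfg$dpgp_max_iter,
                                burn_frac = cfg$burn_frac, hp = hp,
                                seed = stage_seed(cfg$seed, 200 + kc),
                                parent_cluster = kc)
    }
    out
  })

  composite <- character(nrow(trajs$y))
  for (kc in seq_len(chosen_k)) {
    idx <- which(initial$assignment == kc)
    if (!length(idx)) next
    composite[idx] <- sprintf("K%d_D%d", kc, fine[[kc]]$partition)
  }

  validation <- stage_fail("validation", {
    tryCatch(validate_with_classifier(trajs$y, composite,
                                      split_frac = cfg$split_frac,
                                      seed = stage_seed(cfg$seed, 300),
                                      classifier = sdtw_1nn_classifier(cfg$gamma)),
             error = function(e) NULL)
  })

  labels_df <- stage_fail("replicate_labels", {
    dyn <- data.frame(gene_id = trajs$meta$gene_id,
                      condition = trajs$meta$condition,
                      replicate = trajs$meta$replicate,
                      label = composite, stringsAsFactors = FALSE)
    m <- max(gem$samples$replicate)
    off_rows <- do.call(rbind, lapply(c("control", "treated"), function(cond) {
      og <- off[[cond]]$off
      if (!length(og)) return(NULL)
      expand.grid(gene_id = og, condition = cond, replicate = seq_len(m),
                  stringsAsFactors = FALSE)
    }))
    if (!is.null(off_rows)) {
      off_rows$label <- "OFF"
      dyn <- rbind(dyn, off_rows)
    }
    dyn
  })

  shift <- stage_fail("shift_detection", {
    st <- compile_shift_table(labels_df, cfg$min_agree)
    if (cfg$drop_t0_shifts) {
      cents <- composite_centroids(trajs, composite)
      st$records <- drop_t0_driven_shifts(st$records, cents)
      st <- recount_shift_table(st)
    }
    st
  })

  sets <- stage_fail("trajectory_sets",
                     group_trajectory_sets(shift$records, cfg$set_prefix))

  enrichment <- stage_fail("enrichment", {
    if (is.null(cfg$annotations) || nrow(sets$members) == 0) NULL else {
      ann <- if (is.character(cfg$annotations)) {
        read_annotations(cfg$annotations)
      } else cfg$annotations
      enrich_sets(sets, ann, background = rownames(gem$values),
                  alpha = cfg$enrich_alpha)
    }
  })

  summary <- c(list(chosen_k = chosen_k,
                    n_trajectories = nrow(trajs$y),
                    n_trajectory_sets = nrow(sets$sets),
                    f1_weighted = if (is.null(validation)) NA else
                      validation$f1_weighted,
                    min_agree = cfg$min_agree, seed = cfg$seed),
               shift$summary)

  result <- structure(list(gem_norm = norm, off = off, trajectories = trajs,
                           k_report = ksel, chosen_k = chosen_k,
                           initial = initial, fine = fine,
                           labels = labels_df, validation = validation,
                           shift = shift, sets = sets,
                           enrichment = enrichment, summary = summary,
                           config = cfg),
                      class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(result, cfg$outdir)
  result
}

#' Replicate-based noise variance estimate
#'
#' Pools, over every (gene, condition) with at least two replicate
#' trajectories, the per-time-point variance across replicates, and takes
#' the median over gene-conditions (robust to the occasional discordant
#' replicate). This is the observation-noise variance handed to the DP-GP
#' refinement: biological replicates are the direct measurement of it.
#'
#' @param trajs a `trajectories` object.
#' @return noise variance (floored at 1e-4).
#' @export
replicate_noise_var <- function(trajs) {
  key <- paste(trajs$meta$gene_id, trajs$meta$condition)
  groups <- split(seq_len(nrow(trajs$y)), key)
  v <- vapply(groups, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(apply(trajs$y[idx, , drop = FALSE], 2, stats::var))
  }, numeric(1))
  v <- v[is.finite(v)]
  if (!length(v)) return(1e-4)
  max(stats::median(v), 1e-4)
}

# Euclidean mean trajectory per composite label (used by the optional
# first-time-point shift filter and the set plots)
composite_centroids <- function(trajs, composite) {
  out <- list()
  for (lab in unique(composite)) {
    out[[lab]] <- colMeans(trajs$y[composite == lab, , drop = FALSE])
  }
  out
}

recount_shift_table <- function(st) {
  compile_like <- st$records
  cat_n <- function(x) sum(compile_like$category == x)
  n_shift <- cat_n("A_off_to_dynamic") + cat_n("B_dynamic_to_off") +
    cat_n("C_dynamic_to_dynamic")
  st$summary <- list(
    n_genes = nrow(compile_like),
    n_off_control = sum(compile_like$control_label == "OFF"),
    n_off_treated = sum(compile_like$treated_label == "OFF"),
    n_off_both = cat_n("off_both"),
    n_unqualified = cat_n("unqualified"),
    n_qualified_both = n_shift + cat_n("non_shift"),
    n_shift = n_shift,
    n_A_off_to_dynamic = cat_n("A_off_to_dynamic"),
    n_B_dynamic_to_off = cat_n("B_dynamic_to_off"),
    n_C_dynamic_to_dynamic = cat_n("C_dynamic_to_dynamic"),
    n_non_shift = cat_n("non_shift"))
  st
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(df, name) {
    data.table::fwrite(df, file.path(outdir, name), sep = "\t")
  }
  write_gem(result$gem_norm, file.path(outdir, "gem_normalized.tsv"))
  off_df <- do.call(rbind, lapply(c("control", "treated"), function(cond) {
    og <- result$off[[cond]]$off
    if (!length(og)) return(NULL)
    data.frame(gene_id = og, condition = cond)
  }))
  if (!is.null(off_df)) fw(off_df, "off_genes.tsv")
  fw(result$labels, "trajectory_labels.tsv")
  if (!is.null(result$k_report)) {
    fw(as.data.frame(result$k_report), "k_selection.tsv")
  }
  fw(result$shift$records, "shift_table.tsv")
  fw(result$sets$sets, "trajectory_sets.tsv")
  fw(result$sets$members, "trajectory_set_members.tsv")
  if (!is.null(result$enrichment)) fw(result$enrichment, "enrichment.tsv")
  if (!is.null(result$validation)) {
    jsonlite::write_json(
      list(f1_weighted = result$validation$f1_weighted,
           excluded_classes = result$validation$excluded_classes,
           confusion = as.data.frame.matrix(result$validation$confusion)),
      file.path(outdir, "validation.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("trajshift %s", as.character(utils::packageVersion("trajshift"))),
    sprintf("seed: %d", result$config$seed),
    sprintf("chosen_k: %d", result$chosen_k),
    sprintf("min_agree: %d", result$config$min_agree),
    sprintf("gamma: %g", result$config$gamma))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline result: %d genes, chosen k = %d, %d trajectory sets\n",
              s$n_genes, s$chosen_k, s$n_trajectory_sets))
  cat(sprintf("  shift genes: %d (A %d, B %d, C %d); non-shift: %d; off both: %d; unqualified: %d\n",
              s$n_shift, s$n_A_off_to_dynamic, s$n_B_dynamic_to_off,
              s$n_C_dynamic_to_dynamic, s$n_non_shift, s$n_off_both,
              s$n_unqualified))
  invisible(x)
}
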