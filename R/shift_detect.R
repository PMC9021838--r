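#' Consensus trajectory label by replicate sorting
#'
#' Returns the trajectory-cluster label shared by at least `min_agree` of a
#' gene's replicates under one condition, or `"UNQUALIFIED"` when no label
#' reaches that agreement. `min_agree` must exceed half the replicate count
#' so that the consensus, when it exists, is unique; no replicate averaging
#' is ever performed.
#'
#' @param labels character vector of per-replicate labels (length m); the
#'   reserved label `"OFF"` marks an unexpressed replicate profile.
#' @param min_agree required number of agreeing replicates (2 or 3 for
#'   m = 3).
#' @return the consensus label, or `"UNQUALIFIED"`.
#' @export
sort_replicates <- function(labels, min_agree) {
  m <- length(labels)
  if (min_agree > m) stop("min_agree cannot exceed the replicate count")
  if (min_agree <= m / 2) {
    stop("min_agree must exceed half the replicate count (ambiguous consensus)")
  }
  tab <- table(labels)
  top <- which.max(tab)
  if (tab[top] >= min_agree) names(tab)[top] else "UNQUALIFIED"
}

#' Categorize a between-condition pattern shift
#'
#' Pure function of the two consensus labels:
#' off -> dynamic is category A, dynamic -> off category B, two different
#' dynamic labels category C, identical dynamic labels `non_shift`, off in
#' both conditions `off_both` (excluded from shift statistics), and any
#' unqualified side `unqualified`.
#'
#' @param control,treated consensus labels (`"OFF"`, `"UNQUALIFIED"`, or a
#'   dynamic composite label such as `"K3_D1"`).
#' @return one of `"A_off_to_dynamic"`, `"B_dynamic_to_off"`,
#'   `"C_dynamic_to_dynamic"`, `"non_shift"`, `"off_both"`, `"unqualified"`.
#' @export
classify_shift <- function(control, treated) {
  if (control == "UNQUALIFIED" || treated == "UNQUALIFIED") return("unqualified")
  c_off <- control == "OFF"; t_off <- treated == "OFF"
  if (c_off && t_off) return("off_both")
  if (c_off) return("A_off_to_dynamic")
  if (t_off) return("B_dynamic_to_off")
  if (control == treated) return("non_shift")
  "C_dynamic_to_dynamic"
}

#' Compile the per-gene shift table
#'
#' Applies replicate sorting per condition, categorizes every gene, and
#' produces the summary counts: total genes, off genes per condition,
#' genes qualified in both conditions, shift genes (A + B + C) and
#' non-shift genes. The identities `shift = A + B + C` and
#' `qualified = shift + non_shift` always hold.
#'
#' @param labels_df data.frame with columns `gene_id`, `condition`
#'   (`"control"`/`"treated"`), `replicate`, `label` (per-replicate
#'   trajectory labels, `"OFF"` for unexpressed profiles).
#' @param min_agree replicate-agreement threshold passed to
#'   [sort_replicates()].
#' @return a `shift_table`: list with `records` (one row per gene:
#'   `gene_id`, `control_label`, `treated_label`, `category`,
#'   `n_agree_control`, `n_agree_treated`) and `summary` (named count list).
#' @export
compile_shift_table <- function(labels_df, min_agree) {
  need <- c("gene_id", "condition", "replicate", "label")
  stopifnot(all(need %in% names(labels_df)))
  genes <- unique(labels_df$gene_id)
  split_gc <- split(labels_df, list(labels_df$gene_id, labels_df$condition),
                    drop = TRUE)
  consensus <- function(gene, cond) {
    key <- paste(gene, cond, sep = ".")
    sub <- split_gc[[key]]
    if (is.null(sub)) stop("gene '", gene, "' has no labels for condition '",
                           cond, "'")
    lab <- sort_replicates(sub$label, min_agree)
    n_agree <- max(table(sub$label))
    list(label = lab, n_agree = as.integer(n_agree))
  }
  records <- do.call(rbind, lapply(genes, function(g) {
    ctl <- consensus(g, "control")
    trt <- consensus(g, "treated")
    data.frame(gene_id = g, control_label = ctl$label,
               treated_label = trt$label,
               category = classify_shift(ctl$label, trt$label),
               n_agree_control = ctl$n_agree, n_agree_treated = trt$n_agree,
               stringsAsFactors = FALSE)
  }))
  cat_n <- function(x) sum(records$category == x)
  n_shift <- cat_n("A_off_to_dynamic") + cat_n("B_dynamic_to_off") +
    cat_n("C_dynamic_to_dynamic")
  summary <- list(
    n_genes = nrow(records),
    n_off_control = sum(records$control_label == "OFF"),
    n_off_treated = sum(records$treated_label == "OFF"),
    n_off_both = cat_n("off_both"),
    n_unqualified = cat_n("unqualified"),
    n_qualified_both = n_shift + cat_n("non_shift"),
    n_shift = n_shift,
    n_A_off_to_dynamic = cat_n("A_off_to_dynamic"),
    n_B_dynamic_to_off = cat_n("B_dynamic_to_off"),
    n_C_dynamic_to_dynamic = cat_n("C_dynamic_to_dynamic"),
    n_non_shift = cat_n("non_shift")
  )
  structure(list(records = records, summary = summary, min_agree = min_agree),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("shift table (%d/%d replicate sorting): %d genes\n",
              x$min_agree, max(c(x$records$n_agree_control, 3)), s$n_genes))
  cat(sprintf("  qualified in both conditions: %d; shift: %d (A %d, B %d, C %d); non-shift: %d\n",
              s$n_qualified_both, s$n_shift, s$n_A_off_to_dynamic,
              s$n_B_dynamic_to_off, s$n_C_dynamic_to_dynamic, s$n_non_shift))
  cat(sprintf("  off in both: %d; unqualified: %d\n", s$n_off_both, s$n_unqualified))
  invisible(x)
}

#' Group qualified genes into trajectory sets
#'
#' Genes sharing an identical (control label, treated label) signature form
#' one trajectory set; sets are named `{prefix}{rank}` by descending size
#' (rank starting at 0), ties broken by the lexicographic order of the
#' signature string.
#'
#' @param records the `records` data.frame of a [compile_shift_table()]
#'   result (or the `shift_table` itself); rows with category
#'   `unqualified` or `off_both` are dropped.
#' @param prefix set-name prefix (e.g. `"R"` for root, `"S"` for shoot).
#' @return list with `sets` (data.frame `set_id`, `control_label`,
#'   `treated_label`, `category`, `size`) and `members` (data.frame
#'   `set_id`, `gene_id`).
#' @export
group_trajectory_sets <- function(records, prefix = "R") {
  if (inherits(records, "shift_table")) records <- records$records
  keep <- !(records$category %in% c("unqualified", "off_both"))
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(list(sets = data.frame(set_id = character(0),
                                  control_label = character(0),
                                  treated_label = character(0),
                                  category = character(0),
                                  size = integer(0)),
                members = data.frame(set_id = character(0),
                                     gene_id = character(0))))
  }
  sig <- paste(rec$control_label, rec$treated_label, sep = "->")
  tab <- aggregate(rec$gene_id, by = list(signature = sig), FUN = length)
  names(tab)[2] <- "size"
  ord <- order(-tab$size, tab$signature)
  tab <- tab[ord, , drop = FALSE]
  tab$set_id <- paste0(prefix, seq_len(nrow(tab)) - 1)
  first <- match(tab$signature, sig)
  sets <- data.frame(set_id = tab$set_id,
                     control_label = rec$control_label[first],
                     treated_label = rec$treated_label[first],
                     category = rec$category[first],
                     size = tab$size, stringsAsFactors = FALSE)
  members <- data.frame(
    set_id = tab$set_id[match(sig, tab$signature)],
    gene_id = rec$gene_id, stringsAsFactors = FALSE)
  members <- members[order(match(members$set_id, tab$set_id), members$gene_id), ]
  rownames(members) <- NULL
  list(sets = sets, members = members)
}

#' Flag shifts driven only by the first time point
#'
#' Optional heuristic filter: a C-category shift whose control and treated
#' label centroids differ almost entirely at the first time point (the
#' absolute difference at t0 accounts for at least `threshold` of the total
#' L1 centroid difference) is often a start-point artifact. Returns the
#' records with such shifts recategorized as `non_shift`.
#'
#' @param records shift records (see [group_trajectory_sets()]).
#' @param label_centroids named list mapping dynamic composite labels to
#'   centroid series.
#' @param threshold fraction of the total L1 difference attributable to t0
#'   (default 0.8).
#' @return the records data.frame with filtered categories.
#' @export
drop_t0_driven_shifts <- function(records, label_centroids, threshold = 0.8) {
  if (inherits(records, "shift_table")) records <- records$records
  is_c <- records$category == "C_dynamic_to_dynamic"
  for (i in which(is_c)) {
    a <- label_centroids[[records$control_label[i]]]
    b <- label_centroids[[records$treated_label[i]]]
    if (is.null(a) || is.null(b)) next
    d <- abs(a - b)
    if (sum(d) > 0 && d[1] / sum(d) >= threshold) {
      records$category[i] <- "non_shift"
    }
  }
  records
}
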