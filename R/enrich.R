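#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `vocabulary`, `term_id`,
#'   `term_name` (header required).
#' @return data.frame annotation table.
#' @export
read_annotations <- function(path) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "vocabulary", "term_id", "term_name")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  ann
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Hypergeometric upper-tail probability P(X >= a) for the 2x2 table
#' `[a b; c d]` with fixed margins: a = in-set annotated, b = in-set not
#' annotated, c = annotated outside the set, d = the remainder.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return p-value in [0, 1].
#' @export
fisher_right_tail <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are returned in input
#' order, clipped at 1, and never smaller than the raw p-values.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) && (any(pvals < 0) || any(pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Functional-term enrichment of trajectory sets
#'
#' Tests every (trajectory set, term) pair where the term annotates at
#' least one set member, with the one-sided Fisher (hypergeometric) test
#' against the background gene universe, and applies Benjamini-Hochberg
#' correction within each vocabulary (GO, KEGG, IPR, ... separately by
#' default). Sets smaller than `min_set_size` are skipped.
#'
#' @param sets result of [group_trajectory_sets()] (list with `sets` and
#'   `members`), or a data.frame with columns `set_id`, `gene_id`.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param background character vector: the gene universe (all set members
#'   must belong to it).
#' @param alpha adjusted-p significance threshold (default 0.001).
#' @param per_vocabulary apply BH within each vocabulary (default TRUE) or
#'   globally.
#' @param min_set_size smallest set tested (default 2).
#' @return data.frame with one row per tested (set, term): `set_id`,
#'   `vocabulary`, `term_id`, `term_name`, counts `a`,`b`,`c`,`d`,
#'   `p_raw`, `p_adj`, `enriched`; sorted by `p_adj`.
#' @export
enrich_sets <- function(sets, annotations, background, alpha = 0.001,
                        per_vocabulary = TRUE, min_set_size = 2) {
  members <- if (is.data.frame(sets)) sets else sets$members
  stopifnot(all(c("set_id", "gene_id") %in% names(members)))
  outside <- setdiff(members$gene_id, background)
  if (length(outside)) {
    stop("set member gene outside the background: ", outside[1])
  }
  background <- unique(background)
  n_bg <- length(background)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  term_key <- paste(ann$vocabulary, ann$term_id)
  term_genes <- split(ann$gene_id, term_key)
  term_info <- ann[!duplicated(term_key), c("vocabulary", "term_id", "term_name")]
  rownames(term_info) <- unique(term_key)

  rows <- list()
  for (sid in unique(members$set_id)) {
    set_genes <- unique(members$gene_id[members$set_id == sid])
    if (length(set_genes) < min_set_size) next
    for (tk in names(term_genes)) {
      tg <- unique(term_genes[[tk]])
      a <- length(intersect(set_genes, tg))
      if (a == 0) next  # terms annotating no set member are not tested
      b <- length(set_genes) - a
      c_ <- length(tg) - a
      d <- n_bg - a - b - c_
      rows[[length(rows) + 1]] <- data.frame(
        set_id = sid, vocabulary = term_info[tk, "vocabulary"],
        term_id = term_info[tk, "term_id"],
        term_name = term_info[tk, "term_name"],
        a = a, b = b, c = c_, d = d,
        p_raw = fisher_right_tail(a, b, c_, d),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(set_id = character(0), vocabulary = character(0),
                      term_id = character(0), term_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      enriched = logical(0)))
  }
  res <- do.call(rbind, rows)
  if (per_vocabulary) {
    res$p_adj <- NA_real_
    for (v in unique(res$vocabulary)) {
      sel <- res$vocabulary == v
      res$p_adj[sel] <- bh_adjust(res$p_raw[sel])
    }
  } else {
    res$p_adj <- bh_adjust(res$p_raw)
  }
  res$enriched <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$p_raw, res$set_id, res$term_id), ]
  rownames(res) <- NULL
  res
}
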