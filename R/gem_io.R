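#' Construct an expression matrix object
#'
#' Container for a genes x samples abundance matrix with per-sample metadata
#' (condition, time in hours, replicate index). On the `"fpkm"` scale all
#' values must be non-negative; `"quantile_log2"` marks a matrix that has
#' been quantile-normalized and log2(x + 1) transformed.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"control"` or `"treated"`), `time` (hours), `replicate` (integer),
#'   one row per column of `values`, in column order.
#' @param scale `"fpkm"` or `"quantile_log2"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples, scale = c("fpkm", "quantile_log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("values must have gene IDs as rownames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene id in expression matrix")
  if (anyNA(values)) stop("expression matrix contains missing cells")
  if (scale == "fpkm" && any(values < 0)) stop("negative values on fpkm scale")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "time", "replicate")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) stop("samples rows must match value columns")
  if (!all(samples$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'")
  }
  if (any(samples$time < 0)) stop("time must be non-negative")
  if (any(samples$replicate < 1)) stop("replicate index must be positive")
  key <- paste(samples$condition, samples$time, samples$replicate)
  if (anyDuplicated(key)) stop("duplicate (condition, time, replicate) sample")
  # both conditions must cover the same time grid with equal replicate counts
  for (cond in unique(samples$condition)) {
    sub <- samples[samples$condition == cond, ]
    grid <- sort(unique(sub$time))
    reps <- sort(unique(sub$replicate))
    if (nrow(sub) != length(grid) * length(reps) ||
        !all(table(sub$time) == length(reps))) {
      stop("incomplete design for condition '", cond, "'")
    }
  }
  grids <- lapply(split(samples$time, samples$condition), function(x) sort(unique(x)))
  if (length(grids) > 1 && !all(vapply(grids, identical, TRUE, y = grids[[1]]))) {
    stop("conditions do not share the same time grid")
  }
  structure(list(values = values, samples = samples, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  conditions: %s; time grid: %s h; replicates: %s\n",
              paste(unique(x$samples$condition), collapse = ", "),
              paste(sort(unique(x$samples$time)), collapse = ", "),
              max(x$samples$replicate)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# turn a "{condition}_{time}h_r{rep}" style template into a regex with
# one capture group per placeholder
label_pattern_regex <- function(label_pattern) {
  tokens <- c(condition = "([A-Za-z]+)",
              time = "([0-9]+(?:\\.[0-9]+)?)",
              rep = "([0-9]+)")
  # split the template into literal runs and placeholders
  parts <- regmatches(label_pattern,
                      gregexpr("\\{(condition|time|rep)\\}|[^{}]+", label_pattern))[[1]]
  order <- character(0)
  rx <- "^"
  for (p in parts) {
    key <- sub("^\\{(.*)\\}$", "\\1", p)
    if (key %in% names(tokens) && grepl("^\\{", p)) {
      rx <- paste0(rx, tokens[[key]])
      order <- c(order, key)
    } else {
      rx <- paste0(rx, gsub("([.^$*+?()\\[\\]|\\\\])", "\\\\\\1", p))
    }
  }
  if (!all(c("condition", "time", "rep") %in% order)) {
    stop("label_pattern must contain {condition}, {time} and {rep}")
  }
  list(regex = paste0(rx, "$"), order = order)
}

default_condition_map <- c(
  control = "control", ctrl = "control", ctl = "control", c = "control",
  uninoculated = "control", mock = "control", untreated = "control",
  treated = "treated", treat = "treated", trt = "treated", t = "treated",
  inoculated = "treated", rhizobia = "treated"
)

#' Parse sample metadata from sample names
#'
#' @param sample_names character vector of column names.
#' @param label_pattern template with `{condition}`, `{time}` and `{rep}`
#'   placeholders, e.g. `"{condition}_{time}h_r{rep}"`.
#' @param condition_map optional named character vector mapping raw condition
#'   tokens (lower-cased) to `"control"`/`"treated"`; common synonyms
#'   (ctrl, mock, inoculated, ...) are built in.
#' @return data.frame of SampleMeta rows.
#' @export
parse_sample_names <- function(sample_names,
                               label_pattern = "{condition}_{time}h_r{rep}",
                               condition_map = NULL) {
  pat <- label_pattern_regex(label_pattern)
  cmap <- default_condition_map
  if (!is.null(condition_map)) cmap[tolower(names(condition_map))] <- condition_map
  out <- data.frame(sample_id = sample_names, condition = NA_character_,
                    time = NA_real_, replicate = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sample_names)) {
    m <- regmatches(sample_names[i], regexec(pat$regex, sample_names[i]))[[1]]
    if (length(m) == 0) {
      stop("sample name '", sample_names[i],
           "' does not match label pattern '", label_pattern, "'")
    }
    caps <- setNames(m[-1], pat$order)
    raw <- tolower(caps[["condition"]])
    if (!raw %in% names(cmap)) {
      stop("sample name '", sample_names[i], "': unknown condition token '",
           caps[["condition"]], "'")
    }
    out$condition[i] <- unname(cmap[[raw]])
    out$time[i] <- as.numeric(caps[["time"]])
    out$replicate[i] <- as.integer(caps[["rep"]])
  }
  out
}

#' Read a gene expression matrix from TSV
#'
#' The file must be tab-separated with a header of sample names and the gene
#' identifier in the first column. Sample condition / time / replicate are
#' parsed from the names via `label_pattern`, or taken from an explicit
#' sample sheet.
#'
#' @inheritParams parse_sample_names
#' @param path TSV file path.
#' @param sample_sheet optional data.frame (or TSV path) with columns
#'   `sample_id`, `condition`, `time`, `replicate`, overriding name parsing.
#' @return An [expression_matrix()] on the fpkm scale, sample order preserved.
#' @export
read_gem <- function(path, label_pattern = "{condition}_{time}h_r{rep}",
                     sample_sheet = NULL, condition_map = NULL) {
  if (!file.exists(path)) stop("GEM file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, " at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1], ")")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  gene_ids <- as.character(dt[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  }
  vals <- as.matrix(dt[, -1, drop = FALSE])
  rownames(vals) <- gene_ids
  if (!is.null(sample_sheet)) {
    if (is.character(sample_sheet)) {
      sample_sheet <- data.table::fread(sample_sheet, sep = "\t", data.table = FALSE)
    }
    idx <- match(colnames(vals), sample_sheet$sample_id)
    if (anyNA(idx)) {
      stop("sample '", colnames(vals)[is.na(idx)][1], "' missing from sample sheet")
    }
    meta <- sample_sheet[idx, c("sample_id", "condition", "time", "replicate")]
  } else {
    meta <- parse_sample_names(colnames(vals), label_pattern, condition_map)
  }
  expression_matrix(vals, meta, scale = "fpkm")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to the same empirical distribution (the
#' per-rank across-sample means); ties within a column receive the mean of
#' the reference values over their tied ranks. Gene and sample order are
#' unchanged.
#'
#' @param gem an [expression_matrix()] on the fpkm scale.
#' @return the normalized `ExpressionMatrix`, still flagged fpkm scale.
#' @export
quantile_normalize <- function(gem) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (gem$scale != "fpkm") stop("quantile_normalize expects an fpkm-scale matrix")
  if (nrow(gem$values) == 0 || ncol(gem$values) == 0) stop("empty expression matrix")
  norm <- limma::normalizeQuantiles(gem$values, ties = TRUE)
  dimnames(norm) <- dimnames(gem$values)
  gem$values <- norm
  gem
}

#' Log2(x + pseudocount) transform
#'
#' @param gem an [expression_matrix()] with non-negative values.
#' @param pseudocount added before taking log2 (default 1).
#' @return the transformed `ExpressionMatrix`, flagged `"quantile_log2"`.
#' @export
log_transform <- function(gem, pseudocount = 1) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (any(gem$values < 0)) stop("negative input value in log_transform")
  gem$values <- log2(gem$values + pseudocount)
  gem$scale <- "quantile_log2"
  gem
}

#' Extract unexpressed ("off") genes for one condition
#'
#' A gene is called off under a condition when at least `min_zero_replicates`
#' of its biological replicates are exactly zero at every measured time
#' point of that condition. The test runs on raw FPKM values, before any
#' normalization (which would destroy exact zeros).
#'
#' @param gem an [expression_matrix()] on the fpkm scale.
#' @param condition `"control"` or `"treated"`.
#' @param min_zero_replicates minimum all-zero replicates to call a gene off
#'   (default 1).
#' @return list with character vectors `off` and `active`, a partition of
#'   the gene IDs.
#' @export
extract_off_genes <- function(gem, condition, min_zero_replicates = 1) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (gem$scale != "fpkm") stop("off-gene extraction runs on the fpkm scale")
  if (!condition %in% gem$samples$condition) {
    stop("condition '", condition, "' absent from expression matrix")
  }
  sub <- gem$samples$condition == condition
  meta <- gem$samples[sub, ]
  vals <- gem$values[, sub, drop = FALSE]
  reps <- sort(unique(meta$replicate))
  zero_reps <- matrix(FALSE, nrow(vals), length(reps))
  for (r in seq_along(reps)) {
    cols <- meta$replicate == reps[r]
    zero_reps[, r] <- rowSums(vals[, cols, drop = FALSE] != 0) == 0
  }
  n_zero <- rowSums(zero_reps)
  off <- rownames(vals)[n_zero >= min_zero_replicates]
  list(off = off, active = setdiff(rownames(vals), off))
}

#' Build per-replicate trajectories
#'
#' One trajectory per (gene, condition, replicate), values ordered by time.
#'
#' @param gem an [expression_matrix()] on the `"quantile_log2"` scale.
#' @param genes character vector of gene IDs (subset of the matrix rows).
#' @return a `trajectories` object: list with `meta` (data.frame gene_id,
#'   condition, replicate), `y` (trajectories x time matrix) and `time`
#'   (the ordered grid).
#' @export
build_trajectories <- function(gem, genes = rownames(gem$values)) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (gem$scale != "quantile_log2") {
    stop("build_trajectories expects a quantile_log2-scale matrix")
  }
  missing <- setdiff(genes, rownames(gem$values))
  if (length(missing)) stop("gene absent from expression matrix: ", missing[1])
  grid <- sort(unique(gem$samples$time))
  conds <- sort(unique(gem$samples$condition))
  reps <- sort(unique(gem$samples$replicate))
  meta <- expand.grid(replicate = reps, condition = conds, gene_id = genes,
                      stringsAsFactors = FALSE)[, c("gene_id", "condition", "replicate")]
  y <- matrix(NA_real_, nrow(meta), length(grid))
  for (cond in conds) {
    for (r in reps) {
      sel <- gem$samples$condition == cond & gem$samples$replicate == r
      cols <- which(sel)[order(gem$samples$time[sel])]
      rows <- meta$condition == cond & meta$replicate == r
      y[rows, ] <- gem$values[genes, cols, drop = FALSE]
    }
  }
  structure(list(meta = meta, y = y, time = grid), class = "trajectories")
}

#' @export
print.trajectories <- function(x, ...) {
  cat(sprintf("%d trajectories over %d time points (%s h)\n",
              nrow(x$meta), length(x$time), paste(x$time, collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix to TSV
#' @param gem an [expression_matrix()].
#' @param path output file.
#' @export
write_gem <- function(gem, path) {
  df <- data.frame(gene_id = rownames(gem$values), gem$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
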