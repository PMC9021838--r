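# programmatic fixtures

# tiny complete-design expression matrix: 2 conditions x times x reps
make_test_gem <- function(values, times = c(0, 12), reps = 1,
                          genes = paste0("g", seq_len(nrow(values)))) {
  conds <- c("control", "treated")
  meta <- expand.grid(replicate = seq_len(reps), time = times,
                      condition = conds,
                      stringsAsFactors = FALSE)[, c("condition", "time", "replicate")]
  meta$sample_id <- sprintf("%s_%gh_r%d", meta$condition, meta$time,
                            meta$replicate)
  stopifnot(ncol(values) == nrow(meta))
  if (nrow(values) > 0) rownames(values) <- genes
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta[, c("sample_id", "condition", "time",
                                     "replicate")], scale = "fpkm")
}

write_test_gem_tsv <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}

# three well-separated 5-point shapes for clustering fixtures
test_shapes <- rbind(c(0, 0, 0, 2, 4),
                     c(4, 4, 0, 0, 0),
                     c(0, 4, 0, 4, 0))

noisy_shape_series <- function(n_per_shape, sd = 0.1, seed = 1,
                               shapes = test_shapes) {
  set.seed(seed)
  n <- n_per_shape * nrow(shapes)
  Y <- shapes[rep(seq_len(nrow(shapes)), each = n_per_shape), ] +
    matrix(rnorm(n * ncol(shapes), 0, sd), n, ncol(shapes))
  list(y = Y, labels = rep(seq_len(nrow(shapes)), each = n_per_shape))
}
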