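test_that("read_gem parses a small TSV and its sample names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_test_gem_tsv(path,
    "gene\tctrl_0h_r1\tctrl_12h_r1\ttreat_0h_r1\ttreat_12h_r1",
    c("g1\t1\t2\t3\t4", "g2\t0\t0\t0\t0", "g3\t5.5\t1\t2\t8"))
  gem <- read_gem(path)
  expect_s3_class(gem, "ExpressionMatrix")
  expect_equal(dim(gem), c(3L, 4L))
  expect_setequal(unique(gem$samples$condition), c("control", "treated"))
  expect_equal(gem$samples$time, c(0, 12, 0, 12))
  expect_equal(colnames(gem$values),
               c("ctrl_0h_r1", "ctrl_12h_r1", "treat_0h_r1", "treat_12h_r1"))
})

test_that("read_gem rejects malformed input with informative errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  write_test_gem_tsv(dup, "gene\tctrl_0h_r1\ttreat_0h_r1",
                     c("g1\t1\t2", "g1\t3\t4"))
  expect_error(read_gem(dup), "duplicate gene id")

  badname <- withr::local_tempfile(fileext = ".tsv")
  write_test_gem_tsv(badname, "gene\tctrl_0h_r1\tX_banana_7",
                     c("g1\t1\t2"))
  expect_error(read_gem(badname), "X_banana_7")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  write_test_gem_tsv(ragged, "gene\tctrl_0h_r1\ttreat_0h_r1",
                     c("g1\t1\t2", "g2\t1", "g3\t2\t3"))
  expect_error(read_gem(ragged), "line 3")
})

test_that("quantile normalization matches the rank/mean oracle and is idempotent", {
  gem <- make_test_gem(cbind(c(5, 2, 3), c(4, 1, 6)), times = 0, reps = 1)
  qn <- quantile_normalize(gem)
  expect_equal(unname(qn$values[, 1]), c(5.5, 1.5, 3.5))
  expect_equal(unname(qn$values[, 2]), c(3.5, 1.5, 5.5))

  set.seed(3)
  gem2 <- make_test_gem(matrix(rexp(40), 10, 4))
  once <- quantile_normalize(gem2)
  twice <- quantile_normalize(once)
  expect_lt(max(abs(once$values - twice$values)), 1e-12)
  # every column shares the same sorted value multiset
  sorted <- apply(once$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)

  single <- make_test_gem(matrix(c(3, 1, 7), 3, 2), times = 0)
  # two identical columns: unchanged up to the shared distribution
  qs <- quantile_normalize(single)
  expect_equal(sort(qs$values[, 1]), sort(single$values[, 1]))

  empty <- make_test_gem(matrix(numeric(0), 0, 2), times = 0)
  expect_error(quantile_normalize(empty), "empty")
})

test_that("log transform is log2(x + 1) and flags the scale", {
  gem <- make_test_gem(cbind(c(0, 1), c(3, 7)), times = 0)
  lt <- log_transform(gem)
  expect_equal(unname(lt$values), cbind(c(0, 1), c(2, 3)))
  expect_identical(lt$scale, "quantile_log2")
  gem$values[1, 1] <- -1
  expect_error(log_transform(gem), "negative")
})

test_that("off-gene extraction follows the all-zero-replicate rule", {
  # 2 conditions x 2 times x 3 reps, 3 genes
  vals <- matrix(1, 3, 12)
  gem0 <- make_test_gem(vals, times = c(0, 12), reps = 3)
  ctl <- gem0$samples$condition == "control"
  # gene 1: replicate 1 all-zero under control, reps 2-3 nonzero
  r1 <- ctl & gem0$samples$replicate == 1
  gem0$values[1, r1] <- 0
  # gene 2: one zero at a single time point in every replicate
  t0 <- ctl & gem0$samples$time == 0
  gem0$values[2, t0] <- 0
  off <- extract_off_genes(gem0, "control")
  expect_setequal(off$off, "g1")
  expect_setequal(off$active, c("g2", "g3"))
  # the partition covers all genes
  expect_setequal(c(off$off, off$active), rownames(gem0$values))
  # impossible threshold (m + 1) gives an empty off set
  expect_length(extract_off_genes(gem0, "control", 4)$off, 0)
  expect_error(extract_off_genes(gem0, "mystery"), "mystery")
})

test_that("trajectory construction counts and time-orders correctly", {
  gem <- make_test_gem(matrix(seq_len(24), 2, 12), times = c(0, 12),
                       reps = 3)
  norm <- log_transform(gem)
  tr <- build_trajectories(norm)
  expect_equal(nrow(tr$meta), 2 * 2 * 3)
  expect_equal(nrow(tr$y), nrow(tr$meta))
  expect_error(build_trajectories(norm, "nope"), "nope")
  empty <- build_trajectories(norm, character(0))
  expect_equal(nrow(empty$meta), 0)

  # shuffled sample columns still give time-sorted trajectories
  perm <- sample(ncol(gem$values))
  gem2 <- expression_matrix(gem$values[, perm], gem$samples[perm, ],
                            scale = "fpkm")
  tr2 <- build_trajectories(log_transform(gem2))
  key <- function(t) paste(t$meta$gene_id, t$meta$condition, t$meta$replicate)
  expect_equal(tr2$y[order(key(tr2)), ], tr$y[order(key(tr)), ])
  # untransformed input is refused
  expect_error(build_trajectories(gem), "quantile_log2")
})
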