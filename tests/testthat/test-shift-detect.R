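test_that("replicate sorting reproduces the 2/3 and 3/3 behaviors", {
  expect_equal(sort_replicates(c("L1", "L1", "L1"), 3), "L1")
  expect_equal(sort_replicates(c("L1", "L1", "L2"), 3), "UNQUALIFIED")
  expect_equal(sort_replicates(c("L1", "L1", "L2"), 2), "L1")
  expect_equal(sort_replicates(c("L1", "L2", "L3"), 2), "UNQUALIFIED")
  expect_equal(sort_replicates(c("L1", "L2", "L3"), 3), "UNQUALIFIED")
  expect_equal(sort_replicates(c("OFF", "OFF", "OFF"), 3), "OFF")
  expect_error(sort_replicates(c("L1", "L2"), 1), "half")
  expect_error(sort_replicates(c("L1", "L2"), 3), "replicate count")
})

test_that("shift categories agree with the combinatorial truth table", {
  expect_equal(classify_shift("OFF", "K3_D1"), "A_off_to_dynamic")
  expect_equal(classify_shift("K3_D1", "OFF"), "B_dynamic_to_off")
  expect_equal(classify_shift("K3_D1", "K7_D0"), "C_dynamic_to_dynamic")
  expect_equal(classify_shift("K3_D1", "K3_D1"), "non_shift")
  expect_equal(classify_shift("OFF", "OFF"), "off_both")
  # exhaustive over label-pair types
  labs <- c("OFF", "UNQUALIFIED", "K1_D1", "K2_D1")
  for (a in labs) for (b in labs) {
    got <- classify_shift(a, b)
    want <- if (a == "UNQUALIFIED" || b == "UNQUALIFIED") "unqualified"
    else if (a == "OFF" && b == "OFF") "off_both"
    else if (a == "OFF") "A_off_to_dynamic"
    else if (b == "OFF") "B_dynamic_to_off"
    else if (a == b) "non_shift"
    else "C_dynamic_to_dynamic"
    expect_equal(got, want)
    # swapping condition roles maps A <-> B and fixes the rest
    swapped <- classify_shift(b, a)
    mapped <- c(A_off_to_dynamic = "B_dynamic_to_off",
                B_dynamic_to_off = "A_off_to_dynamic")[got]
    if (!is.na(mapped)) expect_equal(swapped, unname(mapped))
    else expect_equal(swapped, got)
  }
})

make_labels_df <- function(per_gene) {
  do.call(rbind, lapply(names(per_gene), function(g) {
    x <- per_gene[[g]]
    data.frame(gene_id = g,
               condition = rep(c("control", "treated"), each = 3),
               replicate = rep(1:3, 2),
               label = c(x$control, x$treated), stringsAsFactors = FALSE)
  }))
}

test_that("the shift table reproduces constructed categories and identities", {
  df <- make_labels_df(list(
    gA = list(control = rep("OFF", 3), treated = rep("K1_D1", 3)),
    gB = list(control = rep("K1_D1", 3), treated = rep("OFF", 3)),
    gC = list(control = rep("K1_D1", 3), treated = rep("K2_D1", 3)),
    gN = list(control = rep("K1_D1", 3), treated = rep("K1_D1", 3)),
    gO = list(control = rep("OFF", 3), treated = rep("OFF", 3)),
    gU = list(control = c("K1_D1", "K2_D1", "K3_D1"),
              treated = rep("K1_D1", 3))))
  st <- compile_shift_table(df, 3)
  s <- st$summary
  expect_equal(s$n_A_off_to_dynamic, 1)
  expect_equal(s$n_B_dynamic_to_off, 1)
  expect_equal(s$n_C_dynamic_to_dynamic, 1)
  expect_equal(s$n_non_shift, 1)
  expect_equal(s$n_off_both, 1)
  expect_equal(s$n_unqualified, 1)
  expect_equal(s$n_shift, 3)
  expect_equal(s$n_qualified_both, s$n_shift + s$n_non_shift)
  # all genes off in both conditions
  alloff <- make_labels_df(list(g1 = list(control = rep("OFF", 3),
                                          treated = rep("OFF", 3))))
  st0 <- compile_shift_table(alloff, 3)
  expect_equal(st0$summary$n_qualified_both, 0)
  expect_equal(st0$summary$n_shift, 0)
  # a gene with one condition missing errors
  half <- df[df$gene_id != "gA" | df$condition != "treated", ]
  expect_error(compile_shift_table(half, 3), "gA")
})

test_that("summary identities and 2/3 superset property hold on random tables", {
  set.seed(14)
  labs <- c("OFF", "K1_D1", "K1_D2", "K2_D1")
  for (rep_i in 1:10) {
    per_gene <- lapply(seq_len(30), function(i) {
      list(control = sample(labs, 3, replace = TRUE),
           treated = sample(labs, 3, replace = TRUE))
    })
    names(per_gene) <- paste0("g", seq_len(30))
    df <- make_labels_df(per_gene)
    st3 <- compile_shift_table(df, 3)
    st2 <- compile_shift_table(df, 2)
    expect_equal(st3$summary$n_qualified_both,
                 st3$summary$n_shift + st3$summary$n_non_shift)
    q3 <- st3$records$gene_id[!st3$records$category %in% c("unqualified")]
    q2 <- st2$records$gene_id[!st2$records$category %in% c("unqualified")]
    expect_true(all(q3 %in% q2))
  }
})

test_that("trajectory sets group by signature and are named by size", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    control_label = c("K1_D1", "K1_D1", "OFF"),
    treated_label = c("K2_D1", "K2_D1", "K2_D1"),
    category = c("C_dynamic_to_dynamic", "C_dynamic_to_dynamic",
                 "A_off_to_dynamic"),
    stringsAsFactors = FALSE)
  gs <- group_trajectory_sets(rec, prefix = "R")
  expect_equal(gs$sets$set_id, c("R0", "R1"))
  expect_equal(gs$sets$size, c(2, 1))
  expect_setequal(gs$members$gene_id[gs$members$set_id == "R0"], c("g1", "g2"))
  # empty input
  empty <- group_trajectory_sets(rec[0, ])
  expect_equal(nrow(empty$sets), 0)
  # size ties broken by signature lexicographic order
  rec2 <- data.frame(
    gene_id = c("g1", "g2"),
    control_label = c("K9_D1", "K2_D1"),
    treated_label = c("K1_D1", "K1_D1"),
    category = "C_dynamic_to_dynamic", stringsAsFactors = FALSE)
  gs2 <- group_trajectory_sets(rec2)
  expect_equal(gs2$sets$control_label, c("K2_D1", "K9_D1"))
  expect_equal(gs2$sets$set_id, c("R0", "R1"))
})

test_that("a synthetic run with known signatures recovers each set exactly", {
  sigs <- list(c("K1_D1", "K2_D1"), c("OFF", "K1_D1"),
               c("K2_D1", "OFF"), c("K3_D1", "K3_D2"))
  rec <- do.call(rbind, lapply(seq_along(sigs), function(i) {
    n <- i + 1
    data.frame(gene_id = sprintf("s%d_g%d", i, seq_len(n)),
               control_label = sigs[[i]][1], treated_label = sigs[[i]][2],
               category = classify_shift(sigs[[i]][1], sigs[[i]][2]),
               stringsAsFactors = FALSE)
  }))
  gs <- group_trajectory_sets(rec)
  expect_equal(nrow(gs$sets), 4)
  expect_equal(sort(gs$sets$size), 2:5)
  for (i in seq_along(sigs)) {
    sid <- gs$sets$set_id[gs$sets$control_label == sigs[[i]][1] &
                            gs$sets$treated_label == sigs[[i]][2]]
    expect_setequal(gs$members$gene_id[gs$members$set_id == sid],
                    rec$gene_id[startsWith(rec$gene_id, sprintf("s%d_", i))])
  }
})
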