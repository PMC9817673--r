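test_that("a transcript's whole count goes to its single best retained element", {
  counts <- matrix(c(100, 40), 2, 1,
                   dimnames = list(c("tx1", "tx2"), "s1"))
  expr <- tiny_expr(counts, total_mapped = 1000)

  # single annotation: everything to that element
  ann <- make_ann("tx1", 1, 300, 500, "hAT-Ac", "DNA/hAT-Ac")
  at <- attribute_expression(ann, expr)
  expect_equal(unname(at$counts["DNA/hAT-Ac", "s1"]), 100)

  # two retained non-overlapping hits: best score takes the whole count
  ann <- make_ann(c("tx1", "tx1"), c(1, 500), c(300, 800), c(500, 400),
                  c("hAT-Ac", "DIRS"), c("DNA/hAT-Ac", "LTR/DIRS"))
  at <- attribute_expression(ann, expr)
  expect_equal(unname(at$counts["DNA/hAT-Ac", "s1"]), 100)
  expect_equal(unname(at$counts["LTR/DIRS", "s1"]), 0)

  # weighted mode splits pro rata by aligned bases but conserves the total
  atw <- attribute_expression(ann, expr, attribution = "weighted")
  expect_equal(sum(atw$counts[, "s1"]), 100)
  expect_equal(unname(atw$counts["DNA/hAT-Ac", "s1"]), 100 * 300 / 601)
})

test_that("element totals match a transcript-by-transcript re-summation oracle", {
  set.seed(81)
  n_tx <- 30
  txs <- sprintf("tx%02d", 1:n_tx)
  counts <- matrix(rpois(n_tx * 3, 50), n_tx, 3,
                   dimnames = list(txs, c("s1", "s2", "s3")))
  expr <- tiny_expr(counts)
  ann <- random_annotations(80, n_tx)
  ann$query_id <- sprintf("tx%02d", as.integer(sub("tx", "", ann$query_id)))
  filtered <- filter_redundant(ann)
  at <- attribute_expression(filtered, expr)

  # oracle: loop transcripts, find best hit by the stated ordering, add count
  expected <- at$counts * 0
  for (tx in unique(filtered$query_id)) {
    b <- filtered[filtered$query_id == tx, , drop = FALSE]
    len <- b$q_end - b$q_begin + 1L
    best <- b[order(-b$sw_score, -len, b$q_begin)[1], ]
    fam <- best$repeat_class_family
    nms <- unique(filtered$repeat_name[filtered$repeat_class_family == fam])
    key <- if (length(nms) > 1) paste(fam, best$repeat_name, sep = "/") else fam
    expected[key, ] <- expected[key, ] + counts[tx, ]
  }
  expect_equal(at$counts, expected)
})

test_that("activity is percent of mapped reads and rolls up conservatively", {
  counts <- matrix(c(100, 30, 40), 3, 1,
                   dimnames = list(c("tx1", "tx2", "tx3"), "s1"))
  expr <- tiny_expr(counts, total_mapped = 1000)
  ann <- make_ann(c("tx1", "tx2", "tx3"), c(1, 1, 1), c(80, 80, 80),
                  c(500, 400, 300), c("hAT-Ac", "L1", "DIRS"),
                  c("DNA/hAT-Ac", "LINE/L1", "LTR/DIRS"))
  act <- aggregate_activity(attribute_expression(ann, expr), expr)

  expect_equal(act[act$level == "element" & act$key == "DNA/hAT-Ac", "s1"], 10)
  cls <- act[act$level == "class", ]
  expect_equal(cls[cls$key == "DNA", "s1"], 10)
  expect_equal(cls[cls$key == "SINE", "s1"], 0)  # absent classes present, zero
  expect_equal(act[act$level == "total", "s1"], 17)  # 10 + 3 + 4
})

test_that("mass is conserved across levels and under count rescaling", {
  set.seed(82)
  cfg <- small_sim("liver", seed = 82)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  expr <- read_expression(sim$paths$counts, sim$paths$totals,
                          sim$paths$samples)
  filtered <- filter_redundant(parse_repeatmasker_out(sim$paths$repeats_out))
  act <- aggregate_activity(attribute_expression(filtered, expr), expr)
  smp <- attr(act, "samples")$sample_id
  for (lvl in c("element", "type", "class")) {
    sums <- colSums(act[act$level == lvl, smp, drop = FALSE])
    total <- unlist(act[act$level == "total", smp])
    expect_equal(sums, total, tolerance = 1e-12)
  }
  expect_true(all(act[, smp] >= 0))
  expect_true(all(act[act$level == "total", smp] <= 100))

  # scale invariance: counts and totals x7 leave every percentage unchanged
  expr7 <- expression_matrix(expr$counts * 7, expr$total_mapped * 7,
                             expr$samples)
  act7 <- aggregate_activity(attribute_expression(filtered, expr7), expr7)
  expect_equal(act7[, smp], act[, smp], tolerance = 1e-12)
})

test_that("zero total mapped reads is an error naming the sample", {
  counts <- matrix(0, 1, 1, dimnames = list("tx1", "s1"))
  expr <- tiny_expr(counts, total_mapped = 0)
  ann <- make_ann("tx1", 1, 50, 100, "L1", "LINE/L1")
  expect_error(aggregate_activity(attribute_expression(ann, expr), expr),
               "s1")
})

test_that("contributor shares decompose the class-level change", {
  # two DNA elements on distinct transcripts; planted deltas +3 and +1
  counts <- matrix(c(0, 0,  0, 0,  3, 1,  3, 1), 2, 4,
                   dimnames = list(c("tx1", "tx2"),
                                   c("a1", "a2", "b1", "b2")))
  expr <- tiny_expr(counts, total_mapped = rep(100, 4),
                    conditions = c("A", "A", "B", "B"))
  ann <- make_ann(c("tx1", "tx2"), c(1, 1), c(50, 50), c(500, 400),
                  c("hAT-Ac", "Tc1"), c("DNA/hAT-Ac", "DNA/TcMar-Tc1"))
  act <- aggregate_activity(attribute_expression(ann, expr), expr)

  rep1 <- top_contributors(act, "DNA", "A", "B", k = 1)
  expect_equal(rep1$class_delta, 4)
  expect_equal(rep1$elements$delta, c(3, 1))
  expect_equal(rep1$top_k_share, 0.75)

  # single contributing element carries the whole change
  rep_all <- top_contributors(act, "DNA", "A", "B", k = 10)
  expect_equal(rep_all$top_k_share, 1.0)

  # zero class delta: shares flagged undefined
  rep0 <- top_contributors(act, "LINE", "A", "B", k = 3)
  expect_false(rep0$shares_defined)
  expect_true(is.na(rep0$top_k_share))
  expect_null(rep0$elements$share)
})

test_that("an empty annotation set warns and yields empty activity", {
  counts <- matrix(5, 1, 1, dimnames = list("tx1", "s1"))
  expr <- tiny_expr(counts)
  empty <- filter_redundant(make_ann("tx1", 1, 10, 50, "(TA)n",
                                     "Simple_repeat"))
  expect_warning(at <- attribute_expression(empty, expr), "no retained")
  act <- aggregate_activity(at, expr)
  expect_equal(act[act$level == "total", "s1"], 0)
})
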