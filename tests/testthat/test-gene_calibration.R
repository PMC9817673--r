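write_busco_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("# BUSCO version is: 5.4.0",
               "# Busco id\tStatus\tSequence\tScore\tLength", rows), path)
  path
}

test_that("BUSCO rows parse and duplicated copies merge into one record", {
  path <- write_busco_fixture(c(
    "b1\tComplete\ttx9\t99.0\t500",
    "b2\tDuplicated\ttx3\t98.0\t400",
    "b2\tDuplicated\ttx7\t97.0\t410",
    "b3\tMissing",
    "b4\tFragmented\ttx5\t50.0\t200"
  ))
  recs <- parse_busco_table(path)
  expect_equal(nrow(recs), 4L)
  expect_equal(recs$status, c("Complete", "Duplicated", "Missing",
                              "Fragmented"))
  expect_equal(recs$transcript_ids[[1]], "tx9")
  expect_equal(sort(recs$transcript_ids[[2]]), c("tx3", "tx7"))
  expect_length(recs$transcript_ids[[3]], 0L)

  bad <- write_busco_fixture("b1\tPartial\ttx1")
  expect_error(parse_busco_table(bad), "line 3")
})

test_that("calibration values follow the status rules", {
  counts <- matrix(c(10, 5, 7, 3,
                     20, 6, 8, 4), 4, 2,
                   dimnames = list(c("tx9", "tx3", "tx7", "txF"),
                                   c("s1", "s2")))
  expr <- tiny_expr(counts)
  path <- write_busco_fixture(c(
    "b1\tComplete\ttx9\t99.0\t500",
    "b2\tDuplicated\ttx3\t98.0\t400",
    "b2\tDuplicated\ttx7\t97.0\t410",
    "b3\tMissing",
    "b4\tFragmented\ttxF\t50.0\t200"
  ))
  cal <- build_calibration(parse_busco_table(path), expr)
  expect_equal(unname(cal$values[, "s1"]), c(10, 5 + 7, 0, 3))
  expect_equal(unname(cal$cumulative), c(10 + 12 + 0 + 3, 20 + 14 + 0 + 4))
  expect_equal(cal$n_orthologs, 4L)

  # transcript named by BUSCO but absent from counts: zero with a warning
  gone <- write_busco_fixture(c("b1\tComplete\ttx9\t99.0\t500",
                                "b2\tComplete\ttxZ\t99.0\t500"))
  expect_warning(cal2 <- build_calibration(parse_busco_table(gone), expr),
                 "absent")
  expect_equal(unname(cal2$values["b2", ]), c(0, 0))
})

test_that("cumulative matches a rule-by-rule loop on a random fixture", {
  set.seed(91)
  statuses <- sample(c("Complete", "Duplicated", "Fragmented", "Missing"),
                     40, replace = TRUE, prob = c(.5, .2, .2, .1))
  rows <- character(0)
  truth_tx <- list()
  k <- 0
  for (i in seq_along(statuses)) {
    id <- sprintf("b%02d", i)
    if (statuses[i] == "Missing") {
      rows <- c(rows, paste(id, "Missing", sep = "\t"))
      truth_tx[[id]] <- character(0)
    } else {
      n <- if (statuses[i] == "Duplicated") sample(2:3, 1) else 1
      tx <- sprintf("tx%03d", k + seq_len(n)); k <- k + n
      rows <- c(rows, paste(id, statuses[i], tx, "90.0", "300", sep = "\t"))
      truth_tx[[id]] <- tx
    }
  }
  counts <- matrix(rpois(k * 3, 30), k, 3,
                   dimnames = list(sprintf("tx%03d", seq_len(k)),
                                   c("s1", "s2", "s3")))
  expr <- tiny_expr(counts)
  cal <- build_calibration(parse_busco_table(write_busco_fixture(rows)), expr)

  expected <- rep(0, 3)
  for (id in names(truth_tx)) {
    for (tx in truth_tx[[id]]) expected <- expected + counts[tx, ]
  }
  expect_equal(unname(cal$cumulative), unname(expected))
})

test_that("scaling factors equalise the calibration cumulative exactly", {
  fake_cal <- structure(list(values = NULL,
                             cumulative = c(s1 = 100, s2 = 200),
                             n_orthologs = 10L),
                        class = "calibration_set")
  sf <- compute_scaling(fake_cal)
  expect_equal(sf$reference_value, 150)
  expect_equal(sf$factors, c(s1 = 1.5, s2 = 0.75))
  expect_equal(unname(sf$factors * fake_cal$cumulative), c(150, 150),
               tolerance = 1e-12)

  equal_cal <- structure(list(cumulative = c(a = 7, b = 7, c = 7)),
                         class = "calibration_set")
  expect_equal(unname(compute_scaling(equal_cal)$factors), rep(1, 3))

  zero_cal <- structure(list(cumulative = c(s1 = 10, s2 = 0)),
                        class = "calibration_set")
  expect_error(compute_scaling(zero_cal), "s2")
})

test_that("factors are invariant under sample relabeling and global rescaling", {
  cum <- c(s1 = 120, s2 = 80, s3 = 100)
  f1 <- compute_scaling(structure(list(cumulative = cum),
                                  class = "calibration_set"))$factors
  perm <- cum[c(3, 1, 2)]
  f2 <- compute_scaling(structure(list(cumulative = perm),
                                  class = "calibration_set"))$factors
  expect_equal(f2[names(f1)], f1)
  f3 <- compute_scaling(structure(list(cumulative = cum * 13),
                                  class = "calibration_set"))$factors
  expect_equal(f3, f1)
})

test_that("TPM normalises by CDS length and sums to one million over its universe", {
  counts <- matrix(c(50, 50), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
  expr <- tiny_expr(counts)
  unit <- list(factors = c(s1 = 1), reference_value = 1)
  panel1 <- data.frame(gene = "g1", group = "x", cds_length = 1000)
  panel1$transcripts <- list("t1")
  expect_equal(unname(calibrated_tpm(panel1, expr, unit,
                                     tpm_universe = "panel")[1, 1]), 1e6)

  panel2 <- data.frame(gene = c("g1", "g2"), group = "x",
                       cds_length = c(1000, 2000))
  panel2$transcripts <- list("t1", "t2")
  tpm <- calibrated_tpm(panel2, expr, unit, tpm_universe = "panel")
  expect_equal(unname(tpm["g1", 1] / tpm["g2", 1]), 2)
  expect_equal(sum(tpm[, 1]), 1e6)

  panel3 <- data.frame(gene = "ghost", group = "x", cds_length = 500)
  panel3$transcripts <- list(character(0))
  expect_warning(tpm3 <- calibrated_tpm(panel3, expr, unit,
                                        tpm_universe = "panel"),
                 "ghost")
  expect_equal(unname(tpm3[1, 1]), 0)
})

test_that("calibration recovers a planted gene fold change under depth imbalance", {
  cfg <- small_sim(NULL, seed = 93,
                   condition_effects = c(ago2 = 2),
                   library_size_multipliers = c("27C" = 1, "13C" = 3))
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  expr <- read_expression(sim$paths$counts, sim$paths$totals,
                          sim$paths$samples)
  cal <- build_calibration(parse_busco_table(sim$paths$busco), expr)
  sf <- compute_scaling(cal)

  # post-scaling cumulatives all equal the reference
  expect_equal(unname(sf$factors * cal$cumulative),
               rep(sf$reference_value, 6), tolerance = 1e-9)
  # factors undo the planted 3x imbalance (ortholog sums are tight)
  truth <- unlist(sim$manifest$expected_scaling_factors)
  expect_equal(unname(sf$factors[names(truth)]), unname(truth),
               tolerance = 0.05)

  is_test <- expr$samples$condition == "13C"
  raw <- colSums(expr$counts["gtx_ago2", , drop = FALSE])
  fc_raw <- mean(raw[is_test]) / mean(raw[!is_test])
  scaled <- raw * sf$factors
  fc_cal <- mean(scaled[is_test]) / mean(scaled[!is_test])
  # uncalibrated counts confound fold change with the 3x depth imbalance
  expect_gt(fc_raw, 4)
  # calibrated counts sit near the planted 2.0 (single-seed sampling noise)
  expect_lt(abs(fc_cal - 2) / 2, 0.25)

  # calibrated TPM gives the same recovery on the reported scale
  panel <- read_gene_panel(sim$paths$panel)
  lens <- read_transcript_lengths(sim$paths$lengths)
  tpm <- calibrated_tpm(panel, expr, sf, lengths = lens)
  fc_tpm <- mean(tpm["ago2", is_test]) / mean(tpm["ago2", !is_test])
  expect_lt(abs(fc_tpm - 2) / 2, 0.25)
})
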