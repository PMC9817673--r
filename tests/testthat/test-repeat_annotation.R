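test_that("parser maps RepeatMasker .out fields onto annotations", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query  position in query  matching repeat",
    "score   div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    "  500 10.0  1.0  1.0  tx1 1 300 (700) + hAT-Ac DNA/hAT-Ac 1 300 (0) 1",
    "  250 21.5  2.0  0.5  tx2 40 120 (500) C DIRS LTR/DIRS (0) 81 1 2 *"
  ), path)
  ann <- parse_repeatmasker_out(path)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$query_id, c("tx1", "tx2"))
  expect_equal(ann$sw_score, c(500L, 250L))
  expect_equal(ann$q_begin, c(1L, 40L))
  expect_equal(ann$q_end, c(300L, 120L))
  expect_equal(ann$perc_div, c(10.0, 21.5))
  expect_equal(ann$strand, c("+", "C"))
  expect_equal(ann$repeat_class_family, c("DNA/hAT-Ac", "LTR/DIRS"))
  expect_equal(ann$hit_id, c(1L, 2L))
  expect_equal(ann$overlap_flag, c(FALSE, TRUE))
})

test_that("header-only files give an empty annotation set, bad lines an error", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", ""), path)
  expect_equal(nrow(parse_repeatmasker_out(path)), 0L)

  writeLines(c("h1", "h2", "", "only three fields"), path)
  expect_error(parse_repeatmasker_out(path), "line 4")

  writeLines(c("h1", "h2", "",
               "  500 10.0 1.0 1.0 tx1 1 300 (700) ? hAT-Ac DNA/hAT-Ac 1 300 (0) 1"),
             path)
  expect_error(parse_repeatmasker_out(path), "strand")
})

test_that("writer output round-trips through the parser byte-identically", {
  set.seed(41)
  ann <- random_annotations(25, 4)
  qlen <- stats::setNames(rep(2000L, 4), paste0("tx", 1:4))
  p1 <- withr::local_tempfile(fileext = ".out")
  p2 <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, p1, q_length = qlen)
  reread <- parse_repeatmasker_out(p1)
  expect_equal(nrow(reread), 25L)
  expect_equal(reread$sw_score, ann$sw_score)
  expect_equal(reread$repeat_class_family, ann$repeat_class_family)
  write_repeatmasker_out(reread, p2, q_length = qlen)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("classification follows the rule table, first match winning", {
  expect_equal(classify_repeat("DNA/hAT-Ac"), "DNA")
  expect_equal(classify_repeat("LTR/DIRS"), "LTR")
  expect_equal(classify_repeat("Simple_repeat"), "NonTE")
  expect_equal(classify_repeat("Unknown"), "Unclear")
  expect_equal(classify_repeat("RC/Helitron"), "DNA")
  expect_equal(classify_repeat("Penelope/Poseidon"), "nonLTR")
  expect_equal(classify_repeat("non-LTR/CRE"), "nonLTR")
  expect_equal(classify_repeat("Retroposon/SVA"), "Retro")
  expect_equal(classify_repeat("Low_complexity"), "NonTE")
})

test_that("classification is total: every string yields exactly one class", {
  set.seed(5)
  strings <- c(
    replicate(200, paste(sample(c(letters, LETTERS, "/", "-", "_"), 8,
                                replace = TRUE), collapse = "")),
    "", "DNA", "LINE/", "/LTR", "anything-else")
  cls <- classify_repeat(strings)
  expect_length(cls, length(strings))
  expect_true(all(cls %in% c(te_classes(), "NonTE")))
  # strings matching no rule fall through to Unclear
  expect_equal(classify_repeat("zzz-novel-repeat"), "Unclear")
})

test_that("the redundancy filter keeps the best-scoring hit of each overlap cluster", {
  # strict dominance: higher score wins its overlap cluster
  ann <- make_ann(c("tx1", "tx1"), c(1, 100), c(300, 250), c(500, 300),
                  c("hAT-Ac", "DIRS"), c("DNA/hAT-Ac", "LTR/DIRS"))
  expect_equal(filter_redundant(ann)$sw_score, 500L)

  # score tie broken by greater query length
  ann <- make_ann(c("tx1", "tx1"), c(1, 1), c(100, 200), c(500, 500),
                  c("a", "b"), c("DNA/hAT-Ac", "DNA/hAT-Ac"))
  expect_equal(filter_redundant(ann)$q_end, 200L)

  # non-overlapping hits on one transcript all survive
  ann <- make_ann(c("tx1", "tx1"), c(1, 500), c(100, 700), c(500, 300),
                  c("a", "b"), c("DNA/hAT-Ac", "LTR/DIRS"))
  expect_equal(nrow(filter_redundant(ann)), 2L)

  # non-TE entries are removed even when they dominate on score
  ann <- make_ann(c("tx1", "tx1"), c(1, 10), c(100, 90), c(900, 100),
                  c("(TA)n", "L1"), c("Simple_repeat", "LINE/L1"))
  expect_equal(filter_redundant(ann)$te_class, "LINE")
})

test_that("filter matches the brute-force overlap-cluster oracle on random sets", {
  set.seed(71)
  for (rep in 1:60) {
    ann <- random_annotations(sample(1:50, 1), sample(1:6, 1))
    got <- filter_redundant(ann)
    want <- oracle_filter(ann)
    expect_equal(got, want)
  }
})

test_that("filtering is idempotent and leaves no overlapping pair", {
  set.seed(72)
  for (rep in 1:20) {
    ann <- random_annotations(40, 4)
    once <- filter_redundant(ann)
    expect_equal(filter_redundant(once[, names(ann)]), once)
    for (q in unique(once$query_id)) {
      b <- once[once$query_id == q, ]
      if (nrow(b) > 1) {
        o <- order(b$q_begin)
        expect_true(all(b$q_begin[o][-1] > b$q_end[o][-nrow(b)]))
      }
    }
  }
})

test_that("the retained set ignores input order when ranking triples are unique", {
  set.seed(73)
  ann <- random_annotations(30, 3)
  ann$sw_score <- sample(1000:2000, 30)  # unique scores
  base <- filter_redundant(ann)
  for (rep in 1:5) {
    perm <- ann[sample(nrow(ann)), ]
    perm$hit_id <- seq_len(nrow(perm))
    got <- filter_redundant(perm)
    expect_equal(got$sw_score, base$sw_score)
    expect_equal(got$q_begin, base$q_begin)
  }
})
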