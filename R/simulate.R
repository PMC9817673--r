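#' Simulation configuration
#'
#' Describes a synthetic two-condition RNA-Seq experiment on a de novo
#' transcriptome: a set of TE elements with target activity levels (percent
#' of mapped reads) per class, a BUSCO ortholog complement, the 34-gene
#' silencing panel, and negative-binomial read counts over replicated
#' samples. Every planted quantity is written to a ground-truth manifest by
#' [simulate_dataset()].
#'
#' Fold changes in \code{condition_effects} are applied at the test
#' condition and may be keyed by TE class (e.g. \code{DNA}), element (e.g.
#' \code{"DNA/hAT-Ac"}, overriding its class) or gene name (e.g.
#' \code{ago2}); anything unnamed stays at 1.
#'
#' @param tissue Tissue label for the sample sheet.
#' @param conditions Length-2 character vector, control first.
#' @param n_replicates Replicates per condition.
#' @param depth Nominal total mapped reads per sample.
#' @param dispersion Negative-binomial dispersion (1/size); counts are drawn
#'   with \code{rnbinom(mu, size = 1/dispersion)}.
#' @param library_size_multipliers Per-sample depth multipliers: NULL (all
#'   1), a vector named by condition, or one value per sample in sample
#'   order.
#' @param te_fraction_by_class Named percent-of-mapped-reads targets for the
#'   seven TE classes at the control condition.
#' @param condition_effects Named fold changes (class, element or gene keys).
#' @param elements_per_class,transcripts_per_element Granularity of the TE
#'   complement.
#' @param redundancy_rate Fraction of TE transcripts receiving overlapping
#'   lower-score decoy hits.
#' @param nonte_hits Number of scattered non-TE annotation rows (simple
#'   repeats etc.).
#' @param n_background Number of unannotated background transcripts.
#' @param n_orthologs Size of the BUSCO complement.
#' @param busco_status_probs Probabilities for
#'   Complete/Duplicated/Fragmented/Missing.
#' @param busco_fraction,gene_fraction,unassigned_fraction Percent of mapped
#'   reads carried by the ortholog set, the gene panel, and reads mapping
#'   outside the annotated transcripts; background transcripts absorb the
#'   remainder.
#' @param write_fasta Whether to emit the transcript FASTA (lengths are
#'   always written as TSV).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A \code{sim_config} list.
#' @export
simulation_config <- function(tissue = "liver",
                              conditions = c("27C", "13C"),
                              n_replicates = 3L,
                              depth = 5e6,
                              dispersion = 0.005,
                              library_size_multipliers = NULL,
                              te_fraction_by_class = c(DNA = 6, LINE = 4,
                                                       Unclear = 2.5,
                                                       Retro = 1.5, LTR = 1,
                                                       SINE = 0.6,
                                                       nonLTR = 0.3),
                              condition_effects = numeric(0),
                              elements_per_class = 6L,
                              transcripts_per_element = 4L,
                              redundancy_rate = 0.3,
                              nonte_hits = 120L,
                              n_background = 2000L,
                              n_orthologs = 2124L,
                              busco_status_probs = c(Complete = 0.85,
                                                     Duplicated = 0.06,
                                                     Fragmented = 0.05,
                                                     Missing = 0.04),
                              busco_fraction = 25,
                              gene_fraction = 0.7,
                              unassigned_fraction = 15,
                              write_fasta = TRUE,
                              seed = 1L) {
  cfg <- list(tissue = tissue, conditions = conditions,
              n_replicates = as.integer(n_replicates), depth = depth,
              dispersion = dispersion,
              library_size_multipliers = library_size_multipliers,
              te_fraction_by_class = te_fraction_by_class,
              condition_effects = condition_effects,
              elements_per_class = as.integer(elements_per_class),
              transcripts_per_element = as.integer(transcripts_per_element),
              redundancy_rate = redundancy_rate, nonte_hits = as.integer(nonte_hits),
              n_background = as.integer(n_background),
              n_orthologs = as.integer(n_orthologs),
              busco_status_probs = busco_status_probs,
              busco_fraction = busco_fraction, gene_fraction = gene_fraction,
              unassigned_fraction = unassigned_fraction,
              write_fasta = isTRUE(write_fasta), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$conditions) == 2L, cfg$n_replicates >= 1L,
            cfg$depth > 0, cfg$dispersion > 0,
            cfg$redundancy_rate >= 0, cfg$redundancy_rate <= 1)
  if (!setequal(names(cfg$te_fraction_by_class), te_classes()))
    stop("te_fraction_by_class must name all seven TE classes")
  if (any(cfg$te_fraction_by_class < 0)) stop("negative TE fraction")
  if (abs(sum(cfg$busco_status_probs) - 1) > 1e-8)
    stop("busco_status_probs must sum to 1")
  if (any(cfg$condition_effects < 0)) stop("negative fold change")
  # assigned mass must stay below 100% of mapped reads in both conditions
  te_ctrl <- sum(cfg$te_fraction_by_class)
  fc <- cfg$condition_effects
  class_fc <- vapply(te_classes(), function(cl) {
    if (cl %in% names(fc)) fc[[cl]] else 1
  }, numeric(1))
  elem_fc_max <- if (length(fc)) max(fc, 1) else 1
  te_test_hi <- sum(cfg$te_fraction_by_class * pmax(class_fc, 1)) * 1 +
    0  # element overrides refine this at build time; checked again there
  fixed <- cfg$busco_fraction + cfg$gene_fraction * elem_fc_max +
    cfg$unassigned_fraction
  if (te_ctrl + fixed >= 100 || te_test_hi + fixed >= 100)
    stop("planted fractions sum to >= 100% of mapped reads")
  invisible(cfg)
}

te_family_pool <- function() {
  list(
    DNA = c("DNA/hAT-Ac", "DNA/TcMar-Tc1", "DNA/hAT-Charlie",
            "DNA/PIF-Harbinger", "DNA/CMC-EnSpm", "RC/Helitron",
            "DNA/Merlin", "DNA/P", "DNA/Kolobok", "DNA/Zator"),
    LINE = c("LINE/L1", "LINE/L2", "LINE/Rex-Babar", "LINE/RTE-BovB",
             "LINE/I", "LINE/Jockey", "LINE/CR1", "LINE/Dong-R4",
             "LINE/Proto2", "LINE/L1-Tx1"),
    LTR = c("LTR/DIRS", "LTR/Gypsy", "LTR/Copia", "LTR/ERV1", "LTR/Ngaro",
            "LTR/Pao", "LTR/ERVK", "LTR/ERVL", "LTR/BEL", "LTR/Unknown-LTR"),
    nonLTR = c("Penelope/Poseidon", "Penelope/Neptune", "non-LTR/CRE",
               "non-LTR/R2", "Penelope/Athena", "non-LTR/NeSL",
               "Penelope/Chlamys", "non-LTR/R4"),
    Retro = c("Retroposon/SVA-like", "Retroposon/L1-dep", "Retro/Unc-A",
              "Retro/Unc-B", "Retroposon/RTEX", "Retro/Unc-C",
              "Retroposon/Dada", "Retro/Unc-D"),
    SINE = c("SINE/tRNA", "SINE/tRNA-Core", "SINE/MIR", "SINE/5S",
             "SINE/tRNA-V", "SINE/Alu-like", "SINE/tRNA-RTE", "SINE/ID"),
    Unclear = rep("Unknown", 10)
  )
}

nonte_family_pool <- function() {
  c("Simple_repeat", "Low_complexity", "Satellite", "rRNA", "tRNA")
}

effect_for <- function(effects, element, te_class) {
  if (element %in% names(effects)) return(effects[[element]])
  if (te_class %in% names(effects)) return(effects[[te_class]])
  1
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Writes, under \code{outdir}: a transcript FASTA and lengths TSV, a
#' RepeatMasker-style \code{.out} file (one true hit per TE transcript plus,
#' at the configured redundancy rate, overlapping strictly-lower-score decoy
#' hits and scattered non-TE rows), a counts TSV of negative-binomial draws
#' whose expectations realise the planted class activities and fold changes,
#' a totals TSV including an unassigned-read remainder so planted percents
#' are exact in expectation, a sample sheet, a BUSCO full table, the gene
#' panel YAML, and \code{manifest.json} recording every planted truth.
#'
#' Decoy hits always lose the redundancy filter by construction (strictly
#' lower score, overlapping the true hit), so ground-truth attribution is
#' never disturbed. With a fixed seed the outputs are byte-identical across
#' runs.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{paths} (named file
#'   paths) and \code{manifest} (the ground-truth list).
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cond_ctrl <- config$conditions[1]
  cond_test <- config$conditions[2]

  ## ---- samples ----
  smp <- expand.grid(replicate = seq_len(config$n_replicates),
                     condition = config$conditions,
                     stringsAsFactors = FALSE)
  smp <- data.frame(sample_id = sprintf("%s_%s_r%d", config$tissue,
                                        smp$condition, smp$replicate),
                    tissue = config$tissue, condition = smp$condition,
                    replicate = smp$replicate, stringsAsFactors = FALSE)
  libm <- config$library_size_multipliers
  lib <- if (is.null(libm)) {
    rep(1, nrow(smp))
  } else if (!is.null(names(libm)) && all(smp$condition %in% names(libm))) {
    unname(libm[smp$condition])
  } else if (length(libm) == nrow(smp)) {
    as.numeric(libm)
  } else stop("library_size_multipliers must be named by condition or one per sample")

  ## ---- TE complement ----
  pool <- te_family_pool()
  el_list <- list()
  for (cl in te_classes()) {
    k <- min(config$elements_per_class, length(pool[[cl]]))
    fam <- pool[[cl]][seq_len(k)]
    name <- if (cl == "Unclear") sprintf("Unc-%d", seq_len(k)) else
      sub(".*/", "", fam)
    key <- if (cl == "Unclear") paste(fam, name, sep = "/") else fam
    w <- 0.55^(seq_len(k) - 1)
    share <- w / sum(w)
    el_list[[cl]] <- data.frame(element = key, te_class = cl, family = fam,
                                repeat_name = name,
                                base_percent = config$te_fraction_by_class[[cl]] * share,
                                stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, el_list)
  rownames(elements) <- NULL
  elements$fold_change <- vapply(seq_len(nrow(elements)), function(i) {
    effect_for(config$condition_effects, elements$element[i],
               elements$te_class[i])
  }, numeric(1))

  ## ---- transcripts ----
  tx <- list()
  # TE transcripts: each element's mass split over its transcripts
  te_rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(elements))) {
    nt <- config$transcripts_per_element
    w <- stats::rgamma(nt, shape = 5)
    w <- w / sum(w)
    ids <- sprintf("TEtx%05d", idx + seq_len(nt))
    idx <- idx + nt
    te_rows[[i]] <- data.frame(
      transcript_id = ids, kind = "te",
      length = sample(800:3000, nt, replace = TRUE),
      base_prop = elements$base_percent[i] / 100 * w,
      fold_change = elements$fold_change[i],
      element = elements$element[i], stringsAsFactors = FALSE)
  }
  tx$te <- do.call(rbind, te_rows)

  # gene panel transcripts
  panel <- silencing_gene_panel()
  panel$transcripts <- lapply(panel$gene, function(g) paste0("gtx_", g))
  gw <- stats::rgamma(nrow(panel), shape = 4)
  gw <- gw / sum(gw)
  gene_fc <- vapply(panel$gene, function(g) {
    if (g %in% names(config$condition_effects))
      config$condition_effects[[g]] else 1
  }, numeric(1))
  tx$gene <- data.frame(
    transcript_id = unlist(panel$transcripts), kind = "gene",
    length = panel$cds_length + sample(300:1500, nrow(panel), replace = TRUE),
    base_prop = config$gene_fraction / 100 * gw,
    fold_change = gene_fc, element = NA_character_,
    stringsAsFactors = FALSE)

  # BUSCO complement
  statuses <- sample(names(config$busco_status_probs), config$n_orthologs,
                     replace = TRUE, prob = config$busco_status_probs)
  busco_ids <- sprintf("%06dat7898", seq_len(config$n_orthologs))
  n_copies <- ifelse(statuses == "Missing", 0L,
                     ifelse(statuses == "Duplicated",
                            sample(2:3, config$n_orthologs, replace = TRUE), 1L))
  bw <- stats::rgamma(config$n_orthologs, shape = 2)
  bw[statuses == "Missing"] <- 0
  bw <- bw / sum(bw)
  busco_prop <- config$busco_fraction / 100 * bw
  btx_rows <- list()
  btab_rows <- list()
  bidx <- 0L
  for (i in seq_len(config$n_orthologs)) {
    if (n_copies[i] == 0L) {
      btab_rows[[i]] <- data.frame(busco_id = busco_ids[i], status = "Missing",
                                   sequence = NA_character_,
                                   stringsAsFactors = FALSE)
      next
    }
    ids <- sprintf("btx%06d", bidx + seq_len(n_copies[i]))
    bidx <- bidx + n_copies[i]
    cw <- stats::rgamma(n_copies[i], shape = 3)
    cw <- cw / sum(cw)
    lo <- if (statuses[i] == "Fragmented") 300:800 else 1000:4000
    btx_rows[[i]] <- data.frame(
      transcript_id = ids, kind = "busco",
      length = sample(lo, n_copies[i], replace = TRUE),
      base_prop = busco_prop[i] * cw, fold_change = 1,
      element = NA_character_, stringsAsFactors = FALSE)
    btab_rows[[i]] <- data.frame(busco_id = busco_ids[i], status = statuses[i],
                                 sequence = ids, stringsAsFactors = FALSE)
  }
  tx$busco <- do.call(rbind, btx_rows)
  busco_tab <- do.call(rbind, btab_rows)

  # background transcripts absorb the remaining assigned mass
  assigned_ctrl <- sum(tx$te$base_prop) + sum(tx$gene$base_prop) +
    sum(tx$busco$base_prop)
  bg_total <- 1 - config$unassigned_fraction / 100 - assigned_ctrl
  extra_test <- sum(tx$te$base_prop * (tx$te$fold_change - 1)) +
    sum(tx$gene$base_prop * (tx$gene$fold_change - 1))
  if (bg_total <= 0 || bg_total - extra_test <= 0)
    stop("planted fractions sum to >= 100% of mapped reads")
  bgw <- stats::rgamma(config$n_background, shape = 1.2)
  bgw <- bgw / sum(bgw)
  tx$background <- data.frame(
    transcript_id = sprintf("tx%05d", seq_len(config$n_background)),
    kind = "background",
    length = sample(500:3000, config$n_background, replace = TRUE),
    base_prop = bg_total * bgw, fold_change = 1, element = NA_character_,
    stringsAsFactors = FALSE)

  transcripts <- rbind(tx$te, tx$gene, tx$busco, tx$background)
  rownames(transcripts) <- NULL

  ## ---- counts ----
  counts <- matrix(0, nrow(transcripts), nrow(smp),
                   dimnames = list(transcripts$transcript_id, smp$sample_id))
  size <- 1 / config$dispersion
  for (s in seq_len(nrow(smp))) {
    eff <- if (smp$condition[s] == cond_test) transcripts$fold_change else 1
    mu <- config$depth * lib[s] * transcripts$base_prop * eff
    counts[, s] <- stats::rnbinom(nrow(transcripts), size = size, mu = mu)
  }
  total_mapped <- pmax(round(config$depth * lib), colSums(counts))
  names(total_mapped) <- smp$sample_id
  expr <- expression_matrix(counts, total_mapped, smp)

  ## ---- RepeatMasker-style annotations ----
  ann_rows <- list()
  hid <- 0L
  rand_pct <- function(n) round(stats::runif(n, 0, 30), 1)
  for (i in seq_len(nrow(tx$te))) {
    len <- tx$te$length[i]
    el <- elements[elements$element == tx$te$element[i], ]
    span <- max(50L, round(len * stats::runif(1, 0.4, 0.9)))
    qb <- sample.int(max(1L, len - span), 1L)
    qe <- min(len, qb + span - 1L)
    score <- sample(1500:9000, 1L)
    hid <- hid + 1L
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      query_id = tx$te$transcript_id[i], q_begin = qb, q_end = qe,
      sw_score = score, perc_div = rand_pct(1), perc_del = rand_pct(1),
      perc_ins = rand_pct(1), strand = sample(c("+", "C"), 1),
      repeat_name = el$repeat_name, repeat_class_family = el$family,
      hit_id = hid, overlap_flag = FALSE, stringsAsFactors = FALSE)
    if (stats::runif(1) < config$redundancy_rate) {
      nd <- sample(1:2, 1)
      for (d in seq_len(nd)) {
        db <- sample(qb:qe, 1L)  # starts inside the true hit: overlap certain
        de <- min(len, db + sample(30:span, 1L))
        dscore <- max(10L, score - sample(100:600, 1L))
        dj <- sample(nrow(elements), 1L)
        hid <- hid + 1L
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          query_id = tx$te$transcript_id[i], q_begin = db, q_end = de,
          sw_score = dscore, perc_div = rand_pct(1), perc_del = rand_pct(1),
          perc_ins = rand_pct(1), strand = sample(c("+", "C"), 1),
          repeat_name = elements$repeat_name[dj],
          repeat_class_family = elements$family[dj],
          hit_id = hid, overlap_flag = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  # scattered non-TE rows on random transcripts
  nonte_fams <- nonte_family_pool()
  nonte_names <- c("(TA)n", "(CA)n", "A-rich", "GC_rich", "SAT-1", "LSU-rRNA",
                   "tRNA-Lys", "(TTAGGG)n")
  pick_tx <- sample(nrow(transcripts), config$nonte_hits, replace = TRUE)
  for (j in seq_len(config$nonte_hits)) {
    len <- transcripts$length[pick_tx[j]]
    span <- sample(20:200, 1L)
    qb <- sample.int(max(1L, len - span), 1L)
    hid <- hid + 1L
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      query_id = transcripts$transcript_id[pick_tx[j]], q_begin = qb,
      q_end = min(len, qb + span - 1L), sw_score = sample(15:500, 1L),
      perc_div = rand_pct(1), perc_del = rand_pct(1), perc_ins = rand_pct(1),
      strand = "+", repeat_name = sample(nonte_names, 1L),
      repeat_class_family = sample(nonte_fams, 1L), hit_id = hid,
      overlap_flag = FALSE, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann_rows)
  rownames(ann) <- NULL

  ## ---- write everything ----
  paths <- list(
    counts = file.path(outdir, "counts.tsv"),
    totals = file.path(outdir, "totals.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    repeats_out = file.path(outdir, "repeats.out"),
    lengths = file.path(outdir, "transcript_lengths.tsv"),
    fasta = file.path(outdir, "transcripts.fasta"),
    busco = file.path(outdir, "busco_full_table.tsv"),
    panel = file.path(outdir, "gene_panel.yaml"),
    classification = file.path(outdir, "te_classification.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_expression(expr, paths$counts, paths$totals, paths$samples)
  qlen <- stats::setNames(transcripts$length, transcripts$transcript_id)
  write_repeatmasker_out(ann, paths$repeats_out, q_length = qlen)
  utils::write.table(data.frame(transcript_id = transcripts$transcript_id,
                                length = transcripts$length),
                     paths$lengths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (config$write_fasta) {
    seqs <- vapply(transcripts$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    writeLines(paste0(">", transcripts$transcript_id, "\n", seqs),
               paths$fasta)
  } else {
    paths$fasta <- NULL
  }
  busco_lines <- c("# BUSCO version is: 5.4.0",
                   "# The lineage dataset is: actinopterygii_odb10",
                   "# Busco id\tStatus\tSequence\tScore\tLength")
  brow <- ifelse(is.na(busco_tab$sequence),
                 paste(busco_tab$busco_id, busco_tab$status, sep = "\t"),
                 paste(busco_tab$busco_id, busco_tab$status,
                       busco_tab$sequence, "100.0", "500", sep = "\t"))
  writeLines(c(busco_lines, brow), paths$busco)
  write_gene_panel(panel, paths$panel)
  write_classification_table(default_classification_table(),
                             paths$classification)

  ## ---- ground-truth manifest ----
  elements$percent_control <- elements$base_percent
  elements$percent_test <- elements$base_percent * elements$fold_change
  elements$delta_percent <- elements$percent_test - elements$percent_control
  class_truth <- lapply(te_classes(), function(cl) {
    e <- elements[elements$te_class == cl, ]
    list(te_class = cl, percent_control = sum(e$percent_control),
         percent_test = sum(e$percent_test))
  })
  manifest <- list(
    seed = config$seed,
    conditions = list(control = cond_ctrl, test = cond_test),
    depth = config$depth, dispersion = config$dispersion,
    n_replicates = config$n_replicates,
    samples = data.frame(smp, lib_multiplier = lib,
                         total_mapped = unname(total_mapped)),
    unassigned_fraction = config$unassigned_fraction,
    elements = elements,
    te_class_percent = do.call(rbind, lapply(class_truth, as.data.frame)),
    total_te_percent = list(
      control = sum(elements$percent_control),
      test = sum(elements$percent_test)),
    genes = data.frame(gene = panel$gene,
                       transcript = unlist(panel$transcripts),
                       cds_length = panel$cds_length,
                       base_percent = 100 * config$gene_fraction / 100 * gw,
                       fold_change = gene_fc, row.names = NULL),
    busco = list(n_orthologs = config$n_orthologs,
                 n_by_status = as.list(table(statuses)),
                 busco_percent = config$busco_fraction),
    expected_scaling_factors = as.list(stats::setNames(mean(lib) / lib,
                                                       smp$sample_id))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(list(dir = outdir, paths = paths, manifest = manifest))
}

#' Ready-made simulation scenarios
#'
#' Three scenarios mirroring the tissue-specific response patterns the
#' pipeline is designed to detect:
#' \describe{
#'   \item{brain}{null — no condition effect on any class or gene; class
#'     abundances in the rank order DNA > LINE > Unclear > Retro > LTR >
#'     SINE > nonLTR.}
#'   \item{gill}{class-level shifts with a roughly flat total: DNA and Retro
#'     up at the test condition, LINE/LTR/non-LTR down.}
#'   \item{liver}{global activation — every class up except LINE, with two
#'     elements (DNA/hAT-Ac and LTR/DIRS) carrying most of their classes'
#'     increase, and silencing-gene upregulation (argonautes at 2-fold).}
#' }
#'
#' @param scenario One of \code{"brain"}, \code{"gill"}, \code{"liver"}.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A \code{sim_config}.
#' @export
scenario_config <- function(scenario = c("liver", "brain", "gill"), ...) {
  scenario <- match.arg(scenario)
  base_frac <- c(DNA = 6, LINE = 4, Unclear = 2.5, Retro = 1.5, LTR = 1,
                 SINE = 0.6, nonLTR = 0.3)
  args <- switch(scenario,
    brain = list(tissue = "brain", te_fraction_by_class = base_frac,
                 condition_effects = numeric(0)),
    gill = list(tissue = "gill", te_fraction_by_class = base_frac,
                condition_effects = c(DNA = 1.15, Retro = 1.4, LINE = 0.75,
                                      LTR = 0.7, nonLTR = 0.7)),
    liver = list(
      tissue = "liver",
      te_fraction_by_class = c(LINE = 5, DNA = 3.5, Unclear = 2,
                               Retro = 1.2, LTR = 0.8, SINE = 0.5,
                               nonLTR = 0.25),
      condition_effects = c(DNA = 1.8, "DNA/hAT-Ac" = 4, LTR = 2.5,
                            "LTR/DIRS" = 6, SINE = 2, Retro = 1.8,
                            Unclear = 1.5, nonLTR = 1.8, LINE = 0.75,
                            ago1 = 2, ago2 = 2, ago3 = 2, ago4 = 2,
                            dnmt1 = 1.8, cbx5 = 1.6, trim33 = 1.5,
                            hdac1 = 1.4, gatad2ab = 1.5, rbbp4 = 1.4,
                            tnrc6a = 1.6, tnrc6b = 1.6))
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
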