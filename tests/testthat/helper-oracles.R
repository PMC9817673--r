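# Independent brute-force oracles and fixture builders shared across tests.

# Random annotation sets over a handful of transcripts, mixing TE and non-TE
# families. Coordinates and scores are small so overlap clusters are common.
random_annotations <- function(n_hits = 30, n_tx = 5) {
  fams <- c("DNA/hAT-Ac", "DNA/TcMar-Tc1", "LINE/L1", "LTR/DIRS", "SINE/tRNA",
            "Penelope/Poseidon", "Retroposon/SVA-like", "Unknown",
            "Simple_repeat", "Low_complexity", "rRNA")
  qb <- sample(1:400, n_hits, replace = TRUE)
  len <- sample(1:120, n_hits, replace = TRUE)
  data.frame(
    query_id = paste0("tx", sample(n_tx, n_hits, replace = TRUE)),
    q_begin = qb, q_end = qb + len - 1L,
    sw_score = sample(1:1000, n_hits, replace = TRUE),
    perc_div = round(runif(n_hits, 0, 40), 1),
    perc_del = round(runif(n_hits, 0, 20), 1),
    perc_ins = round(runif(n_hits, 0, 20), 1),
    strand = sample(c("+", "C"), n_hits, replace = TRUE),
    repeat_name = paste0("rep", sample(20, n_hits, replace = TRUE)),
    repeat_class_family = sample(fams, n_hits, replace = TRUE),
    hit_id = seq_len(n_hits), overlap_flag = FALSE,
    stringsAsFactors = FALSE)
}

# Exhaustive overlap-cluster filter: pairwise overlap adjacency, connected
# components by fixed-point label propagation, then the full ordering rule
# applied per component. Deliberately O(n^2) and loop-based — an independent
# route from the package's coordinate sweep.
oracle_filter <- function(ann, table = default_classification_table()) {
  cls <- classify_repeat(ann$repeat_class_family, table)
  keep <- cls != "NonTE"
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0L) {
    ann$te_class <- character(0)
    rownames(ann) <- NULL
    return(ann)
  }
  ann$te_class <- cls[keep]
  ann$.i <- seq_len(nrow(ann))
  kept <- list()
  for (q in unique(ann$query_id)) {
    b <- ann[ann$query_id == q, , drop = FALSE]
    n <- nrow(b)
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (b$q_begin[i] <= b$q_end[j] && b$q_begin[j] <= b$q_end[i] &&
            lab[j] > lab[i]) {
          lab[j] <- lab[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (comp in unique(lab)) {
      cand <- b[lab == comp, , drop = FALSE]
      len <- cand$q_end - cand$q_begin + 1L
      best <- cand[order(-cand$sw_score, -len, cand$q_begin, cand$.i)[1], ,
                   drop = FALSE]
      kept[[length(kept) + 1L]] <- best
    }
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$query_id, out$q_begin, out$q_end), , drop = FALSE]
  out$.i <- NULL
  rownames(out) <- NULL
  out
}

# Tiny expression matrix: deterministic counts, explicit totals.
tiny_expr <- function(counts, total_mapped = NULL,
                      conditions = rep("A", ncol(counts))) {
  if (is.null(total_mapped))
    total_mapped <- colSums(counts) * 2
  samples <- data.frame(sample_id = colnames(counts), tissue = "liver",
                        condition = conditions,
                        replicate = as.integer(ave(seq_along(conditions),
                                                   conditions, FUN = seq_along)),
                        stringsAsFactors = FALSE)
  expression_matrix(counts, stats::setNames(total_mapped, colnames(counts)),
                    samples)
}

# One-annotation-per-row helper for constructing filtered sets by hand.
make_ann <- function(query_id, q_begin, q_end, sw_score, repeat_name,
                     repeat_class_family,
                     te_class = classify_repeat(repeat_class_family)) {
  data.frame(query_id = query_id, q_begin = as.integer(q_begin),
             q_end = as.integer(q_end), sw_score = as.integer(sw_score),
             perc_div = 10, perc_del = 1, perc_ins = 1, strand = "+",
             repeat_name = repeat_name,
             repeat_class_family = repeat_class_family,
             hit_id = seq_along(query_id), overlap_flag = FALSE,
             te_class = te_class, stringsAsFactors = FALSE)
}

pipeline_from_sim <- function(sim, outdir) {
  pipeline_config(repeats_out = sim$paths$repeats_out,
                  counts = sim$paths$counts, totals = sim$paths$totals,
                  samples = sim$paths$samples, busco = sim$paths$busco,
                  panel = sim$paths$panel, lengths = sim$paths$lengths,
                  classification = sim$paths$classification,
                  outdir = outdir)
}

# Small, fast simulation settings used wherever full scale is not the point.
small_sim <- function(scenario = NULL, ...) {
  defaults <- list(n_orthologs = 150L, n_background = 250L, depth = 1e6,
                   write_fasta = FALSE)
  args <- utils::modifyList(defaults, list(...))
  if (is.null(scenario)) do.call(simulation_config, args)
  else do.call(scenario_config, c(list(scenario = scenario), args))
}
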