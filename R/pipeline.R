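#' Pipeline run configuration
#'
#' Collects the file paths and options for a full run: annotation filtering,
#' TE activity quantification, ortholog calibration and condition
#' statistics. Conditions default to the order they appear in the sample
#' sheet (first = control).
#'
#' @param repeats_out RepeatMasker \code{.out} path.
#' @param counts,totals,samples Expression TSV paths (see
#'   [read_expression()]).
#' @param busco BUSCO \code{full_table.tsv} path.
#' @param panel Gene panel YAML path.
#' @param lengths Transcript lengths TSV or FASTA path (optional; enables
#'   the transcriptome TPM universe).
#' @param classification Classification-table TSV path; \code{NULL} uses
#'   [default_classification_table()].
#' @param outdir Output directory.
#' @param control_condition,test_condition Condition labels; \code{NULL}
#'   takes them from the sample sheet in order of appearance.
#' @param tissue Optional tissue filter; samples of other tissues are
#'   dropped before any computation.
#' @param attribution \code{"best"} or \code{"weighted"} (see
#'   [attribute_expression()]).
#' @param tpm_universe \code{"transcriptome"} or \code{"panel"}.
#' @param top_k Elements combined in contributor reports.
#' @return A \code{run_config} list.
#' @export
pipeline_config <- function(repeats_out, counts, totals, samples, busco,
                            panel, lengths = NULL, classification = NULL,
                            outdir = "tethermoscan_out",
                            control_condition = NULL, test_condition = NULL,
                            tissue = NULL,
                            attribution = c("best", "weighted"),
                            tpm_universe = c("transcriptome", "panel"),
                            top_k = 10L) {
  cfg <- list(repeats_out = repeats_out, counts = counts, totals = totals,
              samples = samples, busco = busco, panel = panel,
              lengths = lengths, classification = classification,
              outdir = outdir, control_condition = control_condition,
              test_condition = test_condition, tissue = tissue,
              attribution = match.arg(attribution),
              tpm_universe = match.arg(tpm_universe),
              top_k = as.integer(top_k))
  inputs <- c(cfg$repeats_out, cfg$counts, cfg$totals, cfg$samples,
              cfg$busco, cfg$panel, cfg$lengths, cfg$classification)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline config from YAML
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; relative paths are resolved against the YAML's
#'   directory.
#' @return A \code{run_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathify <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  for (k in c("repeats_out", "counts", "totals", "samples", "busco",
              "panel", "lengths", "classification")) {
    y[[k]] <- pathify(y[[k]])
  }
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes annotation filtering, activity quantification, contributor
#' decomposition, ortholog calibration, calibrated TPM and per-feature
#' ANOVA, writing every stage's table plus a markdown run report with
#' provenance (package version, config hash, input checksums). On a stage
#' failure a \code{FAILED} marker file is left in the output directory and
#' the error is re-raised; partial outputs are retained.
#'
#' @param config A \code{run_config} from [pipeline_config()].
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$outdir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  res <- tryCatch(
    run_pipeline_stages(config),
    error = function(e) {
      writeLines(conditionMessage(e), marker)
      stop(e)
    }
  )
  invisible(res)
}

run_pipeline_stages <- function(config) {
  out <- function(f) file.path(config$outdir, f)
  log_msg <- function(...) message("[tethermoscan] ", ...)

  log_msg("stage annotate: parsing and filtering ", config$repeats_out)
  table <- if (is.null(config$classification)) {
    default_classification_table()
  } else read_classification_table(config$classification)
  ann <- parse_repeatmasker_out(config$repeats_out)
  filtered <- filter_redundant(ann, table)
  write_filtered_annotations(filtered, out("filtered_annotations.tsv"))

  log_msg("stage quantify: TE activity as percent of mapped reads")
  expr <- read_expression(config$counts, config$totals, config$samples)
  if (!is.null(config$tissue)) {
    keep <- expr$samples$tissue == config$tissue
    expr <- expression_matrix(expr$counts[, keep, drop = FALSE],
                              expr$total_mapped[keep],
                              expr$samples[keep, , drop = FALSE])
  }
  conds <- unique(expr$samples$condition)
  cond_a <- config$control_condition %||% conds[1]
  cond_b <- config$test_condition %||% setdiff(conds, cond_a)[1]

  attributed <- attribute_expression(filtered, expr,
                                     attribution = config$attribution)
  activity <- aggregate_activity(attributed, expr)
  write_activity(activity, out("activity_by_class.tsv"),
                 level = c("class", "total"))
  write_activity(activity, out("activity_by_element.tsv"), level = "element")

  contributors <- list()
  for (cl in te_classes()) {
    rep_cl <- top_contributors(activity, cl, cond_a, cond_b,
                               k = config$top_k)
    contributors[[cl]] <- rep_cl
    utils::write.table(rep_cl$elements,
                       out(sprintf("contributors_%s.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_msg("stage calibrate: BUSCO ortholog scaling and gene TPM")
  records <- parse_busco_table(config$busco)
  cal <- build_calibration(records, expr)
  factors <- compute_scaling(cal)
  utils::write.table(
    data.frame(sample_id = names(factors$factors),
               cumulative = unname(cal$cumulative),
               factor = unname(factors$factors)),
    out("calibration_factors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  panel <- read_gene_panel(config$panel)
  lengths <- if (!is.null(config$lengths))
    read_transcript_lengths(config$lengths) else NULL
  universe <- if (is.null(lengths)) "panel" else config$tpm_universe
  tpm <- calibrated_tpm(panel, expr, factors, lengths = lengths,
                        tpm_universe = universe)
  utils::write.table(data.frame(gene = rownames(tpm), tpm,
                                check.names = FALSE),
                     out("gene_tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log_msg("stage stats: one-way ANOVA ", cond_a, " vs ", cond_b)
  te_vals <- activity_values(activity, "class")
  te_vals <- rbind(te_vals, TOTAL_TE = activity_values(activity, "total"))
  stats_te <- diff_stats(te_vals, expr$samples, cond_a, cond_b)
  utils::write.table(stats_te, out("stats_te.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stats_genes <- diff_stats(tpm, expr$samples, cond_a, cond_b)
  utils::write.table(stats_genes, out("stats_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- write_run_report(config, expr, stats_te, stats_genes,
                             contributors, factors,
                             out("report.md"), cond_a, cond_b)
  log_msg("done: ", config$outdir)
  invisible(list(filtered = filtered, activity = activity,
                 contributors = contributors, calibration = cal,
                 factors = factors, tpm = tpm, stats_te = stats_te,
                 stats_genes = stats_genes, report = report,
                 conditions = c(cond_a, cond_b), outdir = config$outdir))
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

write_run_report <- function(config, expr, stats_te, stats_genes,
                             contributors, factors, path, cond_a, cond_b) {
  cfg_snapshot <- tempfile()
  stable <- config[order(names(config))]
  jsonlite::write_json(stable[!vapply(stable, is.null, logical(1))],
                       cfg_snapshot, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_snapshot))
  unlink(cfg_snapshot)
  inputs <- c(config$repeats_out, config$counts, config$totals,
              config$samples, config$busco, config$panel, config$lengths,
              config$classification)
  sums <- tools::md5sum(inputs)

  lines <- c(
    "# TE activity run report",
    "",
    sprintf("- package: tethermoscan %s",
            as.character(utils::packageVersion("tethermoscan"))),
    sprintf("- config hash (md5): %s", cfg_hash),
    sprintf("- samples: %d (%s vs %s)", ncol(expr$counts), cond_a, cond_b),
    "",
    "## Input checksums",
    "",
    sprintf("- `%s` %s", basename(names(sums)), unname(sums)),
    "",
    "## TE activity (percent of mapped reads)",
    "",
    md_table(stats_te),
    "",
    "## Top contributors",
    ""
  )
  for (cl in names(contributors)) {
    r <- contributors[[cl]]
    lines <- c(lines, if (r$shares_defined) {
      sprintf("- %s: class delta %+.4f; top-%d elements carry %.1f%% of the change",
              cl, r$class_delta, r$k, 100 * r$top_k_share)
    } else {
      sprintf("- %s: class delta 0; shares undefined", cl)
    })
  }
  lines <- c(lines, "",
             "## Calibration",
             "",
             sprintf("- reference cumulative expression: %.2f",
                     factors$reference_value),
             sprintf("- scaling factors: %s",
                     paste(sprintf("%s=%.3f", names(factors$factors),
                                   factors$factors), collapse = ", ")),
             "",
             "## Silencing-gene statistics (calibrated TPM)",
             "",
             md_table(stats_genes))
  writeLines(lines, path)
  path
}
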