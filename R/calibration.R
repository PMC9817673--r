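#' Parse a BUSCO full table
#'
#' Reads BUSCO's \code{full_table.tsv} (comment lines starting with \code{#},
#' then tab-separated rows: busco id, status, sequence, ...). Rows of a
#' Duplicated ortholog — one line per copy — are merged into a single record
#' listing every copy's transcript.
#'
#' @param path Path to a \code{full_table.tsv}.
#' @return Data frame with columns \code{busco_id}, \code{status}
#'   (\code{Complete}, \code{Duplicated}, \code{Fragmented} or
#'   \code{Missing}) and list-column \code{transcript_ids} (empty for
#'   Missing).
#' @export
parse_busco_table <- function(path) {
  lines <- readLines(path)
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[is_data]
  line_no <- which(is_data)
  statuses <- c("Complete", "Duplicated", "Fragmented", "Missing")
  ids <- character(length(body))
  st <- character(length(body))
  tx <- character(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(body[i], "\t")[[1]]
    if (length(tok) == 1L) tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop("malformed BUSCO row at line ", line_no[i])
    if (!tok[2] %in% statuses)
      stop("unknown BUSCO status '", tok[2], "' at line ", line_no[i])
    ids[i] <- tok[1]
    st[i] <- tok[2]
    tx[i] <- if (tok[2] == "Missing" || length(tok) < 3L) NA_character_ else tok[3]
  }
  ord <- !duplicated(ids)
  recs <- data.frame(busco_id = ids[ord], status = st[ord],
                     stringsAsFactors = FALSE)
  recs$transcript_ids <- lapply(recs$busco_id, function(b) {
    v <- tx[ids == b]
    v[!is.na(v)]
  })
  n_tx <- lengths(recs$transcript_ids)
  if (any(recs$status == "Missing" & n_tx > 0))
    stop("Missing ortholog with a sequence entry")
  if (any(recs$status == "Duplicated" & n_tx < 2))
    stop("Duplicated ortholog with fewer than two copies")
  recs
}

#' Build the ortholog calibration set
#'
#' Applies the status rules to turn BUSCO records into per-sample ortholog
#' expression values: Complete (single copy) and Fragmented orthologs keep
#' their transcript's mapped-read count, Duplicated orthologs (transcript
#' isoforms) take the sum over their copies, and Missing orthologs are 0. The
#' per-sample sum of these values is the cumulative calibration expression.
#'
#' @param records BUSCO records from [parse_busco_table()].
#' @param expr An [expression_matrix()]. Transcripts named by BUSCO but
#'   absent from the matrix count as 0, with a warning.
#' @return A \code{calibration_set}: list with \code{values} (ortholog x
#'   sample matrix), \code{cumulative} (named per-sample sums) and
#'   \code{n_orthologs}.
#' @export
build_calibration <- function(records, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  smp <- colnames(expr$counts)
  all_tx <- unique(unlist(records$transcript_ids))
  absent <- setdiff(all_tx, rownames(expr$counts))
  if (length(absent))
    warning(length(absent), " BUSCO transcript(s) absent from counts ",
            "(counted as 0): ", paste(utils::head(absent, 5), collapse = ", "))
  vals <- matrix(0, nrow(records), length(smp),
                 dimnames = list(records$busco_id, smp))
  for (i in seq_len(nrow(records))) {
    tx <- intersect(records$transcript_ids[[i]], rownames(expr$counts))
    if (length(tx))
      vals[i, ] <- colSums(expr$counts[tx, , drop = FALSE])
  }
  structure(list(values = vals, cumulative = colSums(vals),
                 n_orthologs = nrow(records)),
            class = "calibration_set")
}

#' Per-sample scaling factors from a calibration set
#'
#' The reference value is the arithmetic mean of the per-sample cumulative
#' calibration expressions; each sample's factor is reference / cumulative,
#' so that after scaling every sample's calibration cumulative equals the
#' reference exactly. Factors multiply raw counts before any downstream
#' normalisation.
#'
#' @param cal A \code{calibration_set} from [build_calibration()].
#' @return List with \code{factors} (named per-sample positive floats) and
#'   \code{reference_value}.
#' @export
compute_scaling <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  zero <- names(cal$cumulative)[cal$cumulative <= 0]
  if (length(zero))
    stop("calibration cumulative is zero in sample(s): ",
         paste(zero, collapse = ", "), "; calibration impossible")
  ref <- mean(cal$cumulative)
  list(factors = ref / cal$cumulative, reference_value = ref)
}

#' The 34-gene TE-silencing panel
#'
#' Default panel of genes whose products silence transposable elements:
#' ten heterochromatin-formation genes (HP1-family chromobox genes, DNA
#' methyltransferases, setdb1 paralogues), sixteen NuRD-complex genes,
#' the four argonautes and four GW182-family (tnrc6) genes. CDS lengths are
#' representative teleost values in bp; transcript assignments are
#' dataset-specific and left empty here (the synthetic generator, or the
#' user's panel config, fills them in).
#'
#' @return Data frame with columns \code{gene}, \code{group},
#'   \code{cds_length} and empty list-column \code{transcripts}.
#' @export
silencing_gene_panel <- function() {
  g <- function(gene, group, len) data.frame(gene = gene, group = group,
                                             cds_length = len,
                                             stringsAsFactors = FALSE)
  panel <- rbind(
    g("cbx5", "heterochromatin", 576), g("cbx1a", "heterochromatin", 558),
    g("cbx1b", "heterochromatin", 561), g("cbx3a", "heterochromatin", 537),
    g("cbx3b", "heterochromatin", 540), g("dnmt1", "heterochromatin", 4449),
    g("dnmt3aa", "heterochromatin", 2745), g("dnmt3ab", "heterochromatin", 2694),
    g("setdb1a", "heterochromatin", 3861), g("setdb1b", "heterochromatin", 3789),
    g("krab-like", "NuRD", 1182), g("trim33", "NuRD", 3348),
    g("chd3", "NuRD", 5940), g("chd4a", "NuRD", 5862),
    g("chd4b", "NuRD", 5790), g("hdac1", "NuRD", 1446),
    g("mbd2", "NuRD", 1236), g("mbd3a", "NuRD", 873),
    g("mbd3b", "NuRD", 888), g("mta1", "NuRD", 2139),
    g("mta2", "NuRD", 2004), g("mta3", "NuRD", 1776),
    g("gatad2ab", "NuRD", 1842), g("gatad2b", "NuRD", 1785),
    g("rbbp4", "NuRD", 1278), g("rbbp7", "NuRD", 1275),
    g("ago1", "RISC", 2574), g("ago2", "RISC", 2604),
    g("ago3", "RISC", 2583), g("ago4", "RISC", 2565),
    g("tnrc6a", "GW182", 5490), g("tnrc6b", "GW182", 5244),
    g("tnrc6c1", "GW182", 4953), g("tnrc6c2", "GW182", 4890)
  )
  panel$transcripts <- vector("list", nrow(panel))
  panel
}

#' Read / write a gene panel config (YAML)
#'
#' The YAML maps each gene name to \code{transcripts} (a list of transcript
#' ids) and \code{cds_length} (bp), optionally \code{group}.
#'
#' @param path Panel YAML path.
#' @return Data frame with columns \code{gene}, \code{group},
#'   \code{cds_length}, list-column \code{transcripts}.
#' @rdname gene_panel_io
#' @export
read_gene_panel <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- data.frame(gene = names(y),
                      group = vapply(y, function(e) e$group %||% NA_character_,
                                     character(1)),
                      cds_length = vapply(y, function(e) as.numeric(e$cds_length),
                                          numeric(1)),
                      stringsAsFactors = FALSE)
  panel$transcripts <- lapply(y, function(e) as.character(unlist(e$transcripts)))
  if (anyDuplicated(panel$gene)) stop("duplicate gene names in panel")
  if (any(panel$cds_length <= 0)) stop("non-positive CDS length in panel")
  rownames(panel) <- NULL
  panel
}

#' @param panel Panel data frame.
#' @rdname gene_panel_io
#' @export
write_gene_panel <- function(panel, path) {
  y <- lapply(seq_len(nrow(panel)), function(i) {
    list(group = panel$group[i],
         cds_length = panel$cds_length[i],
         transcripts = as.list(panel$transcripts[[i]]))
  })
  names(y) <- panel$gene
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrated TPM for a gene panel
#'
#' Applies the per-sample scaling factors to the genes' raw counts, converts
#' to length-normalised rates (scaled count per kb of CDS) and rescales
#' rates to sum to one million. The rate universe is either the full
#' transcriptome (when per-transcript lengths are supplied; scaled
#' transcript-level rates form the denominator) or the panel itself.
#'
#' @param panel Gene panel data frame with filled \code{transcripts}.
#' @param expr An [expression_matrix()].
#' @param factors Result of [compute_scaling()].
#' @param lengths Named per-transcript lengths (bp); required for
#'   \code{tpm_universe = "transcriptome"}.
#' @param tpm_universe \code{"transcriptome"} or \code{"panel"}.
#' @return Gene x sample matrix of calibrated TPM.
#' @export
calibrated_tpm <- function(panel, expr, factors,
                           lengths = NULL,
                           tpm_universe = c("transcriptome", "panel")) {
  tpm_universe <- match.arg(tpm_universe)
  stopifnot(inherits(expr, "expr_matrix"))
  f <- factors$factors[colnames(expr$counts)]
  if (anyNA(f)) stop("scaling factors missing for some samples")

  gene_counts <- matrix(0, nrow(panel), ncol(expr$counts),
                        dimnames = list(panel$gene, colnames(expr$counts)))
  for (i in seq_len(nrow(panel))) {
    tx <- intersect(panel$transcripts[[i]], rownames(expr$counts))
    if (length(tx) == 0L) {
      warning("gene '", panel$gene[i], "' has no transcript in the count ",
              "matrix; TPM set to 0")
    } else {
      gene_counts[i, ] <- colSums(expr$counts[tx, , drop = FALSE])
    }
  }
  scaled <- sweep(gene_counts, 2, f, "*")
  gene_rate <- scaled / (panel$cds_length / 1000)

  denom <- if (tpm_universe == "transcriptome") {
    if (is.null(lengths))
      stop("transcript lengths are required for tpm_universe = 'transcriptome'")
    len <- lengths[rownames(expr$counts)]
    if (anyNA(len)) stop("lengths missing for some transcripts")
    tx_rate <- sweep(expr$counts / (len / 1000), 2, f, "*")
    colSums(tx_rate)
  } else {
    colSums(gene_rate)
  }
  zero <- denom <= 0
  denom[zero] <- 1  # all-zero rate column: TPM is identically 0
  tpm <- sweep(gene_rate, 2, denom, "/") * 1e6
  tpm[, zero] <- 0
  tpm
}
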