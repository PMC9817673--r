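#' Construct an expression matrix
#'
#' Bundles the transcript-by-sample mapped-read counts with each sample's
#' total mapped reads (the denominator of every percent-of-mapped-reads
#' value) and the sample sheet.
#'
#' @param counts Numeric matrix, transcripts in rows (rownames required),
#'   samples in columns (colnames required); non-negative mapped-read counts.
#' @param total_mapped Named numeric vector of total mapped reads per sample,
#'   names matching \code{colnames(counts)}; each at least the column sum of
#'   \code{counts} (reads can map outside the annotated transcripts, never
#'   the reverse).
#' @param samples Data frame with columns \code{sample_id}, \code{tissue},
#'   \code{condition}, \code{replicate}; one row per sample.
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{counts}, \code{total_mapped} and \code{samples}.
#' @export
expression_matrix <- function(counts, total_mapped, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and sample colnames")
  if (any(counts < 0)) stop("negative counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sample sheet")
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample sheet and count matrix name different samples")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  total_mapped <- total_mapped[colnames(counts)]
  if (anyNA(total_mapped)) stop("total_mapped missing for some samples")
  short <- colSums(counts) > total_mapped + 1e-8
  if (any(short))
    stop("transcript counts exceed total mapped reads in sample(s): ",
         paste(colnames(counts)[short], collapse = ", "))
  structure(list(counts = counts, total_mapped = total_mapped,
                 samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from TSV files
#'
#' @param counts_path Counts TSV: first column transcript id, remaining
#'   columns one per sample (header row of sample ids).
#' @param totals_path Two-column TSV \code{sample_id, total_mapped}.
#' @param samples_path Sample sheet TSV with columns \code{sample_id},
#'   \code{tissue}, \code{condition}, \code{replicate}.
#' @return An \code{expr_matrix}.
#' @export
read_expression <- function(counts_path, totals_path, samples_path) {
  counts <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE)
  totals <- utils::read.table(totals_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  samples <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  tm <- stats::setNames(totals$total_mapped, totals$sample_id)
  expression_matrix(as.matrix(counts), tm, samples)
}

#' Write expression inputs as TSV files
#'
#' Inverse of [read_expression()]; used by the synthetic generator.
#'
#' @param expr An \code{expr_matrix}.
#' @param counts_path,totals_path,samples_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_expression <- function(expr, counts_path, totals_path, samples_path) {
  df <- data.frame(transcript_id = rownames(expr$counts),
                   expr$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(expr$total_mapped),
                                total_mapped = unname(expr$total_mapped)),
                     totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, totals_path, samples_path))
}

#' Read transcript lengths
#'
#' Accepts either a two-column TSV (\code{transcript_id, length}) or a FASTA
#' file, from which sequence lengths are taken.
#'
#' @param path Path to a lengths TSV or FASTA file.
#' @return Named numeric vector of transcript lengths (bp).
#' @export
read_transcript_lengths <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    lens <- Biostrings::fasta.seqlengths(path)
    names(lens) <- sub("\\s.*$", "", names(lens))
    stats::setNames(as.numeric(lens), names(lens))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stats::setNames(as.numeric(tab[[2]]), tab[[1]])
  }
}
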