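#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard fixed-layout RepeatMasker \code{.out} file (two header
#' lines plus one blank line, then one whitespace-delimited row per hit) into
#' a data frame of repeat annotations on the query transcripts.
#'
#' Coordinates are 1-based and inclusive, as in the file itself. The
#' parenthesised "(left)" remainder columns are validated as numbers but not
#' retained. Hits on the reverse strand carry strand \code{"C"} and have their
#' repeat-consensus coordinate columns in the reversed order used by
#' RepeatMasker; both layouts are accepted.
#'
#' @param path Path to a RepeatMasker \code{.out} file.
#' @return A data frame with one row per hit and columns \code{query_id},
#'   \code{q_begin}, \code{q_end}, \code{sw_score}, \code{perc_div},
#'   \code{perc_del}, \code{perc_ins}, \code{strand}, \code{repeat_name},
#'   \code{repeat_class_family}, \code{hit_id}, \code{overlap_flag}. Row order
#'   follows the file. An annotation file with no data lines yields a
#'   zero-row data frame.
#' @seealso [write_repeatmasker_out()], [filter_redundant()]
#' @export
parse_repeatmasker_out <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) > 3L) {
    body <- lines[-(1:3)]
  } else {
    body <- character(0)
  }
  keep <- nzchar(trimws(body))
  body <- body[keep]
  line_no <- which(c(rep(FALSE, min(3L, length(lines))), keep))
  if (length(body) == 0L) return(empty_annotations())

  parse_one <- function(ln, no) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 15L || length(tok) > 16L) {
      stop("malformed RepeatMasker line ", no, ": expected 15-16 fields, got ",
           length(tok), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(tok[c(1:4, 6:7)]))
    if (anyNA(num)) {
      stop("malformed RepeatMasker line ", no, ": non-numeric score/coords",
           call. = FALSE)
    }
    # repeat-consensus coordinates: one of fields 12..14 is "(left)"
    rc <- tok[12:14]
    rc_num <- suppressWarnings(as.numeric(gsub("[()]", "", rc)))
    if (anyNA(rc_num)) {
      stop("malformed RepeatMasker line ", no, ": bad repeat coordinates",
           call. = FALSE)
    }
    id <- suppressWarnings(as.integer(tok[15]))
    if (is.na(id)) {
      stop("malformed RepeatMasker line ", no, ": bad hit ID", call. = FALSE)
    }
    if (!tok[9] %in% c("+", "C")) {
      stop("malformed RepeatMasker line ", no, ": strand must be + or C",
           call. = FALSE)
    }
    list(query_id = tok[5], q_begin = as.integer(num[5]),
         q_end = as.integer(num[6]), sw_score = as.integer(num[1]),
         perc_div = num[2], perc_del = num[3], perc_ins = num[4],
         strand = tok[9], repeat_name = tok[10],
         repeat_class_family = tok[11], hit_id = id,
         overlap_flag = length(tok) == 16L && tok[16] == "*")
  }

  rows <- mapply(parse_one, body, line_no, SIMPLIFY = FALSE)
  ann <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(ann) <- NULL
  validate_annotations(ann)
  ann
}

empty_annotations <- function() {
  data.frame(query_id = character(0), q_begin = integer(0),
             q_end = integer(0), sw_score = integer(0),
             perc_div = numeric(0), perc_del = numeric(0),
             perc_ins = numeric(0), strand = character(0),
             repeat_name = character(0), repeat_class_family = character(0),
             hit_id = integer(0), overlap_flag = logical(0),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann) {
  bad <- which(ann$q_begin > ann$q_end)
  if (length(bad)) stop("annotation ", bad[1], ": q_begin > q_end")
  if (any(ann$sw_score < 0)) stop("negative Smith-Waterman score")
  pct <- c(ann$perc_div, ann$perc_del, ann$perc_ins)
  if (any(pct < 0 | pct > 100)) stop("divergence/deletion/insertion percentage outside [0, 100]")
  invisible(ann)
}

#' Write annotations as a RepeatMasker .out file
#'
#' Emits the canonical \code{.out} layout (two header lines, one blank line,
#' whitespace-separated data rows) so that files produced by the synthetic
#' generator are read back by [parse_repeatmasker_out()] unchanged. Repeat
#' consensus coordinates are reconstructed from the query alignment span.
#'
#' @param ann Annotation data frame as returned by [parse_repeatmasker_out()].
#' @param path Output file path.
#' @param q_length Optional named vector of transcript lengths used to fill
#'   the query "(left)" column; transcripts not named get a remainder of 0.
#' @return The path, invisibly.
#' @export
write_repeatmasker_out <- function(ann, path, q_length = NULL) {
  header <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score   div. del. ins.  sequence   begin end          (left)   repeat         class/family      begin  end    (left)   ID",
    ""
  )
  fmt_row <- function(i) {
    r <- ann[i, ]
    left <- if (!is.null(q_length) && r$query_id %in% names(q_length)) {
      q_length[[r$query_id]] - r$q_end
    } else 0L
    alen <- r$q_end - r$q_begin + 1L
    rcoord <- if (r$strand == "+") {
      sprintf("%d %d (0)", 1L, alen)
    } else {
      sprintf("(0) %d %d", alen, 1L)
    }
    sprintf("%5d %6.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %s %d%s",
            r$sw_score, r$perc_div, r$perc_del, r$perc_ins, r$query_id,
            r$q_begin, r$q_end, left, r$strand, r$repeat_name,
            r$repeat_class_family, rcoord, r$hit_id,
            if (isTRUE(r$overlap_flag)) " *" else "")
  }
  rows <- if (nrow(ann)) vapply(seq_len(nrow(ann)), fmt_row, character(1)) else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the filtered annotation set as TSV
#'
#' @param ann Filtered annotation data frame (with a \code{te_class} column,
#'   as returned by [filter_redundant()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_filtered_annotations <- function(ann, path) {
  cols <- c("query_id", "q_begin", "q_end", "sw_score", "repeat_name",
            "repeat_class_family", "te_class")
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a filtered annotation TSV back into a data frame
#' @param path TSV written by [write_filtered_annotations()].
#' @return Data frame of filtered annotations.
#' @export
read_filtered_annotations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
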