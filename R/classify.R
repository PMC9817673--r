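#' TE activity categories
#'
#' The seven categories under which transcriptional activity is totalled:
#' DNA transposons, LINE, LTR (including endogenous retroviruses), non-LTR
#' retroelements outside LINE/SINE (including Penelope), Retro (retroelements
#' unassignable to a subclass), SINE, and Unclear (repeats without features
#' that determine a class). \code{NonTE} marks entries (simple repeats, low
#' complexity, satellites, structural RNAs) that are removed before any
#' activity is computed and never counted.
#'
#' @return Character vector of the seven countable categories.
#' @export
te_classes <- function() {
  c("DNA", "LINE", "LTR", "nonLTR", "Retro", "SINE", "Unclear")
}

#' Default repeat classification table
#'
#' Ordered regular-expression rules mapping RepeatMasker class/family strings
#' to TE activity categories; the first matching rule wins and unmatched
#' strings fall through to \code{Unclear}. Non-TE annotation types are routed
#' to \code{NonTE} before any family prefix is considered, and Penelope /
#' literal "non-LTR" strings are tested before the LINE prefix so that
#' Penelope-bearing family strings land in the non-LTR category. Helitrons
#' ("RC") are counted with the DNA transposons (class II).
#'
#' The same table ships as a plain TSV config
#' (\code{system.file("extdata", "te_classification.tsv", package =
#' "tethermoscan")}) so the category boundaries can be edited per study.
#'
#' @return Data frame with columns \code{pattern} (regex) and \code{te_class}.
#' @seealso [classify_repeat()], [read_classification_table()]
#' @export
default_classification_table <- function() {
  rules <- matrix(c(
    "^Simple_repeat",  "NonTE",
    "^Low_complexity", "NonTE",
    "^Satellite",      "NonTE",
    "^rRNA",           "NonTE",
    "^tRNA",           "NonTE",
    "^snRNA",          "NonTE",
    "^scRNA",          "NonTE",
    "^srpRNA",         "NonTE",
    "^ARTEFACT",       "NonTE",
    "Penelope",        "nonLTR",
    "non-LTR",         "nonLTR",
    "^DNA",            "DNA",
    "^RC",             "DNA",
    "^LINE",           "LINE",
    "^SINE",           "SINE",
    "^LTR",            "LTR",
    "^Retroposon",     "Retro",
    "^Retro",          "Retro",
    "^Unknown",        "Unclear",
    "^Unspecified",    "Unclear"
  ), ncol = 2, byrow = TRUE)
  data.frame(pattern = rules[, 1], te_class = rules[, 2],
             stringsAsFactors = FALSE)
}

#' Read / write a classification table config
#'
#' @param path TSV with columns \code{pattern} and \code{te_class}, applied
#'   in file order (first match wins).
#' @return Classification table data frame.
#' @rdname classification_table_io
#' @export
read_classification_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("pattern", "te_class") %in% names(tab)))
  ok <- tab$te_class %in% c(te_classes(), "NonTE")
  if (!all(ok)) stop("unknown te_class in classification table: ",
                     paste(unique(tab$te_class[!ok]), collapse = ", "))
  tab
}

#' @param table Classification table data frame.
#' @rdname classification_table_io
#' @export
write_classification_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify repeat class/family strings into TE categories
#'
#' Applies the ordered rules of a classification table to each class/family
#' string; the first rule whose pattern matches decides the category, and a
#' string matching no rule is \code{Unclear}. The function is total: every
#' input yields exactly one category.
#'
#' @param class_family Character vector of RepeatMasker class/family strings,
#'   e.g. \code{"DNA/hAT-Ac"}.
#' @param table Classification table; defaults to
#'   [default_classification_table()].
#' @return Character vector of categories (one of [te_classes()] or
#'   \code{"NonTE"}).
#' @examples
#' classify_repeat(c("DNA/hAT-Ac", "LTR/DIRS", "Simple_repeat", "Unknown"))
#' @export
classify_repeat <- function(class_family, table = default_classification_table()) {
  stopifnot(is.character(class_family))
  out <- rep("Unclear", length(class_family))
  undecided <- rep(TRUE, length(class_family))
  for (i in seq_len(nrow(table))) {
    hit <- undecided & grepl(table$pattern[i], class_family)
    out[hit] <- table$te_class[i]
    undecided <- undecided & !hit
    if (!any(undecided)) break
  }
  out
}

#' Resolve redundant RepeatMasker hits
#'
#' Removes annotations classified as \code{NonTE}, then resolves overlapping
#' hits on each transcript: hits whose query intervals overlap by at least
#' one base are grouped into transitive overlap clusters, and from each
#' cluster a single hit survives — the highest Smith-Waterman score, ties
#' broken by the greatest query alignment length, then by the smallest start
#' coordinate, then by input order. Non-overlapping hits on the same
#' transcript all survive, so a transcript may retain several distinct
#' elements.
#'
#' The operation is idempotent and its result carries no overlapping pair.
#'
#' @param ann Annotation data frame from [parse_repeatmasker_out()].
#' @param table Classification table used to identify \code{NonTE} entries
#'   and to attach a \code{te_class} column to the output.
#' @return Filtered annotation data frame, sorted by \code{(query_id,
#'   q_begin)}, with an extra \code{te_class} column.
#' @export
filter_redundant <- function(ann, table = default_classification_table()) {
  validate_annotations(ann)
  if (nrow(ann) == 0L) {
    out <- ann
    out$te_class <- character(0)
    return(out)
  }
  cls <- classify_repeat(ann$repeat_class_family, table)
  keep <- cls != "NonTE"
  ann <- ann[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(ann) == 0L) {
    out <- ann
    out$te_class <- character(0)
    rownames(out) <- NULL
    return(out)
  }
  ann$te_class <- cls
  ann$.orig <- seq_len(nrow(ann))

  pick <- function(block) {
    # sweep in coordinate order, chaining transitive overlaps into clusters
    o <- order(block$q_begin, block$q_end, block$.orig)
    block <- block[o, , drop = FALSE]
    cluster <- integer(nrow(block))
    cur <- 0L
    cur_end <- -Inf
    for (i in seq_len(nrow(block))) {
      if (block$q_begin[i] > cur_end) cur <- cur + 1L
      cluster[i] <- cur
      cur_end <- max(cur_end, block$q_end[i])
    }
    sel <- vapply(split(seq_len(nrow(block)), cluster), function(idx) {
      b <- block[idx, , drop = FALSE]
      len <- b$q_end - b$q_begin + 1L
      idx[order(-b$sw_score, -len, b$q_begin, b$.orig)[1]]
    }, integer(1))
    block[sort(sel), , drop = FALSE]
  }

  parts <- lapply(split(ann, ann$query_id), pick)
  out <- do.call(rbind, parts)
  out <- out[order(out$query_id, out$q_begin, out$q_end), , drop = FALSE]
  out$.orig <- NULL
  rownames(out) <- NULL
  out
}
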