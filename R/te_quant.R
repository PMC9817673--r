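#' Attribute transcript counts to TE elements
#'
#' Joins the filtered annotation set with the count matrix. Each annotated
#' transcript's whole mapped-read count is attributed to exactly one element:
#' the transcript's retained annotation with the highest Smith-Waterman
#' score, ties broken by the longest query alignment and then the leftmost
#' start (\code{attribution = "best"}, the default). With
#' \code{attribution = "weighted"} the count is instead split across the
#' transcript's retained elements pro rata by aligned bases.
#'
#' The element key is the repeat class/family string (e.g. \code{"LTR/DIRS"})
#' when a single repeat name occurs in that family, and
#' \code{"class_family/repeat_name"} when distinct names share a family, so
#' keys stay unambiguous. Transcripts without any retained TE annotation
#' contribute to nothing.
#'
#' @param filtered Filtered annotation data frame from [filter_redundant()].
#' @param expr An [expression_matrix()].
#' @param attribution \code{"best"} (whole count to the best element) or
#'   \code{"weighted"} (split by aligned bases).
#' @return List with \code{counts} — an element-by-sample numeric matrix —
#'   and \code{elements} — a data frame mapping each element key to its
#'   \code{repeat_class_family} and \code{te_class}.
#' @export
attribute_expression <- function(filtered, expr,
                                 attribution = c("best", "weighted")) {
  attribution <- match.arg(attribution)
  stopifnot(inherits(expr, "expr_matrix"))
  ns <- ncol(expr$counts)
  if (nrow(filtered) == 0L) {
    warning("no retained TE annotations; activity is empty")
    return(list(counts = matrix(0, 0, ns,
                                dimnames = list(NULL, colnames(expr$counts))),
                elements = data.frame(element = character(0),
                                      repeat_class_family = character(0),
                                      te_class = character(0))))
  }
  missing_tx <- setdiff(unique(filtered$query_id), rownames(expr$counts))
  if (length(missing_tx))
    warning(length(missing_tx),
            " annotated transcript(s) absent from the count matrix: ",
            paste(utils::head(missing_tx, 5), collapse = ", "),
            if (length(missing_tx) > 5) ", ...")
  filtered <- filtered[filtered$query_id %in% rownames(expr$counts), ,
                       drop = FALSE]

  # element keys: family string alone unless several repeat names share it
  fam_names <- tapply(filtered$repeat_name, filtered$repeat_class_family,
                      function(x) length(unique(x)))
  multi <- names(fam_names)[fam_names > 1]
  key <- ifelse(filtered$repeat_class_family %in% multi,
                paste(filtered$repeat_class_family, filtered$repeat_name,
                      sep = "/"),
                filtered$repeat_class_family)
  filtered$element <- key

  elements <- unique(filtered[, c("element", "repeat_class_family",
                                  "te_class")])
  elements <- elements[order(elements$element), , drop = FALSE]
  rownames(elements) <- NULL

  counts <- matrix(0, nrow(elements), ncol(expr$counts),
                   dimnames = list(elements$element, colnames(expr$counts)))
  if (attribution == "best") {
    by_tx <- split(seq_len(nrow(filtered)), filtered$query_id)
    for (tx in names(by_tx)) {
      idx <- by_tx[[tx]]
      b <- filtered[idx, , drop = FALSE]
      len <- b$q_end - b$q_begin + 1L
      best <- idx[order(-b$sw_score, -len, b$q_begin)[1]]
      counts[filtered$element[best], ] <-
        counts[filtered$element[best], ] + expr$counts[tx, ]
    }
  } else {
    len <- filtered$q_end - filtered$q_begin + 1L
    by_tx <- split(seq_len(nrow(filtered)), filtered$query_id)
    for (tx in names(by_tx)) {
      idx <- by_tx[[tx]]
      w <- tapply(len[idx], filtered$element[idx], sum)
      w <- w / sum(w)
      for (el in names(w)) {
        counts[el, ] <- counts[el, ] + w[[el]] * expr$counts[tx, ]
      }
    }
  }
  list(counts = counts, elements = elements)
}

#' Aggregate attributed counts into a TE activity table
#'
#' Converts element-level counts into percent of mapped reads per sample
#' (100 x count / total mapped reads) and rolls them up: element rows sum
#' into type rows (one per repeat class/family), type rows into class rows
#' (the seven activity categories), and class rows into a single
#' \code{TOTAL_TE} row. The roll-up conserves mass at every level.
#'
#' @param attributed Result of [attribute_expression()].
#' @param expr The same [expression_matrix()] used for attribution.
#' @return An \code{activity_table}: data frame with columns \code{level}
#'   (\code{element}/\code{type}/\code{class}/\code{total}), \code{key},
#'   \code{te_class}, then one numeric column per sample. The sample sheet
#'   travels along as attribute \code{"samples"}.
#' @export
aggregate_activity <- function(attributed, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  zero <- names(expr$total_mapped)[expr$total_mapped <= 0]
  if (length(zero))
    stop("total mapped reads is zero in sample(s): ",
         paste(zero, collapse = ", "))
  smp <- colnames(expr$counts)
  el <- attributed$counts
  pct <- sweep(el, 2, expr$total_mapped, "/") * 100

  roll <- function(groups) {
    if (nrow(pct) == 0L)
      return(matrix(0, 0, length(smp), dimnames = list(NULL, smp)))
    rowsum(pct, groups, reorder = TRUE)
  }
  info <- attributed$elements
  type_pct <- roll(info$repeat_class_family)
  class_pct <- roll(info$te_class)
  # all seven categories always present, zero-filled
  full <- matrix(0, length(te_classes()), length(smp),
                 dimnames = list(te_classes(), smp))
  present <- intersect(rownames(class_pct), te_classes())
  full[present, ] <- class_pct[present, , drop = FALSE]
  total <- colSums(full)

  type_class <- info$te_class[match(rownames(type_pct),
                                    info$repeat_class_family)]
  block <- function(level, mat, te_class) {
    keys <- rownames(mat)
    if (is.null(keys)) keys <- character(0)
    data.frame(level = rep(level, length(keys)), key = keys,
               te_class = te_class, mat,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(
    block("element", pct, info$te_class[match(rownames(pct), info$element)]),
    block("type", type_pct, type_class),
    data.frame(level = "class", key = rownames(full),
               te_class = rownames(full), full,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(level = "total", key = "TOTAL_TE", te_class = NA_character_,
               t(total), check.names = FALSE, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "samples") <- expr$samples
  class(out) <- c("activity_table", class(out))
  out
}

activity_values <- function(activity, level, keys = NULL) {
  smp <- attr(activity, "samples")$sample_id
  rows <- activity[activity$level == level, , drop = FALSE]
  if (!is.null(keys)) rows <- rows[rows$key %in% keys, , drop = FALSE]
  m <- as.matrix(rows[, smp, drop = FALSE])
  rownames(m) <- rows$key
  m
}

#' Rank the elements driving a class-level activity change
#'
#' For one TE category, computes each element's change in percent of mapped
#' reads between the replicate means of two conditions, ranks elements by
#' absolute change, and reports each element's share of the class-level
#' change together with the combined share of the top \code{k} elements.
#'
#' @param activity An \code{activity_table} from [aggregate_activity()].
#' @param te_class One of [te_classes()].
#' @param cond_a,cond_b Condition labels (change is \code{cond_b - cond_a}).
#' @param k Number of leading elements to combine (default 10).
#' @return A \code{contributor_report} list: \code{te_class}, \code{cond_a},
#'   \code{cond_b}, \code{class_delta}, \code{elements} (data frame with
#'   \code{element}, \code{delta}, \code{share}, sorted by absolute change),
#'   \code{top_k_share}, \code{k} and \code{shares_defined} (FALSE when the
#'   class-level change is zero, in which case shares are omitted).
#' @export
top_contributors <- function(activity, te_class, cond_a, cond_b, k = 10L) {
  stopifnot(k >= 1L, te_class %in% te_classes())
  samples <- attr(activity, "samples")
  for (cond in c(cond_a, cond_b)) {
    if (!any(samples$condition == cond))
      stop("condition not present in sample sheet: ", cond)
  }
  el_rows <- activity[activity$level == "element" &
                        activity$te_class == te_class, , drop = FALSE]
  m <- as.matrix(el_rows[, samples$sample_id, drop = FALSE])
  rownames(m) <- el_rows$key
  mean_in <- function(cond) {
    rowMeans(m[, samples$condition == cond, drop = FALSE])
  }
  delta <- mean_in(cond_b) - mean_in(cond_a)
  class_delta <- sum(delta)
  ord <- order(-abs(delta))
  elements <- data.frame(element = rownames(m)[ord],
                         delta = unname(delta[ord]),
                         stringsAsFactors = FALSE)
  shares_defined <- class_delta != 0
  if (shares_defined) {
    elements$share <- elements$delta / class_delta
    top_k_share <- sum(elements$share[seq_len(min(k, nrow(elements)))])
  } else {
    top_k_share <- NA_real_
  }
  structure(list(te_class = te_class, cond_a = cond_a, cond_b = cond_b,
                 class_delta = class_delta, elements = elements,
                 top_k_share = top_k_share, k = as.integer(k),
                 shares_defined = shares_defined),
            class = "contributor_report")
}

#' @export
print.contributor_report <- function(x, ...) {
  cat(sprintf("Top contributors, %s: %s -> %s (class delta %+.4f %%)\n",
              x$te_class, x$cond_a, x$cond_b, x$class_delta))
  if (x$shares_defined) {
    cat(sprintf("top-%d combined share: %.2f%%\n", x$k, 100 * x$top_k_share))
  } else {
    cat("class-level change is zero; shares undefined\n")
  }
  print(utils::head(x$elements, x$k))
  invisible(x)
}

#' Write an activity table (or one level of it) as TSV
#' @param activity An \code{activity_table}.
#' @param path Output path.
#' @param level Optional level filter (\code{"element"}, \code{"type"},
#'   \code{"class"}, \code{"total"}).
#' @return The path, invisibly.
#' @export
write_activity <- function(activity, path, level = NULL) {
  out <- as.data.frame(activity)
  if (!is.null(level)) out <- out[out$level %in% level, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
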