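#' Classical one-way fixed-effects ANOVA
#'
#' Partitions the total sum of squares into between- and within-group parts
#' and refers the F ratio to the F distribution with (groups - 1,
#' N - groups) degrees of freedom. For two groups the statistic equals the
#' square of the pooled-variance two-sample t statistic.
#'
#' Degenerate inputs are flagged rather than hidden: zero within-group
#' variance with unequal means gives an infinite F and p = 0 with
#' \code{degenerate = TRUE}; identical groups give F = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group; at least two groups
#'   with at least two finite observations each.
#' @return An \code{anova_result} list: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p_value}, \code{stars}, \code{group_means},
#'   \code{group_sems}, \code{degenerate}.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5 on (1, 4) df
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs at least two observations")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop("non-finite observations")
  k <- length(groups)
  N <- sum(n)
  gm <- vapply(groups, mean, numeric(1))
  grand <- mean(x)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  degenerate <- FALSE
  if (ssw == 0) {
    if (ssb == 0) {
      F <- 0
      p <- 1
    } else {
      F <- Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    F <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  }
  sems <- vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1))
  structure(list(F = F, df_between = dfb, df_within = dfw, p_value = p,
                 stars = star_annotation(p), group_means = gm,
                 group_sems = sems, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s\n",
              x$df_between, x$df_within, x$F, x$p_value, x$stars))
  invisible(x)
}

#' Significance stars for p-values
#'
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for p < 0.05,
#' empty otherwise; thresholds are strict inequalities.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Character vector of star strings.
#' @export
star_annotation <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

#' Replicate mean and standard error per condition
#'
#' @param values_by_condition Named list of replicate value vectors, one
#'   entry per condition, each with at least two replicates.
#' @return Data frame with columns \code{condition}, \code{mean}, \code{sem}
#'   (sample SD over \eqn{\sqrt n}) and \code{n}.
#' @export
summarize_replicates <- function(values_by_condition) {
  stopifnot(is.list(values_by_condition), length(values_by_condition) >= 1L)
  n <- lengths(values_by_condition)
  if (any(n < 2L))
    stop("standard error undefined with fewer than two replicates")
  data.frame(condition = names(values_by_condition),
             mean = vapply(values_by_condition, mean, numeric(1)),
             sem = vapply(values_by_condition,
                          function(v) stats::sd(v) / sqrt(length(v)),
                          numeric(1)),
             n = as.integer(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-feature condition statistics table
#'
#' Runs [one_way_anova()] on every row of a feature-by-sample value matrix,
#' comparing two conditions on whatever scale the matrix carries (percent of
#' mapped reads for TE features, calibrated TPM for genes). Emits the
#' replicate means and standard errors per condition, F, degrees of freedom,
#' the raw p-value with its star annotation, and — as an additional column
#' that never feeds the stars — the Benjamini-Hochberg adjusted p-value.
#'
#' @param values Numeric feature x sample matrix.
#' @param samples Sample sheet data frame (\code{sample_id},
#'   \code{condition}, ...).
#' @param cond_a,cond_b The two condition labels to compare.
#' @return Data frame with one row per feature: \code{feature},
#'   \code{mean_<cond>}, \code{sem_<cond>}, \code{F}, \code{df_between},
#'   \code{df_within}, \code{p_value}, \code{stars}, \code{p_bh}.
#' @export
diff_stats <- function(values, samples, cond_a, cond_b) {
  values <- as.matrix(values)
  a <- samples$sample_id[samples$condition == cond_a]
  b <- samples$sample_id[samples$condition == cond_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two replicates per condition")
  res <- lapply(seq_len(nrow(values)), function(i) {
    one_way_anova(list(values[i, a], values[i, b]))
  })
  out <- data.frame(
    feature = rownames(values),
    mean_a = vapply(res, function(r) r$group_means[1], numeric(1)),
    sem_a = vapply(res, function(r) r$group_sems[1], numeric(1)),
    mean_b = vapply(res, function(r) r$group_means[2], numeric(1)),
    sem_b = vapply(res, function(r) r$group_sems[2], numeric(1)),
    F = vapply(res, function(r) r$F, numeric(1)),
    df_between = vapply(res, function(r) r$df_between, integer(1)),
    df_within = vapply(res, function(r) r$df_within, integer(1)),
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    stars = vapply(res, function(r) r$stars, character(1)),
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_a"] <- paste0("mean_", cond_a)
  names(out)[names(out) == "sem_a"] <- paste0("sem_", cond_a)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", cond_b)
  names(out)[names(out) == "sem_b"] <- paste0("sem_", cond_b)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
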