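#' @title Accuracy metrics and cohort summaries
#'
#' @description Dice-coefficient evaluation of masks, pairwise comparison of
#' interaction levels across a cohort, the three-way category partition used
#' for timing analyses (axial-only / MPR drags / additional edits), and
#' mean / standard deviation / range summary tables.
#' @name evaluation
NULL

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to
#' agree perfectly (`1`), and an empty vs a nonempty mask scores `0`, so that
#' failed lesions evaluate without crashing.
#'
#' @param A,B Logical arrays on the same grid (any dimensionality).
#' @return Value in `[0, 1]`.
#' @export
dsc <- function(A, B) {
  stopifnot_same_grid(A, B)
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0L) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Count significantly improved / worsened / unchanged patients
#'
#' A patient improves from condition `a` to `b` when the Dice score rises by
#' at least `delta` (default 0.05), worsens when it falls by at least
#' `delta`, and is unchanged otherwise; the three counts partition the
#' cohort.
#'
#' @param results_a,results_b Data frames with columns `patient_id`, `dsc`.
#' @param delta Significance margin on the Dice scale.
#' @return Named integer vector `c(improved, worsened, unchanged)`.
#' @export
compare_levels <- function(results_a, results_b, delta = 0.05) {
  a <- results_a[order(results_a$patient_id), ]
  b <- results_b[order(results_b$patient_id), ]
  if (!identical(as.character(a$patient_id), as.character(b$patient_id)))
    stop("patient ids do not match between the two result sets", call. = FALSE)
  dd <- b$dsc - a$dsc
  c(improved = sum(dd >= delta), worsened = sum(dd <= -delta),
    unchanged = sum(dd > -delta & dd < delta))
}

#' Category thresholds for the interaction-requirement partition
#'
#' @param cat1_dsc Axial-only Dice above which a case needs only an axial
#'   long axis (default 0.883).
#' @param cat2_dsc MPR Dice at or above which a case is satisfied by MPR
#'   drags (default 0.796).
#' @param delta Significant-change margin (default 0.05).
#' @param subset_cat1,subset_cat2 Stricter subset thresholds kept as named
#'   constants (0.93, 0.85).
#' @return A `category_thresholds` list.
#' @export
category_thresholds <- function(cat1_dsc = 0.883, cat2_dsc = 0.796,
                                delta = 0.05, subset_cat1 = 0.93,
                                subset_cat2 = 0.85) {
  structure(list(cat1_dsc = cat1_dsc, cat2_dsc = cat2_dsc, delta = delta,
                 subset_cat1 = subset_cat1, subset_cat2 = subset_cat2),
            class = "category_thresholds")
}

#' Partition patients by the interaction they require
#'
#' Category 1: the axial-only Dice already exceeds `cat1_dsc`. Category 2:
#' otherwise, the MPR-drag Dice reaches `cat2_dsc`. Category 3: everything
#' else (additional edits required). Every patient lands in exactly one
#' category.
#'
#' @param axial_results,mpr_results Data frames with `patient_id`, `dsc`.
#' @param thresholds A [category_thresholds()].
#' @return Data frame with `patient_id`, `category` (integer 1-3).
#' @export
partition_categories <- function(axial_results, mpr_results,
                                 thresholds = category_thresholds()) {
  a <- axial_results[order(axial_results$patient_id), ]
  m <- mpr_results[order(mpr_results$patient_id), ]
  if (!identical(as.character(a$patient_id), as.character(m$patient_id)))
    stop("patient ids do not match between cohorts", call. = FALSE)
  cat <- ifelse(a$dsc > thresholds$cat1_dsc, 1L,
                ifelse(m$dsc >= thresholds$cat2_dsc, 2L, 3L))
  data.frame(patient_id = a$patient_id, category = cat)
}

#' Mean / standard deviation / range summary by group
#'
#' The summary layout used throughout the reports: per group, the mean,
#' sample (n-1) standard deviation and `[min, max]` range of the Dice
#' scores. Single-observation groups report `sd = 0` with `sd_defined =
#' FALSE`.
#'
#' @param results Data frame containing `dsc` and the grouping columns.
#' @param group_by Character vector of column names to group on.
#' @return Data frame with one row per group: grouping columns, `n`, `mean`,
#'   `sd`, `min`, `max`, `sd_defined`.
#' @export
summarize_results <- function(results, group_by = "level") {
  if (nrow(results) == 0L) stop("no results to summarize", call. = FALSE)
  key <- interaction(results[group_by], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- results[key == k, , drop = FALSE]
    v <- sub$dsc
    out <- sub[1, group_by, drop = FALSE]
    out$n <- length(v)
    out$mean <- mean(v)
    out$sd <- if (length(v) > 1L) stats::sd(v) else 0
    out$min <- min(v); out$max <- max(v)
    out$sd_defined <- length(v) > 1L
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
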