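# Normalized high-content and FACS autophagy-flux readouts and their group
# statistics: per-cell ratio metrics, normalization to an untreated reference
# within experiment/replicate strata, per-well aggregation, one-sample t
# against the reference value 1, Wilcoxon rank-sum comparisons with BH
# correction, Tukey box summaries, and tandem-reporter MFI fold changes.

#' Per-cell ratio metric
#'
#' Computes `numerator / denominator` per cell (e.g. marker-in-lysosome over
#' marker-total for flux, or surface over total intensity). Cells with a
#' missing or non-positive denominator are excluded; the exclusion count is
#' attached as attribute `"excluded"`.
#'
#' @param table a cell feature data.frame.
#' @param numerator_feature,denominator_feature column names.
#' @param name name of the new metric column.
#' @return The table, restricted to retained cells, with the metric column
#'   appended.
#' @export
ratio_metric <- function(table, numerator_feature, denominator_feature,
                         name = "metric") {
  for (f in c(numerator_feature, denominator_feature)) {
    if (!f %in% names(table)) stop("feature column absent: ", f)
  }
  num <- table[[numerator_feature]]
  den <- table[[denominator_feature]]
  drop <- is.na(den) | den <= 0 | is.na(num)
  out <- table[!drop, , drop = FALSE]
  out[[name]] <- num[!drop] / den[!drop]
  attr(out, "excluded") <- sum(drop)
  out
}

#' Normalize values to a reference group within strata
#'
#' Divides every value by the mean of the reference group's values within
#' the same stratum (experiment or biological replicate), so the reference
#' mean becomes exactly 1 in every stratum — the "normalized to the
#' untreated (UT) WT mean within the same experiment" convention.
#'
#' @param values numeric vector.
#' @param is_reference logical vector: which values belong to the reference
#'   group.
#' @param stratum vector of stratum labels (same length); a single stratum
#'   if omitted.
#' @return Numeric vector of normalized values.
#' @export
normalize_to_reference <- function(values, is_reference, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", length(values))
  stopifnot(length(is_reference) == length(values),
            length(stratum) == length(values))
  out <- numeric(length(values))
  for (s in unique(stratum)) {
    in_s <- stratum == s
    ref <- values[in_s & is_reference]
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0L) stop("no reference values in stratum '", s, "'")
    out[in_s] <- values[in_s] / mean(ref)
  }
  out
}

#' Per-well means of a metric
#'
#' @param table cell feature data.frame containing `well_id`.
#' @param metric metric column name.
#' @param keep grouping columns carried through (first value per well).
#' @return data.frame with one row per well: grouping columns, `mean_metric`,
#'   `n_cells`. Wells whose cells are all missing are dropped with a warning.
#' @export
well_aggregate <- function(table, metric = "metric",
                           keep = intersect(c("replicate", "condition",
                                              "genotype"), names(table))) {
  if (!"well_id" %in% names(table)) stop("well_id column absent")
  if (!metric %in% names(table)) stop("metric column absent: ", metric)
  ok <- !is.na(table[[metric]])
  dropped <- setdiff(unique(table$well_id), unique(table$well_id[ok]))
  if (length(dropped) > 0L) {
    warning("well(s) with no retained cells dropped: ",
            paste(dropped, collapse = ", "))
  }
  t2 <- table[ok, , drop = FALSE]
  wells <- unique(t2$well_id)
  rows <- lapply(wells, function(w) {
    sub <- t2[t2$well_id == w, , drop = FALSE]
    cbind(data.frame(well_id = w, stringsAsFactors = FALSE),
          sub[1L, keep, drop = FALSE],
          data.frame(mean_metric = mean(sub[[metric]]), n_cells = nrow(sub)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided one-sample t-test against a reference value
#'
#' Used for normalized readouts where the untreated reference equals 1 by
#' construction: tests whether a group of normalized values differs from
#' `mu`.
#'
#' @param values numeric vector, `n >= 2`.
#' @param mu reference value.
#' @return list `t`, `df`, `p_two_sided`, `mean`, `n`, `testable` (`FALSE`
#'   with `NA` statistics when the sd is 0).
#' @export
one_sample_test <- function(values, mu = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p_two_sided = NA_real_,
                mean = mean(values), n = n, testable = FALSE))
  }
  ht <- stats::t.test(values, mu = mu)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value, mean = mean(values), n = n,
       testable = TRUE)
}

# Two-sided Wilcoxon rank-sum p. Exact (no ties, combined n <= exact_max),
# else normal approximation with tie-corrected variance and continuity
# correction — stats::wilcox.test implements both branches.
ranksum_p <- function(x, y, exact_max = 25L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(W = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}

#' Wilcoxon rank-sum comparisons with BH correction
#'
#' Runs the two-sided Wilcoxon rank-sum test for each requested pair of
#' groups and corrects the family with Benjamini-Hochberg FDR. The exact
#' null distribution is used when there are no ties and the combined sample
#' size is at most `exact_max`; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @param comparisons list of 2-element character vectors, e.g.
#'   `list(c("KO", "WT"))`; default all pairwise.
#' @param exact_max combined-n switch between exact and approximate p.
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `W`, `p`, `q`
#'   (BH across the family), `exact`, `stars`.
#' @export
group_compare <- function(values, group, comparisons = NULL,
                          exact_max = 25L) {
  stopifnot(length(values) == length(group))
  groups <- unique(group)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups, 2L, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% groups)) {
      stop("unknown group in comparison: ",
           paste(setdiff(cmp, groups), collapse = ", "))
    }
    x <- values[group == cmp[1L]]
    y <- values[group == cmp[2L]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    r <- ranksum_p(x, y, exact_max)
    data.frame(group1 = cmp[1L], group2 = cmp[2L],
               n1 = length(x), n2 = length(y),
               W = r$W, p = r$p, exact = r$exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$q)
  out[, c("group1", "group2", "n1", "n2", "W", "p", "q", "exact", "stars")]
}

#' Significance stars
#'
#' Standard annotation: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `n.s.` otherwise.
#'
#' @param p numeric vector of p- (or q-) values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "n.s."),
      right = FALSE) |> as.character()
}

#' Tukey box-plot summary
#'
#' Median, quartiles (linear interpolation between order statistics),
#' whiskers at the most extreme data points within 1.5 x IQR of the box, and
#' the count of points beyond the whiskers.
#'
#' @param values numeric vector, `n >= 1`.
#' @return list `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outlier_count`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2L], q25 = q[1L], q75 = q[3L],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outlier_count = sum(values < lo_fence | values > hi_fence))
}

#' Tandem-reporter MFI fold changes
#'
#' Computes the per-sample reporter ratio (mCherry MFI over GFP MFI by
#' default; the ratio rises as the GFP moiety quenches in acidified
#' lysosomes) and normalizes it to the mean ratio of the untreated samples
#' of the same cell line, so each line's untreated mean fold change is
#' exactly 1.
#'
#' @param facs data.frame with `cell_line`, `condition`, `replicate`,
#'   `mfi_mcherry`, `mfi_gfp` (MFIs > 0).
#' @param untreated_label condition denoting the untreated reference.
#' @param ratio `"mcherry_over_gfp"` or `"gfp_over_mcherry"`.
#' @return The table with `ratio` and `fold_change` columns appended.
#' @export
mfi_fold_change <- function(facs, untreated_label = "UT",
                            ratio = c("mcherry_over_gfp",
                                      "gfp_over_mcherry")) {
  ratio <- match.arg(ratio)
  needed <- c("cell_line", "condition", "mfi_mcherry", "mfi_gfp")
  missing <- setdiff(needed, names(facs))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(facs$mfi_mcherry <= 0 | facs$mfi_gfp <= 0, na.rm = TRUE)) {
    stop("MFIs must be positive")
  }
  r <- if (ratio == "mcherry_over_gfp") {
    facs$mfi_mcherry / facs$mfi_gfp
  } else {
    facs$mfi_gfp / facs$mfi_mcherry
  }
  no_ut <- setdiff(unique(facs$cell_line),
                   unique(facs$cell_line[facs$condition == untreated_label]))
  if (length(no_ut) > 0L) {
    stop("no untreated ('", untreated_label, "') sample for cell line(s): ",
         paste(no_ut, collapse = ", "))
  }
  facs$ratio <- r
  facs$fold_change <- normalize_to_reference(
    r, facs$condition == untreated_label, stratum = facs$cell_line)
  facs
}

#' Log2 intensity pairs for per-cell scatter plots
#'
#' @param table cell feature data.frame.
#' @param feature_x,feature_y intensity columns (must be positive to be
#'   included; non-positive/missing cells are excluded and counted).
#' @param puncta_column optional puncta-count column carried through (bubble
#'   size).
#' @return data.frame `log2_x`, `log2_y` (+ puncta column when present),
#'   attribute `"excluded"` = number of excluded cells.
#' @export
log2_intensity_scatter <- function(table, feature_x, feature_y,
                                   puncta_column = "puncta_count") {
  for (f in c(feature_x, feature_y)) {
    if (!f %in% names(table)) stop("feature column absent: ", f)
  }
  x <- table[[feature_x]]
  y <- table[[feature_y]]
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  out <- data.frame(log2_x = log2(x[ok]), log2_y = log2(y[ok]))
  if (puncta_column %in% names(table)) {
    out[[puncta_column]] <- table[[puncta_column]][ok]
  }
  attr(out, "excluded") <- sum(!ok)
  out
}
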