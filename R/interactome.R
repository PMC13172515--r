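# Label-free interactome calling.
#
# Calling rule: a protein is an interactor when it passes a 5% FDR-corrected
# one-sided two-sample t-test (bait > control, Student pooled variance) with
# a minimal enrichment factor of two (linear scale, i.e. log2 difference
# >= 1). The two-sided p is computed alongside for volcano plots. FDR is
# Benjamini-Hochberg by default; a permutation-based alternative (group-label
# permutation null of the t statistic) is available.

#' Prepare an LFQ matrix for testing
#'
#' Zeros become missing, positive intensities are log2-transformed, and
#' proteins that do not reach `min_valid_per_group` observed values in any
#' tested group are dropped (the drop list is attached as an attribute).
#'
#' @param lfq an `lfq_matrix` (linear scale).
#' @param min_valid_per_group minimum observed values a protein needs in at
#'   least one of `groups` to be retained.
#' @param groups conditions considered for the valid-value filter; default
#'   all conditions in the sample sheet.
#' @return An `lfq_matrix` on the log2 scale, with attribute `"dropped"`
#'   (character vector of removed protein ids) and `"scale" = "log2"`.
#' @export
preprocess_lfq <- function(lfq, min_valid_per_group = 2L, groups = NULL) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  m <- lfq$intensities
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
  m[m == 0] <- NA_real_
  m <- log2(m)
  if (is.null(groups)) groups <- unique(lfq$samples$condition)
  valid <- sapply(groups, function(g) {
    cols <- lfq$samples$condition == g
    rowSums(!is.na(m[, cols, drop = FALSE]))
  })
  valid <- matrix(valid, nrow = nrow(m))
  keep <- apply(valid >= min_valid_per_group, 1L, any)
  out <- lfq
  out$intensities <- m[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[!keep]
  attr(out, "scale") <- "log2"
  out
}

#' Impute missing log2 intensities from a downshifted normal
#'
#' Perseus-convention imputation: per sample, missing values are drawn from
#' `Normal(mean - shift * sd, (width * sd)^2)` of that sample's observed
#' values — i.e. from the lower tail of the detected distribution, emulating
#' below-detection-limit missingness.
#'
#' @param lfq log2-scale `lfq_matrix` (from [preprocess_lfq()]).
#' @param shift downshift of the imputation mean, in sample standard
#'   deviations.
#' @param width imputation sd, as a fraction of the sample sd.
#' @param seed integer seed; imputation is reproducible.
#' @return The matrix with missing entries filled; attribute `"imputed"`
#'   holds the logical mask of imputed cells.
#' @export
impute_missing <- function(lfq, shift = 1.8, width = 0.3, seed) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  m <- lfq$intensities
  mask <- is.na(m)
  if (!any(mask)) {
    attr(lfq, "imputed") <- mask
    return(lfq)
  }
  n_obs <- colSums(!mask)
  if (any(n_obs < 2L)) {
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(m)[n_obs < 2L], collapse = ", "))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- mask[, j]
      if (!any(miss)) next
      obs <- m[!miss, j]
      mu <- mean(obs) - shift * stats::sd(obs)
      m[miss, j] <- stats::rnorm(sum(miss), mean = mu,
                                 sd = width * stats::sd(obs))
    }
  })
  lfq$intensities <- m
  attr(lfq, "imputed") <- mask
  lfq
}

# Vectorized Student (pooled-variance) two-sample t over matrix rows.
# Returns NA statistics for rows where either group has < 2 observed values.
pooled_t_rows <- function(xb, xc) {
  nb <- rowSums(!is.na(xb))
  nc <- rowSums(!is.na(xc))
  mb <- rowMeans(xb, na.rm = TRUE)
  mc <- rowMeans(xc, na.rm = TRUE)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1L, 1L)
  vc <- rowSums((xc - mc)^2, na.rm = TRUE) / pmax(nc - 1L, 1L)
  df <- nb + nc - 2L
  sp2 <- ((nb - 1L) * vb + (nc - 1L) * vc) / df
  se <- sqrt(sp2 * (1 / nb + 1 / nc))
  t <- (mb - mc) / se
  testable <- nb >= 2L & nc >= 2L
  t[!testable] <- NA_real_
  list(t = t, df = df, mean_bait = mb, mean_control = mc,
       difference = mb - mc, n_bait = nb, n_control = nc,
       testable = testable)
}

#' Per-protein two-sample enrichment test
#'
#' Student two-sample t-test with pooled variance per protein, comparing the
#' bait condition to the control condition on the log2 scale. The one-sided p
#' (bait > control) drives interactor calling; the two-sided p is reported
#' for volcano plots. Proteins with fewer than 2 observed values in either
#' group are flagged untestable (`NA` statistics) and are excluded from any
#' subsequent FDR denominator.
#'
#' @param lfq log2-scale `lfq_matrix`.
#' @param bait_condition,control_condition condition labels in the sample
#'   sheet.
#' @param welch use Welch (unequal-variance) t instead of pooled Student.
#' @return data.frame with per-protein columns `protein_id`,
#'   `mean_log2_bait`, `mean_log2_control`, `difference`, `t_statistic`,
#'   `df`, `p_one_sided`, `p_two_sided`, `enrichment_factor`, `testable`.
#' @export
test_enrichment <- function(lfq, bait_condition, control_condition,
                            welch = FALSE) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  cond <- lfq$samples$condition
  for (g in c(bait_condition, control_condition)) {
    if (!any(cond == g)) stop("condition not found in sample sheet: ", g)
  }
  xb <- lfq$intensities[, cond == bait_condition, drop = FALSE]
  xc <- lfq$intensities[, cond == control_condition, drop = FALSE]
  if (welch) {
    res <- welch_t_rows(xb, xc)
  } else {
    res <- pooled_t_rows(xb, xc)
  }
  p1 <- stats::pt(res$t, df = res$df, lower.tail = FALSE)
  p2 <- 2 * stats::pt(abs(res$t), df = res$df, lower.tail = FALSE)
  data.frame(
    protein_id = rownames(lfq$intensities),
    mean_log2_bait = res$mean_bait,
    mean_log2_control = res$mean_control,
    difference = res$difference,
    t_statistic = res$t,
    df = res$df,
    p_one_sided = p1,
    p_two_sided = p2,
    enrichment_factor = 2^res$difference,
    testable = res$testable,
    stringsAsFactors = FALSE
  )
}

welch_t_rows <- function(xb, xc) {
  nb <- rowSums(!is.na(xb)); nc <- rowSums(!is.na(xc))
  mb <- rowMeans(xb, na.rm = TRUE); mc <- rowMeans(xc, na.rm = TRUE)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1L, 1L)
  vc <- rowSums((xc - mc)^2, na.rm = TRUE) / pmax(nc - 1L, 1L)
  se2 <- vb / nb + vc / nc
  df <- se2^2 / ((vb / nb)^2 / (nb - 1L) + (vc / nc)^2 / (nc - 1L))
  t <- (mb - mc) / sqrt(se2)
  testable <- nb >= 2L & nc >= 2L
  t[!testable] <- NA_real_
  list(t = t, df = df, mean_bait = mb, mean_control = mc,
       difference = mb - mc, n_bait = nb, n_control = nc,
       testable = testable)
}

#' FDR adjustment
#'
#' `method = "bh"` is the Benjamini-Hochberg step-up with monotonicity
#' enforcement (via [stats::p.adjust()]). `method = "permutation"` estimates
#' q as the ratio of the expected number of null exceedances (t statistics
#' from group-label permutations at least as large as the observed one,
#' averaged over permutations) to the number of observed statistics at least
#' as large — the Perseus-style permutation FDR, monotonized.
#'
#' @param p p-values in `[0, 1]` (for `"bh"`); `NA`s allowed and returned
#'   `NA`.
#' @param method `"bh"` or `"permutation"`.
#' @param t_obs,t_null observed t statistics and a matrix of permuted-null t
#'   statistics (rows = proteins, columns = permutations); required for
#'   `"permutation"`.
#' @param seed unused for `"bh"`; kept for interface symmetry.
#' @return q-values aligned with the input.
#' @export
adjust_fdr <- function(p = NULL, method = c("bh", "permutation"),
                       t_obs = NULL, t_null = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "bh") {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    # untestable (NA) entries stay NA and do not enter the family size
    ok <- !is.na(p)
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    return(q)
  }
  if (is.null(t_obs) || is.null(t_null)) {
    stop("permutation FDR needs t_obs and t_null")
  }
  ok <- !is.na(t_obs)
  q <- rep(NA_real_, length(t_obs))
  to <- t_obs[ok]
  tn <- t_null[ok, , drop = FALSE]
  ord <- order(to, decreasing = TRUE)
  n_perm <- ncol(tn)
  null_sorted <- sort(as.numeric(tn), decreasing = TRUE)
  fdr <- vapply(seq_along(ord), function(k) {
    thr <- to[ord[k]]
    n_null <- sum(null_sorted >= thr) / n_perm
    min(1, n_null / k)
  }, numeric(1))
  # enforce monotone non-increasing FDR with decreasing threshold
  fdr <- rev(cummin(rev(fdr)))
  q[ok][ord] <- fdr
  q
}

#' Call interactors
#'
#' A protein is an interactor when `q_fdr <= q_threshold` and its linear
#' enrichment factor is at least `min_enrichment_factor` ("passed a 5%
#' FDR-corrected one-sided two-sample t-test with a minimal enrichment
#' factor of two"). Volcano coordinates (`difference`, `neg_log10_p`) are
#' emitted for every protein; the volcano p is two-sided by default.
#'
#' @param stats_df output of [test_enrichment()].
#' @param q_threshold FDR level.
#' @param min_enrichment_factor minimum linear bait/control factor.
#' @param fdr_method `"bh"` or `"permutation"` (see [adjust_fdr()]).
#' @param volcano_p which p-value feeds the volcano y axis.
#' @param t_null permuted-null t matrix when `fdr_method = "permutation"`.
#' @return `stats_df` with columns `q_fdr`, `interactor`, `neg_log10_p`
#'   appended; attribute `"metadata"` records thresholds and methods used.
#' @export
call_interactors <- function(stats_df, q_threshold = 0.05,
                             min_enrichment_factor = 2,
                             fdr_method = c("bh", "permutation"),
                             volcano_p = c("two_sided", "one_sided"),
                             t_null = NULL) {
  fdr_method <- match.arg(fdr_method)
  volcano_p <- match.arg(volcano_p)
  q <- if (fdr_method == "bh") {
    adjust_fdr(stats_df$p_one_sided, "bh")
  } else {
    adjust_fdr(method = "permutation", t_obs = stats_df$t_statistic,
               t_null = t_null)
  }
  stats_df$q_fdr <- q
  stats_df$interactor <- !is.na(q) & q <= q_threshold &
    stats_df$enrichment_factor >= min_enrichment_factor
  pv <- if (volcano_p == "two_sided") stats_df$p_two_sided else stats_df$p_one_sided
  stats_df$neg_log10_p <- -log10(pv)
  attr(stats_df, "metadata") <- list(
    q_threshold = q_threshold,
    min_enrichment_factor = min_enrichment_factor,
    fdr_method = fdr_method, volcano_p = volcano_p,
    test = "two-sample Student t, pooled variance",
    call_sided = "one_sided_greater"
  )
  stats_df
}

#' Pairwise fold-change gate between two conditions
#'
#' Flags proteins whose ratio of linear-scale condition means (x over y)
#' reaches `threshold` (boundary inclusive). Proteins whose denominator mean
#' is zero or missing are excluded and reported as incomputable.
#'
#' @param lfq linear-scale `lfq_matrix`.
#' @param condition_x,condition_y condition labels (numerator, denominator).
#' @param threshold minimum ratio.
#' @return data.frame `protein_id`, `mean_x`, `mean_y`, `ratio`, `flagged`,
#'   `incomputable`.
#' @export
pairwise_fc_gate <- function(lfq, condition_x, condition_y, threshold = 2) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  cond <- lfq$samples$condition
  for (g in c(condition_x, condition_y)) {
    if (!any(cond == g)) stop("condition not found: ", g)
  }
  mx <- rowMeans(lfq$intensities[, cond == condition_x, drop = FALSE],
                 na.rm = TRUE)
  my <- rowMeans(lfq$intensities[, cond == condition_y, drop = FALSE],
                 na.rm = TRUE)
  incomputable <- !is.finite(my) | my == 0 | !is.finite(mx)
  ratio <- ifelse(incomputable, NA_real_, mx / my)
  data.frame(protein_id = rownames(lfq$intensities),
             mean_x = mx, mean_y = my, ratio = ratio,
             flagged = !incomputable & ratio >= threshold,
             incomputable = incomputable,
             stringsAsFactors = FALSE)
}

#' Per-condition z-scores of average intensity
#'
#' For each protein, averages the (log-scale) intensity per condition, then
#' z-scores those averages across conditions using the sample standard
#' deviation — the quantity shown by condition-profile heatmaps. Proteins
#' with zero across-condition sd get z = 0 and are flagged.
#'
#' @param lfq `lfq_matrix`, conventionally log2 scale.
#' @return list with `z` (proteins x conditions matrix), `means` (condition
#'   averages) and `flat` (logical: sd was 0).
#' @export
condition_zscore <- function(lfq) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  conds <- unique(lfq$samples$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  means <- sapply(conds, function(g) {
    rowMeans(lfq$intensities[, lfq$samples$condition == g, drop = FALSE],
             na.rm = TRUE)
  })
  means <- matrix(means, nrow = nrow(lfq$intensities),
                  dimnames = list(rownames(lfq$intensities), conds))
  mu <- rowMeans(means)
  sd_ <- apply(means, 1L, stats::sd)
  flat <- !is.na(sd_) & sd_ == 0
  z <- (means - mu) / ifelse(sd_ == 0, Inf, sd_)
  z[flat, ] <- 0
  list(z = z, means = means, flat = flat)
}
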