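make_lfq <- function(m, conditions) {
  samples <- data.frame(sample_id = colnames(m), condition = conditions,
                        replicate = as.integer(stats::ave(
                          seq_along(conditions), conditions,
                          FUN = seq_along)),
                        stringsAsFactors = FALSE)
  lfq_matrix(m, samples)
}

test_that("preprocessing log-transforms, treats zero as missing and filters", {
  m <- rbind(P1 = c(1024, 2048, 4096, 2, 4, 8),
             P2 = c(0, 0, 0, 0, 0, 0),
             P3 = c(8, 0, 0, 0, 0, 16))
  colnames(m) <- paste0("s", 1:6)
  lfq <- make_lfq(m, rep(c("bait", "ctrl"), each = 3))
  pp <- preprocess_lfq(lfq, min_valid_per_group = 2)
  expect_equal(unname(pp$intensities["P1", 1]), 10)   # log2(1024)
  expect_equal(rownames(pp$intensities), "P1")
  expect_setequal(attr(pp, "dropped"), c("P2", "P3"))

  # all-valid matrix -> no drops
  ok <- preprocess_lfq(make_lfq(m[1, , drop = FALSE],
                                rep(c("bait", "ctrl"), each = 3)))
  expect_length(attr(ok, "dropped"), 0L)

  m_neg <- m; m_neg[1, 1] <- -1
  expect_error(
    preprocess_lfq(suppressWarnings(
      make_lfq(abs(m_neg), rep(c("bait", "ctrl"), each = 3))) |>
        (\(x) { x$intensities[1, 1] <- -1; x })()),
    "negative")
})

test_that("downshifted-normal imputation has the stated distribution", {
  # one sample with observed mean 20, sd 1 and 10,000 missing entries:
  # imputed mean must sit at 20 - 1.8 = 18.2 within +/- 0.02
  set.seed(2)
  obs <- rnorm(5000, 20, 1)
  obs <- (obs - mean(obs)) / sd(obs) + 20  # exact mean 20, sd 1
  m <- matrix(c(obs, rep(NA_real_, 10000)), ncol = 1)
  rownames(m) <- paste0("P", seq_len(nrow(m)))
  colnames(m) <- "s1"
  lfq <- make_lfq(m, "bait")
  attr(lfq, "scale") <- "log2"
  imp <- impute_missing(lfq, seed = 99)
  filled <- imp$intensities[attr(imp, "imputed")]
  expect_length(filled, 10000L)
  expect_lt(abs(mean(filled) - 18.2), 0.02)
  expect_lt(abs(sd(filled) - 0.3), 0.02)

  # determinism and no-op on complete matrices
  imp2 <- impute_missing(lfq, seed = 99)
  expect_identical(imp$intensities, imp2$intensities)
  full <- make_lfq(matrix(rnorm(12, 20), 2, 6,
                          dimnames = list(c("P1", "P2"), paste0("s", 1:6))),
                   rep(c("bait", "ctrl"), each = 3))
  expect_equal(impute_missing(full, seed = 1)$intensities, full$intensities)

  sparse <- make_lfq(matrix(c(1, NA, NA, NA), 2, 2,
                            dimnames = list(c("P1", "P2"), c("s1", "s2"))),
                     c("bait", "ctrl"))
  expect_error(impute_missing(sparse, seed = 1), "s1")
})

test_that("pooled two-sample t matches the closed form and stats::t.test", {
  m <- rbind(P1 = c(10, 11, 12, 8, 8, 9))
  colnames(m) <- paste0("s", 1:6)
  lfq <- make_lfq(m, rep(c("bait", "ctrl"), each = 3))
  st <- test_enrichment(lfq, "bait", "ctrl")
  ref <- t.test(c(10, 11, 12), c(8, 8, 9), var.equal = TRUE)
  expect_equal(st$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(st$t_statistic, 4.0, tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$difference, 8 / 3, tolerance = 1e-12)
  expect_equal(st$p_two_sided, ref$p.value, tolerance = 1e-12)
  expect_equal(st$p_one_sided, ref$p.value / 2, tolerance = 1e-12)

  # identical groups with nonzero variance -> t = 0, one-sided p = 0.5
  m0 <- rbind(P1 = c(1, 2, 3, 1, 2, 3))
  colnames(m0) <- paste0("s", 1:6)
  st0 <- test_enrichment(make_lfq(m0, rep(c("bait", "ctrl"), each = 3)),
                         "bait", "ctrl")
  expect_equal(st0$t_statistic, 0)
  expect_equal(st0$p_one_sided, 0.5)

  # swapping groups negates t and difference
  sw <- test_enrichment(lfq, "ctrl", "bait")
  expect_equal(sw$t_statistic, -st$t_statistic)
  expect_equal(sw$difference, -st$difference)
})

test_that("vectorized t agrees with per-row stats::t.test on random data", {
  set.seed(8)
  m <- matrix(rnorm(50 * 8, 20, 2), 50, 8,
              dimnames = list(paste0("P", 1:50), paste0("s", 1:8)))
  cond <- rep(c("bait", "ctrl"), each = 4)
  st <- test_enrichment(make_lfq(m, cond), "bait", "ctrl")
  stw <- test_enrichment(make_lfq(m, cond), "bait", "ctrl", welch = TRUE)
  for (i in c(1, 17, 50)) {
    ref <- t.test(m[i, 1:4], m[i, 5:8], var.equal = TRUE)
    expect_equal(st$t_statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st$p_two_sided[i], ref$p.value, tolerance = 1e-10)
    refw <- t.test(m[i, 1:4], m[i, 5:8])
    expect_equal(stw$t_statistic[i], unname(refw$statistic),
                 tolerance = 1e-10)
    expect_equal(stw$df[i], unname(refw$parameter), tolerance = 1e-10)
  }
})

test_that("proteins with fewer than two values per group are untestable", {
  m <- rbind(P1 = c(10, NA, NA, 8, 8, 9), P2 = c(10, 11, 12, 8, 8, 9))
  colnames(m) <- paste0("s", 1:6)
  st <- test_enrichment(make_lfq(m, rep(c("bait", "ctrl"), each = 3)),
                        "bait", "ctrl")
  expect_false(st$testable[1]); expect_true(st$testable[2])
  expect_true(is.na(st$t_statistic[1]))
  called <- call_interactors(st)
  # untestable protein contributes nothing to the FDR family
  expect_true(is.na(called$q_fdr[1]))
  expect_equal(called$q_fdr[2], st$p_one_sided[2])  # single-member family
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(123)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    q <- adjust_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(order(q[order(p)]), seq_along(p))  # order-preserving
  }
})

test_that("permutation FDR is calibrated on an obvious spike", {
  set.seed(5)
  g <- gen_lfq(300, 5, log2_effect = 4, within_sd = 0.3, seed = 55)
  pp <- preprocess_lfq(g$lfq)
  st <- test_enrichment(pp, "bait", "control")
  # null t matrices from the generator's own null (no spikes)
  t_null <- sapply(1:20, function(k) {
    gn <- gen_lfq(300, 0, within_sd = 0.3, seed = 1000 + k)
    test_enrichment(preprocess_lfq(gn$lfq), "bait", "control")$t_statistic
  })
  q <- adjust_fdr(method = "permutation", t_obs = st$t_statistic,
                  t_null = t_null)
  expect_true(all(q[st$protein_id %in% g$truth$labels] < 0.05))
  expect_lt(mean(q[!st$protein_id %in% g$truth$labels] <= 0.05), 0.02)
})

test_that("interactor calling is the FDR x enrichment-factor conjunction", {
  st <- data.frame(
    protein_id = c("A", "B", "C"),
    difference = c(2, 0.9, 3),
    t_statistic = c(8, 8, 2),
    df = 4,
    p_one_sided = c(0.001, 0.001, 0.06),
    p_two_sided = c(0.002, 0.002, 0.12),
    enrichment_factor = c(4, 1.9, 8),
    testable = TRUE
  )
  called <- call_interactors(st)
  # q = BH over the three one-sided p-values
  expect_equal(called$q_fdr, oracle_bh(st$p_one_sided))
  expect_equal(called$interactor, c(TRUE, FALSE, FALSE))
  expect_equal(called$neg_log10_p, -log10(st$p_two_sided))
  md <- attr(called, "metadata")
  expect_equal(md$q_threshold, 0.05)
  expect_equal(md$min_enrichment_factor, 2)
})

test_that("spiked proteins are recovered and volcano axes behave", {
  g <- gen_lfq(500, 20, log2_effect = 3, within_sd = 0.3, seed = 77)
  pp <- preprocess_lfq(g$lfq)
  called <- call_interactors(test_enrichment(pp, "bait", "control"))
  hits <- called$protein_id[called$interactor]
  expect_true(all(g$truth$labels %in% hits))
  expect_lt(length(setdiff(hits, g$truth$labels)), 5)
  # -log10 p monotone decreasing in p
  ord <- order(called$p_two_sided)
  expect_true(all(diff(called$neg_log10_p[ord]) <= 0))
})

test_that("the pairwise fold-change gate is boundary-inclusive", {
  m <- rbind(P1 = c(8, 8, 4, 4), P2 = c(7.9, 7.9, 4, 4),
             P3 = c(5, 5, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  lfq <- make_lfq(m, rep(c("S10A", "S10D"), each = 2))
  gate <- pairwise_fc_gate(lfq, "S10A", "S10D", threshold = 2)
  expect_equal(gate$flagged, c(TRUE, FALSE, FALSE))
  expect_true(gate$incomputable[3])
  expect_equal(gate$ratio[1], 2)
})

test_that("condition z-scores standardize each protein across conditions", {
  m <- rbind(P1 = c(8, 8, 12, 12), P2 = c(3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  lfq <- make_lfq(m, rep(c("c1", "c2"), each = 2))
  z <- condition_zscore(lfq)
  expect_equal(unname(z$z["P1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z$z["P2", ]), c(0, 0))  # flat row flagged, set to 0
  expect_true(z$flat["P2"])
  expect_lt(max(abs(rowMeans(z$z))), 1e-12)
})
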