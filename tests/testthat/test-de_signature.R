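test_that("log2CPM follows the closed form and is scale invariant", {
  counts <- matrix(c(1000, 999000), ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  lc <- log2cpm_matrix(counts, pseudocount = 0)
  expect_equal(lc["g1", 1], log2(1000), tolerance = 1e-12)
  set.seed(30)
  m <- matrix(rpois(300, 50), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  expect_equal(log2cpm_matrix(2 * m, 0), log2cpm_matrix(m, 0),
               tolerance = 1e-12)
  # per-cell formula oracle
  pc <- 0.5
  lib <- colSums(m)
  expected <- m
  for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
    expected[i, j] <- log2((m[i, j] + pc) / (lib[j] + 2 * pc) * 1e6)
  }
  expect_equal(log2cpm_matrix(m, pc), expected, tolerance = 1e-12)
  expect_error(log2cpm_matrix(m, -1), "pseudocount")
})

test_that("low-expression filter eliminates strictly below threshold", {
  lc <- rbind(at = rep(-3, 4), below = rep(-3.5, 4), above = rep(0, 4))
  expect_setequal(filter_low_expression(lc, -3), c("at", "above"))
  set.seed(31)
  lc2 <- matrix(rnorm(600, -3, 2), nrow = 100,
                dimnames = list(paste0("g", 1:100), NULL))
  expect_setequal(filter_low_expression(lc2, -3),
                  rownames(lc2)[rowMeans(lc2) >= -3])
  expect_setequal(filter_low_expression(lc2, -Inf), rownames(lc2))
  expect_length(filter_low_expression(lc2, Inf), 0)
})

test_that("BH adjustment matches the hand step-up on worked and random cases", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(32)
  for (rep in 1:100) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature concordance reproduces the hand-filtered example", {
  disease <- data.frame(gene_id = c("g1", "g2", "g3"),
                        log2fc = c(2, 1.2, -1.5), fdr = c(0.01, 0.2, 0.01))
  treatment <- data.frame(gene_id = c("g1", "g3"),
                          log2fc = c(-1, 0.5), fdr = c(0.01, 0.5))
  cc <- signature_concordance(disease, treatment, c("g1", "g2", "g3"))
  up <- cc[cc$direction == "up", ]
  down <- cc[cc$direction == "down", ]
  expect_equal(unlist(up[, -1], use.names = FALSE), c(1, 1, 1))
  expect_equal(unlist(down[, -1], use.names = FALSE), c(1, 1, 0))
})

test_that("concordance counts are monotone in the FDR threshold and vanish at (Inf, 0)", {
  set.seed(33)
  n <- 300
  disease <- data.frame(gene_id = paste0("g", 1:n), log2fc = rnorm(n, 0, 2),
                        fdr = runif(n))
  treatment <- data.frame(gene_id = paste0("g", 1:n), log2fc = rnorm(n, 0, 2),
                          fdr = runif(n))
  prev <- NULL
  for (thr in c(0.01, 0.05, 0.2, 1)) {
    cc <- signature_concordance(disease, treatment, fdr_threshold = thr)
    counts <- unlist(cc[, -1])
    if (!is.null(prev)) expect_true(all(counts >= prev))
    prev <- counts
  }
  cc0 <- signature_concordance(disease, treatment,
                               lfc_threshold = Inf, fdr_threshold = 0)
  expect_true(all(unlist(cc0[, -1]) == 0))
  expect_error(signature_concordance(disease[, 1:2], treatment), "missing")
})

test_that("panel selection applies all three strict filters", {
  tpm <- c(a = 40, b = 35, c = 100, d = 10)
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.6, 3, 1.5, 4))
  expect_equal(select_dux4_panel(tpm, de), "a")
  set.seed(34)
  tpm2 <- stats::setNames(runif(200, 0, 100), paste0("g", 1:200))
  de2 <- data.frame(gene_id = names(tpm2), log2fc = rnorm(200, 1, 1))
  expect_setequal(select_dux4_panel(tpm2, de2),
                  names(tpm2)[tpm2 > 35 & de2$log2fc > 1.5])
})

test_that("planted signature genes are recovered end-to-end with the Welch plumbing", {
  # at n = 10 vs 10 the unmoderated Welch test has genome-wide power: >= 90%
  # of planted genes land in the fully significant concordance category
  disease <- sim_expression_experiment(n_genes = 2000, n_per_group = 10,
                                       planted = 50, lfc = 2, seed = 100)
  treatment <- sim_expression_experiment(n_genes = 2000, n_per_group = 10,
                                         planted = disease$planted, lfc = -2,
                                         seed = 101)
  de_dis <- welch_de(disease$counts, disease$group, treated = "treated")
  de_trt <- welch_de(treatment$counts, treatment$group, treated = "treated")
  cc <- signature_concordance(de_dis, de_trt, disease$planted,
                              lfc_threshold = 1, fdr_threshold = 0.05)
  up <- cc[cc$direction == "up", ]
  expect_gte(up$n_responding_significant, 0.9 * length(disease$planted))
})

test_that("at small group sizes the planted direction is still fully recovered", {
  # n = 4 vs 4: BH significance is power-limited for an unmoderated test, but
  # the sign of the treatment response (category b) is recovered throughout
  disease <- sim_expression_experiment(n_genes = 2000, n_per_group = 4,
                                       planted = 50, lfc = 2, seed = 100)
  treatment <- sim_expression_experiment(n_genes = 2000, n_per_group = 4,
                                         planted = disease$planted, lfc = -2,
                                         seed = 101)
  de_dis <- welch_de(disease$counts, disease$group, treated = "treated")
  de_trt <- welch_de(treatment$counts, treatment$group, treated = "treated")
  cc <- signature_concordance(de_dis, de_trt, disease$planted,
                              lfc_threshold = 1, fdr_threshold = 1)
  up <- cc[cc$direction == "up", ]
  expect_gte(up$n_responding, 0.9 * length(disease$planted))
})

test_that("welch_de is calibrated under the null and keeps fdr >= p", {
  null <- sim_expression_experiment(n_genes = 2000, n_per_group = 5,
                                    planted = 0, seed = 102)
  de <- welch_de(null$counts, null$group)
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
  expect_true(all(de$fdr >= de$p_value - 1e-12))
})
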