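targets <- c("MBD3L2", "ZSCAN4", "LEUTX", "KHDC1L")
hks <- c("AHSA1", "RPL27")

make_ct <- function(target_mock, target_treated, hk_mock = c(20, 21),
                    hk_treated = hk_mock) {
  ct <- data.frame(condition = c("mock", "treated"))
  for (i in seq_along(targets)) {
    ct[[targets[i]]] <- c(target_mock[i], target_treated[i])
  }
  for (i in seq_along(hks)) {
    ct[[hks[i]]] <- c(hk_mock[i], hk_treated[i])
  }
  ct
}

test_that("composite is 100% when treated wells coincide with mock wells", {
  ct <- make_ct(c(28, 29, 30, 31), c(28, 29, 30, 31))
  res <- fshd_composite(ct, targets, hks)
  expect_equal(res$per_well$composite_percent,
               c(100, 100))
})

test_that("two extra target cycles give a 25% composite", {
  ct <- make_ct(c(28, 29, 30, 31), c(30, 31, 32, 33))
  res <- fshd_composite(ct, targets, hks)
  treated <- res$per_well[res$per_well$condition == "treated", ]
  expect_equal(treated$delta_ct, 11)
  expect_equal(treated$delta_delta_ct, 2)
  expect_equal(treated$composite_percent, 25)
})

test_that("composite is multiplicative in treated-target cycle shifts", {
  set.seed(20)
  ct <- sim_ct_table(n_mock = 6, n_treated = 6, seed = 3)
  base <- fshd_composite(ct, targets, hks)
  for (c_shift in c(0.5, 1, 3)) {
    ct2 <- ct
    treated <- ct2$condition == "treated"
    for (g in targets) ct2[[g]][treated] <- ct2[[g]][treated] + c_shift
    shifted <- fshd_composite(ct2, targets, hks)
    expect_equal(
      shifted$per_well$composite_percent[treated],
      base$per_well$composite_percent[treated] * 2^(-c_shift),
      tolerance = 1e-12)
  }
})

test_that("composite is invariant to adding a constant to every Ct", {
  ct <- sim_ct_table(n_mock = 5, n_treated = 5, seed = 4)
  base <- fshd_composite(ct, targets, hks)
  ct2 <- ct
  for (g in c(targets, hks)) ct2[[g]] <- ct2[[g]] + 2.7
  expect_equal(fshd_composite(ct2, targets, hks)$per_well$composite_percent,
               base$per_well$composite_percent, tolerance = 1e-12)
})

test_that("undetermined Cts are excluded with a warning, or error in strict mode", {
  ct <- make_ct(c(28, 29, 30, 31), c(30, 31, 32, 33))
  ct <- rbind(ct, ct[1, ])
  ct$MBD3L2[3] <- NA
  expect_warning(res <- fshd_composite(ct, targets, hks), "excluding 1")
  expect_equal(nrow(res$per_well), 2L)
  expect_error(fshd_composite(ct, targets, hks, strict = TRUE), "undetermined")
})

test_that("missing gene columns raise a schema error", {
  ct <- make_ct(c(28, 29, 30, 31), c(30, 31, 32, 33))
  expect_error(fshd_composite(ct, c(targets, "NOPE"), hks), "NOPE")
  expect_error(fshd_composite(ct[ct$condition == "treated", ], targets, hks),
               "mock")
})

test_that("single-gene ddCt relative expression follows the Livak formula", {
  ct <- data.frame(group = c("ctrl", "ctrl", "trt", "trt"),
                   ACTA1 = c(24, 24, 23, 25),
                   AHSA1 = c(20, 20, 20, 20))
  rel <- relative_expression_ddct(ct, "ACTA1", "AHSA1", "ctrl")
  expect_equal(rel$relative_expression, c(1, 1, 2, 0.5))
  # spreadsheet-style recomputation on a mixed table
  set.seed(21)
  ct2 <- data.frame(group = rep(c("ctrl", "trt"), each = 5),
                    G = rnorm(10, 25), R = rnorm(10, 20))
  rel2 <- relative_expression_ddct(ct2, "G", "R", "ctrl")
  dct <- ct2$G - ct2$R
  expected <- 2^(-(dct - mean(dct[ct2$group == "ctrl"])))
  expect_equal(rel2$relative_expression, expected, tolerance = 1e-9)
})

test_that("geometric-mean composite scales the reference group to 100%", {
  panel <- data.frame(group = c("veh", "veh", "dose"),
                      A = c(1, 1, 1), B = c(4, 4, 4))
  res <- geometric_mean_composite(panel, c("A", "B"), "veh")
  expect_equal(res$geomean, c(2, 2, 2))
  expect_equal(res$composite_percent, c(100, 100, 100))
  set.seed(22)
  panel2 <- data.frame(group = rep(c("veh", "d1", "d2"), each = 4),
                       A = runif(12, 1, 50), B = runif(12, 1, 50),
                       C = runif(12, 1, 50))
  res2 <- geometric_mean_composite(panel2, c("A", "B", "C"), "veh")
  gm <- exp(rowMeans(log(as.matrix(panel2[, c("A", "B", "C")]))))
  expect_equal(res2$geomean, gm, tolerance = 1e-9)
  expect_equal(mean(res2$composite_percent[panel2$group == "veh"]), 100,
               tolerance = 1e-9)
  expect_error(
    geometric_mean_composite(
      data.frame(group = "veh", A = 0), "A", "veh"), "floor")
})

test_that("NanoString positive-control factors match the stated construction", {
  counts <- rbind(P1 = c(100, 200), P2 = c(100, 200),
                  HK = c(50, 50), G1 = c(10, 10))
  colnames(counts) <- c("A", "B")
  run <- nanostring_run(counts, c("positive", "positive", "housekeeping",
                                  "endogenous"))
  res <- nanostring_normalize(run)
  expect_equal(unname(res$positive_factor),
               c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-9)
})

test_that("NanoString normalization is the identity on uniform runs and idempotent", {
  counts <- matrix(rep(c(100, 20, 7, 3, 4, 5), 3), ncol = 3,
                   dimnames = list(c("P1", "P2", "HK", "D1", "D2", "D3"),
                                   c("A", "B", "C")))
  run <- nanostring_run(counts, c("positive", "positive", "housekeeping",
                                  "dux4", "dux4", "dux4"))
  res <- nanostring_normalize(run)
  expect_equal(res$normalized, counts)
  expect_equal(unname(res$dux4), c(4, 4, 4))
  # idempotence: renormalizing an already-normalized run changes nothing
  run2 <- nanostring_run(res$normalized, run$probe_class)
  expect_equal(nanostring_normalize(run2)$normalized, res$normalized,
               tolerance = 1e-12)
})

test_that("NanoString normalization rejects zero positive controls", {
  counts <- rbind(P1 = c(0, 10), P2 = c(5, 10), HK = c(5, 5))
  run <- nanostring_run(counts, c("positive", "positive", "housekeeping"))
  expect_error(nanostring_normalize(run), "zero")
})

test_that("calibrator scaling sets calibrator-sample means to 1 per probe", {
  set.seed(23)
  counts <- matrix(runif(24, 10, 100), nrow = 4,
                   dimnames = list(c("P1", "P2", "HK", "G1"), paste0("s", 1:6)))
  run <- nanostring_run(counts,
                        c("positive", "positive", "housekeeping", "endogenous"),
                        calibrator = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  res <- nanostring_normalize(run)
  expect_equal(unname(rowMeans(res$normalized[, 1:2])), rep(1, 4),
               tolerance = 1e-12)
})
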