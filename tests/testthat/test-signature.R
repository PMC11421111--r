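test_that("binScore reproduces the printed bin assignments", {
  expect_equal(binScore(0.95), 10L)   # top bin, open above
  expect_equal(binScore(1.77), 10L)   # observed catalog maximum, not a cap
  expect_equal(binScore(0.55), 6L)
  expect_equal(binScore(0.005), 0L)
  expect_equal(binScore(0.20), 3L)    # "at least 20% present (score: '3')"
  expect_equal(binScore(0.10), 2L)
  expect_equal(binScore(0.01), 1L)
  expect_equal(binScore(0), 0L)
  expect_error(binScore(-0.1), "non-negative")
})

test_that("binScore is monotone and tiles [0, Inf) without gaps", {
  grid <- seq(0, 2, by = 0.001)
  s <- binScore(grid)
  expect_true(all(diff(s) >= 0))          # monotone non-decreasing
  expect_true(all(s %in% 0:10))           # every value scored
  expect_equal(sort(unique(s)), 0:10)     # every score reachable
  # inclusive lower edges
  expect_equal(binScore(defaultBinEdges()), 1:10)
})

test_that("threshold and gap-fill follow the 20% rule with III/IV exceptions", {
  # f1 = 0.15 (raw score 2), s3 = 4 -> the gap is filled back to 2
  out <- thresholdAndFill(s1_raw = 2L, s2_raw = 0L, s3 = 4L, s4 = 0L,
                          f1 = 0.15, f2 = 0)
  expect_equal(out$s1, 2L)
  # f1 = 0.15, s3 = 2 (and s4 = 1) -> no fill, zeroed
  out <- thresholdAndFill(2L, 0L, s3 = 2L, s4 = 1L, f1 = 0.15, f2 = 0)
  expect_equal(out$s1, 0L)
  # at or above 20% the raw score stands regardless of s3/s4
  out <- thresholdAndFill(3L, 0L, s3 = 0L, s4 = 0L, f1 = 0.25, f2 = 0)
  expect_equal(out$s1, 3L)
  # symmetric rule for s2 with s4
  out <- thresholdAndFill(0L, 1L, s3 = 0L, s4 = 5L, f1 = 0, f2 = 0.05)
  expect_equal(out$s2, 1L)
})

test_that("gap-filling only ever restores small raw scores when s3/s4 >= 3", {
  # exhaustive scan over a value grid: the rule never fires without the
  # quotient trigger, never lowers a score, and only restores 1 or 2
  f1grid <- seq(0, 1, by = 0.01)
  flexgrid <- seq(0.1, 2.0, by = 0.1)
  for (flex in flexgrid) {
    q3 <- f1grid / flex
    s1raw <- binScore(f1grid)
    s3 <- binScore(q3)
    out <- thresholdAndFill(s1raw, 0L, s3, 0L, f1grid, 0)
    thresholded <- ifelse(f1grid >= 0.20, s1raw, 0L)
    filled <- out$s1 != thresholded
    # fills happen only below the presence threshold ...
    expect_true(all(f1grid[filled] < 0.20))
    # ... only when the quotient fingerprint scored above 2 ...
    expect_true(all(s3[filled] >= 3L))
    # ... and only restore the raw score 1 or 2
    expect_true(all(out$s1[filled] %in% 1:2))
    expect_true(all(out$s1 >= thresholded))
  }
})

test_that("tier classification implements both primary criteria", {
  # criterion (i): fraction occurrence at or above 20%
  expect_equal(classifyTier(f1 = 0.25, f2 = 0, q3 = 0, q4 = 0), "primary")
  expect_equal(classifyTier(f1 = 0.20, f2 = 0, q3 = 0, q4 = 0), "primary")
  # criterion (ii): quotient >= 0.2 plus occurrence >= 10%
  expect_equal(classifyTier(f1 = 0.12, f2 = 0, q3 = 0.30, q4 = 0), "primary")
  # neither criterion
  expect_equal(classifyTier(f1 = 0.12, f2 = 0.05, q3 = 0.15, q4 = 0.1),
               "secondary")
  # quotient alone is not enough below 10% occurrence
  expect_equal(classifyTier(f1 = 0.05, f2 = 0.05, q3 = 0.9, q4 = 0.9),
               "secondary")
  # undefined quotients fail criterion (ii)
  expect_equal(classifyTier(f1 = 0.12, f2 = 0, q3 = NA, q4 = NA),
               "secondary")
})

test_that("buildSignature scores, totals, tiers and orders deterministically", {
  # maximal case: present in every compound and class, flexibility 1.0
  fp <- data.frame(substructure_id = "S1", name = "max", smiles = "c1ccccc1",
                   n_hits = 10L, f1 = 1, n_class_hits = 3L, f2 = 1,
                   n_H_total = 6L, n_H_defined = 0L, n_H_variable = 6L,
                   n_heavy = 6L, flexibility = 1, q3 = 1, q4 = 1)
  sig <- buildSignature(fp)
  expect_equal(sig$s1, 10L)
  expect_equal(sig$s2, 10L)
  expect_equal(sig$s3, 10L)
  expect_equal(sig$s4, 10L)
  expect_equal(sig$total, 40L)
  expect_equal(sig$tier, "primary")

  # absent everywhere: total 0, secondary
  fp0 <- fp
  fp0[, c("f1", "f2", "q3", "q4")] <- 0
  fp0$n_hits <- 0L
  sig0 <- buildSignature(fp0)
  expect_equal(sig0$total, 0L)
  expect_equal(sig0$tier, "secondary")

  # every substructure lands in exactly one tier
  fpN <- do.call(rbind, replicate(5, fp, simplify = FALSE))
  fpN$substructure_id <- paste0("S", 1:5)
  fpN$f1 <- c(1, 0.5, 0.15, 0.05, 0)
  fpN$q3 <- fpN$f1 / fpN$flexibility
  fpN$f2 <- 0; fpN$q4 <- 0
  sigN <- buildSignature(fpN)
  expect_equal(sort(table(sigN$tier), decreasing = TRUE)[["primary"]] +
                 sum(sigN$tier == "secondary"), 5L)
  # ordered by total descending, ties broken reproducibly
  expect_true(all(diff(sigN$total) <= 0))
  expect_equal(buildSignature(fpN[sample(5), ]), sigN)
})

test_that("flexibility-zero patterns fall back to thresholded fraction scores", {
  fp <- data.frame(substructure_id = "S1", name = "rigid", smiles = "[H]C#C[H]",
                   n_hits = 3L, f1 = 0.3, n_class_hits = 1L, f2 = 0.1,
                   n_H_total = 2L, n_H_defined = 2L, n_H_variable = 0L,
                   n_heavy = 2L, flexibility = 0, q3 = NA_real_,
                   q4 = NA_real_)
  sig <- buildSignature(fp)
  expect_equal(sig$s3, sig$s1)     # falls back to thresholded s1
  expect_equal(sig$s4, 0L)         # f2 below threshold -> 0
  expect_equal(sig$tier, "primary")  # criterion (i) via f1 = 0.3
})

test_that("criterion-(i) primaries carry a fraction score of at least 3", {
  f1 <- withr::with_seed(11, runif(200))
  flex <- 0.7
  fp <- data.frame(substructure_id = sprintf("S%03d", 1:200), name = "x",
                   smiles = "C", n_hits = 1L, f1 = f1, n_class_hits = 1L,
                   f2 = 0, n_H_total = 4L, n_H_defined = 0L,
                   n_H_variable = 4L, n_heavy = 1L, flexibility = flex,
                   q3 = f1 / flex, q4 = 0)
  sig <- buildSignature(fp)
  critI <- pmax(sig$f1, sig$f2) >= 0.20
  expect_true(all(sig$s1[critI] >= 3L | sig$s2[critI] >= 3L))
})
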