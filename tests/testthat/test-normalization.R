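test_that("FPKM follows its closed form and is scale invariant", {
  cm <- toy_cm(matrix(c(50L, 50L), 1, 2), lengths = 1000)
  # one gene, length 1000, 50 counts, library 50 -> 50e9/(1000*50) = 1e6
  expect_equal(unname(fpkm(cm)$values[1, 1]), 50 * 1e9 / (1000 * 50))

  set.seed(1)
  cnt <- matrix(rpois(12, 80) + 1L, 3, 4)
  cm2 <- toy_cm(cnt, lengths = c(500, 2000, 8000))
  f1 <- fpkm(cm2)$values
  cm3 <- toy_cm(cnt * 2L, lengths = c(500, 2000, 8000))
  expect_equal(fpkm(cm3)$values, f1)  # doubling all counts leaves FPKM unchanged

  # hand-computed toy values
  cmh <- toy_cm(matrix(c(10L, 20L, 70L), 3, 1), lengths = c(100, 1000, 10000))
  expect_equal(unname(fpkm(cmh)$values[, 1]),
               c(10 * 1e9 / (100 * 100), 20 * 1e9 / (1000 * 100),
                 70 * 1e9 / (10000 * 100)))
})

test_that("TPM sums to one million per sample and matches the FPKM conversion", {
  cm <- toy_cm(matrix(c(123L, 0L), 2, 1), lengths = c(700, 900))
  expect_equal(unname(tpm(cm)$values[1, 1]), 1e6)  # single expressed gene

  set.seed(2)
  cnt <- matrix(rpois(40, 60) + 1L, 8, 5)
  cm2 <- toy_cm(cnt, lengths = round(seq(300, 9000, length.out = 8)))
  tv <- tpm(cm2)$values
  expect_equal(unname(colSums(tv)), rep(1e6, 5), tolerance = 1e-6)
  # direct computation agrees with rescaled FPKM to 1e-9 relative
  fv <- fpkm(cm2)$values
  conv <- sweep(fv, 2, colSums(fv), `/`) * 1e6
  expect_equal(tv, conv, tolerance = 1e-9)
  # FPKM column sums are not constant on this table, unlike TPM
  expect_gt(diff(range(colSums(fv))), 0)
})

test_that("the nuclear TPM budget shrinks as the mt share of rate grows", {
  # two-gene construction carrying exact length-normalized mt shares
  budget <- function(mt_share) {
    cm <- toy_cm(matrix(c(round(mt_share * 1000), 1000 - round(mt_share * 1000)),
                        2, 1), lengths = c(1000, 1000),
                 origin = c("mitochondrial", "nuclear"))
    sum(tpm(cm)$values[2, ])
  }
  expect_equal(budget(0.125), 875000)
  expect_equal(budget(0.954), 46000)
  expect_lt(budget(0.954), 50000)
})

test_that("CPM with an excluded set rescales only the remaining genes", {
  set.seed(3)
  cnt <- matrix(rpois(20, 50) + 1L, 4, 5)
  cm <- toy_cm(cnt, origin = c("mitochondrial", "nuclear", "nuclear", "nuclear"))
  # empty exclusion equals plain CPM
  plain <- cpm_excluding(cm, character(0))$values
  expect_equal(plain, sweep(cm$counts, 2, colSums(cm$counts), `/`) * 1e6)

  # mt genes at 50% of counts -> nuclear values exactly double plain CPM
  cnt2 <- matrix(c(100L, 60L, 40L, 100L, 30L, 70L), 3, 2)
  cm2 <- toy_cm(cnt2, origin = c("mitochondrial", "nuclear", "nuclear"))
  ex <- cpm_excluding(cm2, "g1")$values
  expect_equal(unname(ex[2:3, ]), sweep(cnt2[2:3, ], 2, colSums(cnt2), `/`) * 2e6)
  # the excluded gene keeps the full-total scaling
  expect_equal(unname(ex[1, ]), cnt2[1, ] / colSums(cnt2) * 1e6)

  # hand oracle with a 2-gene exclusion
  cnt3 <- matrix(c(10L, 20L, 30L, 40L), 4, 1)
  cm3 <- toy_cm(cnt3)
  ex3 <- cpm_excluding(cm3, c("g1", "g2"))$values
  expect_equal(unname(ex3[, 1]),
               c(10 / 100, 20 / 100, 30 / 70, 40 / 70) * 1e6)

  expect_error(cpm_excluding(cm3, paste0("g", 1:4)), "zero remaining")
})

test_that("upper-quartile factors use the linear-interpolation quantile of non-zero counts", {
  cm <- toy_cm(matrix(c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L), 5, 2))
  uq <- uq_factors(cm)
  expect_equal(unname(uq$raw), c(3.25, 3.25))  # non-zero basis (1,2,3,4)
  expect_equal(unname(uq$factors), c(1, 1))    # identical samples

  # scaling one sample's counts by 10 scales its raw quartile by 10
  cm2 <- toy_cm(cbind(s1 = c(0L, 1L, 2L, 3L, 4L), s2 = c(0L, 10L, 20L, 30L, 40L)))
  uq2 <- uq_factors(cm2)
  expect_equal(unname(uq2$raw[2] / uq2$raw[1]), 10)
  # depth-relative factors are equal: the scaling is pure depth
  expect_equal(unname(uq2$factors), c(1, 1))
})

test_that("median-of-ratios factors follow the definition", {
  cnt <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2)
  expect_equal(unname(mrn_factors(toy_cm(cnt))$factors), c(1, 1))

  # sample2 = 4 x sample1 -> factors (0.5, 2)
  cnt2 <- cbind(s1 = c(10L, 20L, 40L), s2 = c(40L, 80L, 160L))
  expect_equal(unname(mrn_factors(toy_cm(cnt2))$factors), c(0.5, 2))

  # no all-positive gene -> undefined
  cnt3 <- cbind(s1 = c(0L, 5L), s2 = c(5L, 0L))
  expect_error(mrn_factors(toy_cm(cnt3)), "median-of-ratios undefined")
})

test_that("MRN and TMM factors match independent brute-force oracles", {
  set.seed(11)
  for (i in 1:50) {
    cnt <- matrix(rnbinom(40, mu = 60, size = 3) + (i %% 3 == 0) * 0L, 10, 4)
    if (i %% 3 != 0) cnt <- cnt + 1L  # mix of tables with and without zeros
    if (!any(rowSums(cnt > 0) == 4)) cnt[1, ] <- cnt[1, ] + 1L
    cm <- toy_cm(cnt)
    expect_equal(mrn_factors(cm)$factors, oracle_mrn(cm$counts),
                 tolerance = 1e-10)
    if (all(cnt > 0)) {
      f <- tmm_factors(cm, ref = 2)$factors
      expect_equal(f, oracle_tmm(cm$counts, 2), tolerance = 1e-10)
    }
  }
})

test_that("MRN and TMM factors match the reference implementations", {
  set.seed(21)
  for (i in 1:10) {
    cnt <- matrix(rpois(60, 80) + 1L, 12, 5,
                  dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
    cm <- toy_cm(cnt)
    expect_equal(mrn_factors(cm)$factors,
                 DESeq2::estimateSizeFactorsForMatrix(cnt), tolerance = 1e-12)
    expect_equal(unname(tmm_factors(cm, ref = 1)$factors),
                 edgeR::calcNormFactors(edgeR::DGEList(cnt), method = "TMM",
                                        refColumn = 1)$samples$norm.factors,
                 tolerance = 1e-12)
  }
})

test_that("TMM is exactly one for proportional libraries", {
  cnt <- cbind(s1 = c(10L, 20L, 30L, 40L, 5L, 8L, 13L, 21L),
               s2 = c(30L, 60L, 90L, 120L, 15L, 24L, 39L, 63L))
  f <- tmm_factors(toy_cm(cnt))
  expect_equal(unname(f$factors), c(1, 1))
})

test_that("composition robustness: scaling one gene everywhere leaves factors almost unchanged", {
  set.seed(31)
  cnt <- matrix(rpois(60, 200) + 1L, 12, 5)
  cm <- toy_cm(cnt)
  cnt2 <- cnt; cnt2[1, ] <- cnt2[1, ] * 50L
  cm2 <- toy_cm(cnt2)
  # the scaled gene moves into the trimmed tail / away from the median,
  # so MRN factors (depth part aside) shift by far less than the 50x distortion
  r1 <- mrn_factors(cm)$factors
  r2 <- mrn_factors(cm2)$factors
  expect_lt(max(abs(log(r2 / r1))), 0.1)
  t1 <- tmm_factors(cm, ref = 1)$factors * colSums(cnt)
  t2 <- tmm_factors(cm2, ref = 1)$factors * colSums(cnt2)
  expect_lt(diff(range(log((t2 / t1)))), 0.1)
})

test_that("apply_scaling produces the documented value scales", {
  cnt <- cbind(s1 = c(10L, 20L, 40L), s2 = c(40L, 80L, 160L))
  cm <- toy_cm(cnt)
  mrn <- apply_scaling(cm, mrn_factors(cm))
  expect_equal(mrn$values[, 1], mrn$values[, 2])  # pseudocounts equalized

  uq <- uq_factors(cm)
  v <- apply_scaling(cm, uq)
  expect_equal(v$values, sweep(cm$counts, 2, uq$lib_size * uq$factors, `/`) * 1e6)

  cm_other <- toy_cm(cnt[, 1, drop = FALSE])
  expect_error(apply_scaling(cm_other, uq), "do not match")
})

test_that("all methods agree on correlation structure when composition is constant", {
  set.seed(41)
  base <- rpois(30, 300) + 1L
  depth <- c(1, 2, 0.5, 1.5, 3, 0.8)
  cnt <- round(outer(base, depth))
  storage.mode(cnt) <- "integer"
  cm <- toy_cm(cnt, lengths = sample(500:5000, 30),
               origin = c(rep("mitochondrial", 3), rep("nuclear", 27)))
  vals <- lapply(c("TPM", "FPKM", "CPM_EXCL", "UQ", "MRN", "TMM"),
                 function(m) normalize_counts(cm, m)$values)
  # proportional samples: every method yields per-gene values constant
  # across samples up to rounding, so all pairwise structure is identical
  for (v in vals)
    expect_lt(max(apply(v / v[, 1], 1, function(x) diff(range(x)))), 0.02)
})

test_that("mt fraction is the mt share of the per-sample totals", {
  cnt <- cbind(s1 = c(30L, 70L), s2 = c(100L, 0L))
  cm <- toy_cm(cnt, origin = c("mitochondrial", "nuclear"))
  expect_equal(unname(mt_fraction(cm)), c(0.3, 1.0))
  cm2 <- toy_cm(cnt, origin = c("nuclear", "nuclear"))
  expect_error(mt_fraction(cm2), "empty mitochondrial set")
  expect_equal(unname(mt_fraction(cm2, "g1")), c(0.3, 1.0))
})
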