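res_fixture <- function(n_genes = 20, n = 30, cohorts = 2, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_genes * n * cohorts), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n * cohorts))))
  structure(list(residuals = M,
                 cohorts = stats::setNames(rep(paste0("c", seq_len(cohorts)),
                                               each = n), colnames(M)),
                 scope = "per_cohort", dropped_columns = character(0)),
            class = "residual_matrix")
}

test_that("within-cohort ranking uses average ranks and flags constants", {
  M <- rbind(g1 = c(0.3, -1, 2, 5, 5, 7), g2 = c(1, 1, 1, 2, 1, 3))
  colnames(M) <- paste0("s", 1:6)
  rk <- rank_within_cohort(M, rep(c("a", "b"), each = 3))
  expect_equal(unname(rk["g1", 1:3]), c(2, 1, 3))
  expect_equal(unname(rk["g1", 4:6]), c(1.5, 1.5, 3))
  # constant within cohort a -> flagged
  M2 <- rbind(g1 = c(4, 4, 4, 1, 2, 3))
  colnames(M2) <- paste0("s", 1:6)
  rk2 <- rank_within_cohort(M2, rep(c("a", "b"), each = 3))
  expect_equal(attr(rk2, "constant_genes")$a, "g1")
})

test_that("ranking is invariant under strictly increasing transforms", {
  rf <- res_fixture()
  rk1 <- rank_within_cohort(rf)
  rf2 <- rf; rf2$residuals <- exp(3 * rf$residuals) - 5
  rk2 <- rank_within_cohort(rf2)
  expect_equal(rk1, rk2)
})

test_that("the combined analysis returns exact medians for degenerate sets", {
  rf <- res_fixture(n_genes = 5, n = 25, cohorts = 3)
  cs <- combined_set_correlation(rf, "g1", "g1", k = 10, R = 4, seed = 2)
  expect_equal(cs$rho["g1", "g1"], 1)
  expect_true(is.na(cs$between_median))  # only the same-gene pair exists
  expect_error(combined_set_correlation(rf, "g1", "g2", k = 30, R = 2, seed = 1),
               "smaller than k")
})

test_that("aggregated rank correlation is invariant to monotone within-cohort transforms", {
  rf <- res_fixture(n_genes = 8, n = 30, cohorts = 2, seed = 5)
  cs1 <- combined_set_correlation(rf, c("g1", "g2"), c("g3", "g4"),
                                  k = 20, R = 6, seed = 9)
  rf2 <- rf
  for (ch in unique(rf$cohorts)) {  # different monotone map per cohort
    sel <- rf$cohorts == ch
    rf2$residuals[, sel] <- if (ch == "c1") exp(rf$residuals[, sel])
                            else atan(rf$residuals[, sel]) * 10
  }
  cs2 <- combined_set_correlation(rf2, c("g1", "g2"), c("g3", "g4"),
                                  k = 20, R = 6, seed = 9)
  expect_equal(cs1$rho, cs2$rho, tolerance = 1e-12)
})

test_that("fixed seeds reproduce the combined analysis exactly", {
  rf <- res_fixture(n_genes = 6, n = 20, cohorts = 2, seed = 7)
  a <- combined_set_correlation(rf, c("g1", "g2"), c("g3", "g4"), 10, 5, seed = 3)
  b <- combined_set_correlation(rf, c("g1", "g2"), c("g3", "g4"), 10, 5, seed = 3)
  expect_identical(a$rho, b$rho)
})

test_that("cohort-level correlations handle monotone and anti-monotone sets", {
  set.seed(11)
  base <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(paste0("g", 1:3), NULL))
  M <- rbind(base, exp(base) + 1)  # g4..g6 are monotone transforms of g1..g3
  rownames(M)[4:6] <- paste0("h", 1:3)
  colnames(M) <- paste0("s", 1:40)
  cc <- cohort_set_correlation(M, paste0("g", 1:3), paste0("h", 1:3))
  expect_equal(unname(diag(cc$pairs)), rep(1, 3))
  M2 <- rbind(base, -base)
  rownames(M2)[4:6] <- paste0("h", 1:3); colnames(M2) <- paste0("s", 1:40)
  cc2 <- cohort_set_correlation(M2, paste0("g", 1:3), paste0("h", 1:3))
  expect_equal(unname(diag(cc2$pairs)), rep(-1, 3))
  # same-gene pairs are excluded from the summary
  cc3 <- cohort_set_correlation(M, paste0("g", 1:3), paste0("g", 1:3))
  expect_true(all(is.na(diag(cc3$pairs))))
})

test_that("bootstrap p values follow the directional and substitution rules", {
  # strongly coordinated sets: no bootstrap median crosses zero -> 1/B bound
  set.seed(13)
  f <- rnorm(40)
  M <- rbind(outer(rep(1, 4), f) + matrix(rnorm(160), 4) * 0.2,
             outer(rep(1, 4), f) + matrix(rnorm(160), 4) * 0.2)
  rownames(M) <- c(paste0("g", 1:4), paste0("h", 1:4))
  colnames(M) <- paste0("s", 1:40)
  rf <- structure(list(residuals = M,
                       cohorts = stats::setNames(rep("c1", 40), colnames(M)),
                       scope = "per_cohort", dropped_columns = character(0)),
                  class = "residual_matrix")
  sp <- bootstrap_median_correlation(rf, paste0("g", 1:4), paste0("h", 1:4),
                                     B = 100, seed = 5)
  expect_true(sp$p_is_bound)
  expect_equal(sp$p_raw, 1 / 100)
  expect_lte(sp$p_raw, 0.001 * 10)  # reported as an upper bound
  expect_equal(sp$call, "positive")
  expect_true(sp$ci_lo <= sp$median_rho && sp$median_rho <= sp$ci_hi)

  # an observed median of exactly zero gives p = 1 by the two-fraction rule
  M2 <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
              h1 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11),
              h2 = c(11, 12, 9, 10, 7, 8, 5, 6, 3, 4, 1, 2))
  colnames(M2) <- paste0("s", 1:12)
  rf2 <- structure(list(residuals = M2,
                        cohorts = stats::setNames(rep("c1", 12), colnames(M2)),
                        scope = "per_cohort", dropped_columns = character(0)),
                   class = "residual_matrix")
  obs <- cohort_set_correlation(M2, "g1", c("h1", "h2"))$median_rho
  expect_equal(obs, 0)
  sp2 <- bootstrap_median_correlation(rf2, "g1", c("h1", "h2"), B = 50, seed = 2)
  expect_equal(sp2$p_raw, 1)
  expect_equal(sp2$call, "ns")
})

test_that("the random-gene null standardizes the observed median correctly", {
  rf <- res_fixture(n_genes = 60, n = 40, cohorts = 2, seed = 17)
  rg <- random_gene_null(rf, paste0("g", 1:4), paste0("g", 5:10),
                         eligible = paste0("g", 11:60), panel_size = 6,
                         n_iter = 30, seed = 3)
  nulls <- attr(rg, "null_medians")
  for (i in seq_len(nrow(rg))) {
    expect_equal(rg$z[i],
                 (rg$observed[i] - mean(nulls[i, ])) / sd(nulls[i, ]))
    expect_equal(rg$p_two[i], 2 * pnorm(-abs(rg$z[i])))
    expect_equal(rg$p_one[i], rg$p_two[i] / 2)
  }
  # Z at 1.96 corresponds to a two-sided p of 0.05
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
  expect_error(random_gene_null(rf, "g1", "g2", eligible = paste0("g", 3:8),
                                panel_size = 50, n_iter = 5, seed = 1),
               "too few eligible")
})

test_that("expression filtering keeps nuclear genes above the median-TPM threshold", {
  cnt <- rbind(mt1 = c(800000L, 900000L), hi = c(150000L, 150000L),
               lo = c(2L, 3L))
  cm <- count_matrix(cbind(s1 = cnt[, 1], s2 = cnt[, 2]),
                     lengths = c(1000, 1000, 1000),
                     origin = c("mitochondrial", "nuclear", "nuclear"))
  tv <- tpm(cm)
  expect_setequal(expressed_genes(tv, threshold = 5), "hi")
  expect_setequal(expressed_genes(tv, threshold = 5, nuclear_only = FALSE),
                  c("mt1", "hi"))
})

test_that("Fisher's exact test matches the printed example and enumeration", {
  f <- fisher_exact_2x2(matrix(c(13, 1, 7, 7), 2, 2, byrow = TRUE))
  expect_equal(signif(f$p_value, 3), 0.0329)   # 3 s.f.
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, 2))$p_value, 0.1)
  z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(fdr_adjust(0.01), 0.01)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "p values")
  # monotone non-decreasing in p-rank
  set.seed(19)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("matched-pair analysis enforces cohort and donor matching rules", {
  md <- simulate_matched_cohorts(n_cohorts = 3, n_donors = 12,
                                 rho_tumor = 0.5, rho_normal = 0,
                                 n_background_genes = 60, rho_nu = 0.5,
                                 mt_fraction_mean = 0.15, gene_sigma = 0.4,
                                 seed = 23)
  # drop three normals from one cohort so it falls below the threshold
  norm3 <- which(md$metadata$cohort == "cohort03" &
                   md$metadata$sample_class == "adjacent_normal")
  keep_ids <- md$metadata$sample_id[-norm3[1:3]]
  cm <- md$counts[, keep_ids]
  mp <- matched_pair_analysis(cm, md$metadata[md$metadata$sample_id %in% keep_ids, ],
                              sim_mt_ids(), sim_nu_ids(), min_normals = 10,
                              B = 100, n_subsets = 25, seed = 7)
  expect_equal(mp$n_cohorts_excluded, 1)   # cohort03 fell below 10 normals
  expect_equal(nrow(mp$per_cohort), 4)     # 2 cohorts x 2 classes
  expect_equal(sum(mp$table), 4)
  # reproducible under the same seed
  mp2 <- matched_pair_analysis(cm, md$metadata[md$metadata$sample_id %in% keep_ids, ],
                               sim_mt_ids(), sim_nu_ids(), min_normals = 10,
                               B = 100, n_subsets = 25, seed = 7)
  expect_identical(mp$per_cohort, mp2$per_cohort)
})
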