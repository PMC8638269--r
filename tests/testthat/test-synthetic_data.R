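test_that("degenerate latent settings give exact expected mt read shares", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 30,
                           n_background_genes = 40, mt_fraction_mean = 0.35,
                           mt_fraction_cv = 0, gene_sigma = 0, dispersion = 0,
                           age_effect = 0, sex_effect = 0, batch_effect = 0,
                           seed = 4)
  d <- simulate_dataset(cfg)
  # with no latent noise the expected read share is exactly the target;
  # Poisson sampling jitters the realized share only slightly
  expect_equal(unname(d$truth$true_mt_share),
               rep(0.35, 30), tolerance = 1e-12)
  expect_equal(mean(mt_fraction(d$counts)), 0.35, tolerance = 0.01)
})

test_that("the generator hits the target mean mt read share", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 200,
                           n_background_genes = 200, mt_fraction_mean = 0.6,
                           mt_fraction_cv = 0.3, seed = 1)
  d <- simulate_dataset(cfg)
  expect_lt(abs(mean(mt_fraction(d$counts)) - 0.6), 0.05)
})

test_that("planted Spearman targets are exact at the latent level", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 2000,
                           n_background_genes = 10, rho_mt = 0.8,
                           rho_nu = 0.4, rho_mt_nu = 0.5, seed = 8)
  d <- simulate_dataset(cfg)
  z <- d$truth$latent_scores
  mt <- sim_mt_ids(); nu <- sim_nu_ids()
  sp_mt <- cor(t(z[mt, ]), method = "spearman")
  expect_lt(abs(median(sp_mt[upper.tri(sp_mt)]) - 0.8), 0.02)
  sp_x <- cor(t(z[mt, ]), t(z[nu[1:40], ]), method = "spearman")
  expect_lt(abs(median(sp_x) - 0.5), 0.02)
})

test_that("null planting leaves latent rank correlations at zero", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 400,
                           n_background_genes = 0, rho_mt = 0, rho_nu = 0,
                           rho_mt_nu = 0, seed = 12)
  d <- simulate_dataset(cfg)
  z <- d$truth$latent_scores
  sp <- cor(t(z[c(sim_mt_ids(), sim_nu_ids()[1:30]), ]), method = "spearman")
  expect_lt(abs(median(sp[upper.tri(sp)])), 2 / sqrt(400))
})

test_that("mt share spread grows monotonically with the configured cv", {
  spread <- vapply(c(0.05, 0.2, 0.5), function(cv) {
    cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 150,
                             n_background_genes = 50, mt_fraction_mean = 0.3,
                             mt_fraction_cv = cv, seed = 77)
    sd(mt_fraction(simulate_dataset(cfg)$counts))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("identical seed and config reproduce identical counts", {
  cfg <- simulation_config(n_cohorts = 2, samples_per_cohort = 25,
                           n_background_genes = 30, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$metadata, d2$metadata)
})

test_that("infeasible cross-block correlation is rejected", {
  expect_error(simulation_config(rho_mt = 0.1, rho_nu = 0.1, rho_mt_nu = 0.8),
               "not positive semi-definite")
  expect_error(simulation_config(mt_fraction_mean = 1.2), "mt_fraction_mean")
  expect_error(simulation_config(rho_mt = 1), "rho")
})

test_that("dominant-gene injection hits the requested pooled share", {
  set.seed(3)
  cnt <- matrix(rpois(100 * 20, 100), 100, 20)
  cm <- toy_cm(cnt)
  out <- inject_dominant_genes(cm, c("g1", "g2", "g3", "g4"), share = 0.408)
  dom <- colSums(out$counts[1:4, ]) / colSums(out$counts)
  expect_true(all(abs(dom - 0.408) < 0.02))

  # requesting each sample's current share leaves the matrix unchanged
  cur <- colSums(cm$counts[1:4, ]) / colSums(cm$counts)
  out2 <- inject_dominant_genes(cm, c("g1", "g2", "g3", "g4"), cur)
  expect_lt(max(abs(out2$counts - cm$counts)), 1)

  # single gene at 50% of a 2-gene matrix equalizes the genes
  cm2 <- toy_cm(matrix(c(100L, 300L, 100L, 300L), 2, 2, byrow = TRUE))
  out3 <- inject_dominant_genes(cm2, "g1", 0.5)
  expect_equal(unname(out3$counts[1, ]), unname(out3$counts[2, ]))

  expect_error(inject_dominant_genes(cm, "g1", 1.2), "share")
  expect_error(inject_dominant_genes(cm, "ghost", 0.3), "not present")
})

test_that("matched cohorts carry donor-paired tumour and normal samples", {
  md <- simulate_matched_cohorts(n_cohorts = 2, n_donors = 12,
                                 rho_tumor = 0.5, rho_normal = 0,
                                 n_background_genes = 40, seed = 5)
  m <- md$metadata
  expect_setequal(unique(m$sample_class), c("primary_tumor", "adjacent_normal"))
  # every normal has at least one tumour sample from the same donor
  nm <- m[m$sample_class == "adjacent_normal", ]
  tm <- m[m$sample_class == "primary_tumor", ]
  expect_true(all(paste(nm$cohort, nm$donor_id) %in% paste(tm$cohort, tm$donor_id)))
  # some donor contributed a duplicate tumour sample
  expect_gt(nrow(tm), nrow(nm))
})
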