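#' Configuration for the multi-cohort count simulator
#'
#' The simulator emulates the data regime in which composition bias arises:
#' several cohorts (tissues or cancer types), a latent per-sample
#' mitochondrial activity factor whose mean and coefficient of variation
#' control how much of the read pool the 13 mtDNA-encoded genes absorb,
#' correlated gene blocks planted at exact Spearman targets via a Gaussian
#' copula, confounder shifts, library-size variation, and negative-binomial
#' count sampling.
#'
#' Rank-correlation planting uses the Pearson-Spearman correction
#' `rho_pearson = 2*sin(pi*rho_s/6)` so that planted Spearman targets are
#' exact at the latent level. The mitochondrial read share is controlled in
#' expectation (the mt baseline is adjusted analytically given the log-normal
#' activity factor), not forced per sample.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_cohort Samples per cohort (scalar or per-cohort vector).
#' @param n_mt_genes Number of mitochondrial genes (default 13, the
#'   mtDNA-encoded OXPHOS subunits).
#' @param n_nu_genes Number of genes in the nuclear OXPHOS-like correlated
#'   block (default 126).
#' @param n_background_genes Uncorrelated nuclear background genes.
#' @param mt_fraction_mean Target expected share of reads from mt genes
#'   (scalar or per-cohort vector, each in (0,1)).
#' @param mt_fraction_cv Coefficient of variation of the latent mt activity
#'   factor (scalar or per-cohort; >= 0). Within-tissue mtRNA shares in bulk
#'   human data span wide ranges, which a cv around 0.3 reproduces.
#' @param rho_mt Planted within-block Spearman among mt genes (|rho| < 1).
#' @param rho_nu Planted within-block Spearman among nuclear-block genes.
#' @param rho_mt_nu Planted mito-nuclear cross-block Spearman (0 for null
#'   scenarios).
#' @param nu_log_boost Log-scale baseline boost applied to the nuclear
#'   correlated block (OXPHOS subunits are high-expressed genes; boosting
#'   their baseline abundance reduces their counting noise relative to the
#'   background pool).
#' @param gene_sigma Biological log-sd of per-gene expression within a cohort.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson counts).
#' @param age_effect,sex_effect,batch_effect Standard deviations of the
#'   per-gene confounder coefficients applied on the log scale.
#' @param n_batches Sequencing batches per cohort.
#' @param lib_size_log_mean,lib_size_log_sd Log-normal library size
#'   parameters.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cohorts = 5L, samples_per_cohort = 150L,
                              n_mt_genes = 13L, n_nu_genes = 126L,
                              n_background_genes = 200L,
                              mt_fraction_mean = 0.3, mt_fraction_cv = 0.3,
                              rho_mt = 0.85, rho_nu = 0.35, rho_mt_nu = 0,
                              nu_log_boost = 0, gene_sigma = 0.2, dispersion = 0.02,
                              age_effect = 0.1, sex_effect = 0.1,
                              batch_effect = 0.1, n_batches = 2L,
                              lib_size_log_mean = log(2e6),
                              lib_size_log_sd = 0.3, seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = rep_len(as.integer(samples_per_cohort), n_cohorts),
              n_mt_genes = as.integer(n_mt_genes),
              n_nu_genes = as.integer(n_nu_genes),
              n_background_genes = as.integer(n_background_genes),
              mt_fraction_mean = rep_len(mt_fraction_mean, n_cohorts),
              mt_fraction_cv = rep_len(mt_fraction_cv, n_cohorts),
              rho_mt = rho_mt, rho_nu = rho_nu, rho_mt_nu = rho_mt_nu,
              nu_log_boost = nu_log_boost,
              gene_sigma = gene_sigma, dispersion = dispersion,
              age_effect = age_effect, sex_effect = sex_effect,
              batch_effect = batch_effect, n_batches = as.integer(n_batches),
              lib_size_log_mean = lib_size_log_mean,
              lib_size_log_sd = lib_size_log_sd, seed = as.integer(seed))
  if (any(cfg$mt_fraction_mean <= 0 | cfg$mt_fraction_mean >= 1))
    stop("config error: mt_fraction_mean must be in (0, 1)")
  if (any(cfg$mt_fraction_cv < 0))
    stop("config error: mt_fraction_cv must be >= 0")
  if (any(abs(c(rho_mt, rho_nu, rho_mt_nu)) >= 1))
    stop("config error: |rho| must be < 1")
  if (cfg$dispersion < 0) stop("config error: dispersion must be >= 0")
  # feasibility of the cross-block factor loading
  sp2p <- function(r) 2 * sin(pi * r / 6)
  if (rho_mt_nu != 0) {
    denom <- sp2p(rho_mt) * sp2p(rho_nu)
    if (denom <= 0 || sp2p(rho_mt_nu)^2 > denom)
      stop("config error: planted correlation matrix not positive ",
           "semi-definite (rho_mt_nu too large for the block correlations)")
  }
  structure(cfg, class = "simulation_config")
}

# Pearson latent correlation giving a target Spearman under a Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a multi-cohort count dataset with known ground truth
#'
#' Counts are drawn in six steps: (1) per-cohort baseline log-rates per gene;
#' (2) correlated latent Gaussian scores for the mt and nuclear blocks via a
#' one-factor-per-block construction that achieves the planted Spearman
#' targets exactly at the latent level; (3) a per-sample log-normal mt
#' activity multiplier with the configured expected read share and
#' coefficient of variation, scaling all mt-gene rates; (4) confounder shifts
#' added on the log scale; (5) renormalization of rates to the sample library
#' size; (6) negative-binomial sampling. The truth object records all
#' latents, so parameter-recovery tests can compare estimates to what was
#' planted.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (a [count_matrix()]), `metadata`
#'   (data.frame: `sample_id`, `cohort`, `donor_id`, `age_bracket`, `sex`,
#'   `batch`, `ischemic_time`, `hardy_scale`, `sample_class`) and `truth`
#'   (class `simulation_truth`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_mt <- config$n_mt_genes; n_nu <- config$n_nu_genes
  n_bg <- config$n_background_genes
  n_genes <- n_mt + n_nu + n_bg
  gene_ids <- c(sprintf("MT-%02d", seq_len(n_mt)),
                sprintf("NUOX-%03d", seq_len(n_nu)),
                sprintf("BG-%03d", seq_len(n_bg)))
  origin <- c(rep("mitochondrial", n_mt), rep("nuclear", n_nu + n_bg))
  # nuclear lengths log-uniform; mt transcripts get the mean nuclear length
  # so the read-share dial and the transcript-share lever coincide
  lengths <- round(exp(stats::runif(n_genes, log(300), log(10000))))
  lengths[seq_len(n_mt)] <- 2767L  # mean of the log-uniform 300-10000 draw

  # gene base abundances (shared across cohorts) + cohort-specific shifts
  base_log <- stats::rnorm(n_genes, 0, 1.2)
  base_log[n_mt + seq_len(n_nu)] <- base_log[n_mt + seq_len(n_nu)] +
    config$nu_log_boost
  cohort_shift <- matrix(stats::rnorm(n_genes * config$n_cohorts, 0, 0.2),
                         n_genes, config$n_cohorts)

  r_mt_p <- spearman_to_pearson(config$rho_mt)
  r_nu_p <- spearman_to_pearson(config$rho_nu)
  r_x_p <- spearman_to_pearson(config$rho_mt_nu)
  factor_cor <- if (r_x_p == 0) 0 else r_x_p / sqrt(r_mt_p * r_nu_p)

  mt_idx <- seq_len(n_mt)
  nu_idx <- n_mt + seq_len(n_nu)
  bg_idx <- n_mt + n_nu + seq_len(n_bg)

  counts_all <- list(); meta_all <- list()
  z_all <- list(); m_all <- c(); fmt_all <- c(); fnu_all <- c()
  lib_all <- c(); share_all <- c()
  beta_age <- stats::rnorm(n_genes, 0, config$age_effect)
  beta_sex <- stats::rnorm(n_genes, 0, config$sex_effect)

  brackets <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
  for (c_i in seq_len(config$n_cohorts)) {
    n_s <- config$samples_per_cohort[c_i]
    f_tgt <- config$mt_fraction_mean[c_i]
    cv <- config$mt_fraction_cv[c_i]

    # latent block scores
    F_mt <- stats::rnorm(n_s)
    F_nu <- factor_cor * F_mt + sqrt(1 - factor_cor^2) * stats::rnorm(n_s)
    z <- matrix(stats::rnorm(n_genes * n_s), n_genes, n_s)
    if (r_mt_p > 0)
      z[mt_idx, ] <- sqrt(r_mt_p) * rep(F_mt, each = n_mt) +
        sqrt(1 - r_mt_p) * z[mt_idx, ]
    if (r_nu_p > 0)
      z[nu_idx, ] <- sqrt(r_nu_p) * rep(F_nu, each = n_nu) +
        sqrt(1 - r_nu_p) * z[nu_idx, ]

    # mt activity multiplier, E[m] = 1, CV = cv
    s2 <- log(1 + cv^2)
    m <- if (cv == 0) rep(1, n_s) else
      stats::rlnorm(n_s, meanlog = -s2 / 2, sdlog = sqrt(s2))

    # confounders
    donor <- sprintf("D%02d-%04d", c_i, seq_len(n_s))
    age_bracket <- sample(brackets, n_s, replace = TRUE)
    age_mid <- vapply(age_bracket, age_midpoint, numeric(1))
    age_std <- (age_mid - 49.5) / 17  # approx centring/scaling of bracket midpoints
    sex <- sample(c("male", "female"), n_s, replace = TRUE)
    sex_code <- ifelse(sex == "male", 0.5, -0.5)
    batch <- sample(sprintf("B%d", seq_len(config$n_batches)), n_s, replace = TRUE)
    gamma_batch <- matrix(stats::rnorm(n_genes * config$n_batches, 0,
                                       config$batch_effect),
                          n_genes, config$n_batches)
    batch_i <- match(batch, sprintf("B%d", seq_len(config$n_batches)))

    log_rate <- base_log + cohort_shift[, c_i] + config$gene_sigma * z +
      outer(beta_age, age_std) + outer(beta_sex, sex_code) +
      gamma_batch[, batch_i]

    # analytic mt baseline adjustment: reads are proportional to transcript
    # abundance times transcript length, and with E[m] = 1 the mt baseline
    # scale alpha is chosen so the expected mt share of reads hits the target
    e_nu <- sum(exp(base_log[-mt_idx] + cohort_shift[-mt_idx, c_i] +
                      config$gene_sigma^2 / 2) * lengths[-mt_idx])
    e_mt <- sum(exp(base_log[mt_idx] + cohort_shift[mt_idx, c_i] +
                      config$gene_sigma^2 / 2) * lengths[mt_idx])
    alpha <- f_tgt / (1 - f_tgt) * e_nu / e_mt
    rate <- exp(log_rate)
    rate[mt_idx, ] <- alpha * rate[mt_idx, ] * rep(m, each = n_mt)

    lib <- stats::rlnorm(n_s, config$lib_size_log_mean, config$lib_size_log_sd)
    read_rate <- rate * lengths
    mu <- sweep(read_rate, 2, lib / colSums(read_rate), `*`)
    cnt <- if (config$dispersion == 0)
      matrix(stats::rpois(length(mu), mu), n_genes, n_s)
    else
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             n_genes, n_s)

    sid <- sprintf("C%02d-S%04d", c_i, seq_len(n_s))
    colnames(cnt) <- sid; rownames(cnt) <- gene_ids
    counts_all[[c_i]] <- cnt
    meta_all[[c_i]] <- data.frame(
      sample_id = sid, cohort = sprintf("cohort%02d", c_i), donor_id = donor,
      age_bracket = age_bracket, sex = sex, batch = batch,
      ischemic_time = round(stats::rnorm(n_s, 600, 150)),
      hardy_scale = sample(0:4, n_s, replace = TRUE),
      sample_class = "healthy", stringsAsFactors = FALSE)
    z_all[[c_i]] <- z
    m_all <- c(m_all, m); fmt_all <- c(fmt_all, F_mt); fnu_all <- c(fnu_all, F_nu)
    lib_all <- c(lib_all, lib)
    share_all <- c(share_all,
                   colSums(read_rate[mt_idx, , drop = FALSE]) / colSums(read_rate))
  }

  counts <- do.call(cbind, counts_all)
  metadata <- do.call(rbind, meta_all)
  truth <- structure(list(
    latent_scores = do.call(cbind, z_all),
    mt_multiplier = stats::setNames(m_all, metadata$sample_id),
    block_factors = data.frame(sample_id = metadata$sample_id,
                               F_mt = fmt_all, F_nu = fnu_all),
    planted = list(rho_mt = config$rho_mt, rho_nu = config$rho_nu,
                   rho_mt_nu = config$rho_mt_nu),
    mt_idx = mt_idx, nu_idx = nu_idx, bg_idx = bg_idx,
    beta_age = beta_age, beta_sex = beta_sex,
    lib_sizes = stats::setNames(lib_all, metadata$sample_id),
    true_mt_share = stats::setNames(share_all, metadata$sample_id),
    config = config), class = "simulation_truth")
  dimnames(truth$latent_scores) <- list(gene_ids, metadata$sample_id)

  list(counts = count_matrix(counts, lengths = lengths, origin = origin),
       metadata = metadata, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d genes x %d samples\n",
              nrow(x$latent_scores), ncol(x$latent_scores)))
  cat(sprintf("  planted Spearman: mt %.2f, nu %.2f, mt-nu %.2f\n",
              x$planted$rho_mt, x$planted$rho_nu, x$planted$rho_mt_nu))
  cat(sprintf("  mean true mt share: %.3f\n", mean(x$true_mt_share)))
  invisible(x)
}

#' Rescale genes so their pooled read share hits a target
#'
#' Counterpart of the dominant-transcript situations seen in real tissues
#' (haemoglobin genes in whole blood, digestive serine proteases in
#' pancreas): the named genes are scaled per sample so that their pooled
#' expected share of the sample total equals `share`, preserving relative
#' proportions among all other genes. Counts are rounded back to integers.
#'
#' @param cm A [count_matrix()].
#' @param gene_ids Genes forming the dominant block.
#' @param share Target count fraction in (0, 1); a scalar applies to every
#'   sample, a vector gives per-sample targets.
#' @return A `count_matrix` with rescaled counts.
#' @export
inject_dominant_genes <- function(cm, gene_ids, share) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(share <= 0) || any(share >= 1))
    stop("config error: share must be in (0, 1)")
  share <- rep_len(share, ncol(cm$counts))
  missing <- setdiff(gene_ids, rownames(cm$counts))
  if (length(missing) > 0)
    stop("validation error: genes not present: ", paste(missing, collapse = ", "))
  counts <- cm$counts
  di <- rownames(counts) %in% gene_ids
  dom <- colSums(counts[di, , drop = FALSE])
  oth <- colSums(counts[!di, , drop = FALSE])
  if (any(dom == 0))
    stop("validation error: dominant block has zero counts in some samples")
  scale <- (share / (1 - share)) * oth / dom
  counts[di, ] <- round(sweep(counts[di, , drop = FALSE], 2, scale, `*`))
  gi <- match(rownames(counts), cm$genes$gene_id)
  count_matrix(counts, lengths = cm$genes$length_bp[gi],
               origin = cm$genes$origin[gi], symbols = cm$genes$symbol[gi])
}

#' Simulate matched tumour/normal cohorts
#'
#' Builds the data shape required by [matched_pair_analysis()]: for each
#' cohort, donor-matched primary-tumour and adjacent-normal samples, with the
#' mito-nuclear coordination planted separately in each class (e.g. present
#' in tumours, absent in normals). A fraction of donors contribute two
#' tumour samples to exercise the retain-one-at-random rule.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_donors Donors per cohort (each yields one normal and >= 1 tumour
#'   sample).
#' @param rho_tumor,rho_normal Planted mito-nuclear Spearman in each class.
#' @param dup_tumor_frac Fraction of donors with a duplicate tumour sample.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulation_config()] (gene counts,
#'   mt fraction, noise levels).
#' @return A list with `counts`, `metadata` and per-class `truth` objects.
#' @export
simulate_matched_cohorts <- function(n_cohorts = 4L, n_donors = 30L,
                                     rho_tumor = 0.5, rho_normal = 0,
                                     dup_tumor_frac = 0.1, seed = 1L, ...) {
  build <- function(class_rho, class_seed) {
    cfg <- simulation_config(n_cohorts = n_cohorts,
                             samples_per_cohort = n_donors,
                             rho_mt_nu = class_rho, seed = class_seed, ...)
    simulate_dataset(cfg)
  }
  tum <- build(rho_tumor, stage_seed(seed, "tumor"))
  nor <- build(rho_normal, stage_seed(seed, "normal"))

  relabel <- function(d, class, tag) {
    d$metadata$sample_class <- class
    d$metadata$sample_id <- paste0(d$metadata$sample_id, tag)
    colnames(d$counts$counts) <- d$metadata$sample_id
    d$counts$samples <- d$metadata$sample_id
    d
  }
  tum <- relabel(tum, "primary_tumor", "-T")
  nor <- relabel(nor, "adjacent_normal", "-N")
  # same donors in both classes
  nor$metadata$donor_id <- tum$metadata$donor_id

  # duplicate tumour samples for a fraction of donors
  set.seed(stage_seed(seed, "dup"))
  n_dup <- max(1L, round(dup_tumor_frac * n_donors))
  dup_rows <- unlist(lapply(seq_len(n_cohorts), function(c_i) {
    rows <- which(tum$metadata$cohort == sprintf("cohort%02d", c_i))
    sample(rows, n_dup)
  }))
  dup_counts <- tum$counts$counts[, dup_rows, drop = FALSE]
  dup_meta <- tum$metadata[dup_rows, ]
  dup_meta$sample_id <- paste0(dup_meta$sample_id, "b")
  colnames(dup_counts) <- dup_meta$sample_id

  counts <- cbind(tum$counts$counts, dup_counts, nor$counts$counts)
  metadata <- rbind(tum$metadata, dup_meta, nor$metadata)
  g <- tum$counts$genes
  list(counts = count_matrix(counts, lengths = g$length_bp,
                             origin = g$origin, symbols = g$symbol),
       metadata = metadata,
       truth = list(tumor = tum$truth, normal = nor$truth))
}
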