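#' Rank residuals within each cohort
#'
#' Ranks every gene's residuals within each cohort (ties receive average
#' ranks). Ranking within cohort makes the downstream aggregated
#' correlation invariant to any strictly monotone within-cohort transform
#' of the residuals and stops high-expression cohorts from dominating the
#' combined statistic. Genes constant within a cohort receive equal ranks
#' and are flagged.
#'
#' @param residuals A `residual_matrix` from [regress_out()] or a bare
#'   genes-by-samples matrix.
#' @param cohort_labels Character vector of cohort labels per sample
#'   (ignored when `residuals` is a `residual_matrix`).
#' @return A genes-by-samples matrix of within-cohort ranks with attribute
#'   `constant_genes` (named list per cohort).
#' @export
rank_within_cohort <- function(residuals, cohort_labels = NULL) {
  M <- resid_values(residuals)
  if (is.null(cohort_labels)) cohort_labels <- resid_cohorts(residuals)
  stopifnot(length(cohort_labels) == ncol(M))
  out <- M
  const <- list()
  for (ch in unique(cohort_labels)) {
    sel <- which(cohort_labels == ch)
    if (length(sel) < 3) stop("cohort '", ch, "' has fewer than 3 samples")
    sub <- M[, sel, drop = FALSE]
    out[, sel] <- t(apply(sub, 1, rank))
    cg <- rownames(M)[apply(sub, 1, function(x) length(unique(x)) == 1)]
    if (length(cg) > 0) const[[ch]] <- cg
  }
  attr(out, "constant_genes") <- const
  out
}

resid_values <- function(x) {
  if (inherits(x, "residual_matrix")) x$residuals
  else if (inherits(x, "normalized_matrix")) x$values
  else as.matrix(x)
}

resid_cohorts <- function(x) {
  if (inherits(x, "residual_matrix")) return(unname(x$cohorts))
  stop("cohort labels required when residuals is a bare matrix")
}

check_sets <- function(set_a, set_b, M) {
  set_a <- intersect(as.character(set_a), rownames(M))
  set_b <- intersect(as.character(set_b), rownames(M))
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("validation error: gene set has no genes present in the matrix")
  list(a = set_a, b = set_b)
}

#' Combined-cohort set correlation by rank aggregation
#'
#' The combined analysis draws `k` samples per cohort without replacement,
#' ranks each gene's residuals within the drawn cohort subset, concatenates
#' the ranks across cohorts, and computes the correlation of every gene
#' pair across the aggregated ranks (Pearson on concatenated within-cohort
#' ranks; within-cohort ranks repeat identically across cohorts, so global
#' re-ranking would only introduce ties). The procedure is repeated `R`
#' times and the elementwise median over iterations is reported.
#'
#' @param residuals A `residual_matrix`.
#' @param set_a,set_b Character vectors of gene ids.
#' @param k Samples drawn per cohort each iteration.
#' @param R Number of iterations.
#' @param seed Integer seed.
#' @return A `correlation_matrix_result`: list with `rho` (median
#'   correlation matrix over the union of the sets), `set_a`, `set_b`,
#'   `between_median` (median over all between-set pairs, same-gene pairs
#'   excluded), `within_a_median`, `within_b_median` (off-diagonal pairs
#'   only), `k`, `R`, `seed`.
#' @export
combined_set_correlation <- function(residuals, set_a, set_b, k = 100L,
                                     R = 100L, seed = 1L) {
  stopifnot(R >= 1, k >= 3)
  M <- resid_values(residuals)
  cohorts <- resid_cohorts(residuals)
  sets <- check_sets(set_a, set_b, M)
  genes <- union(sets$a, sets$b)
  M <- M[genes, , drop = FALSE]

  sizes <- table(cohorts)
  small <- names(sizes)[sizes < k]
  if (length(small) > 0)
    stop("cohort(s) smaller than k = ", k, ": ", paste(small, collapse = ", "))

  set.seed(seed)
  acc <- array(NA_real_, c(length(genes), length(genes), R))
  for (r in seq_len(R)) {
    ranked <- lapply(unique(cohorts), function(ch) {
      sel <- sample(which(cohorts == ch), k)
      t(apply(M[, sel, drop = FALSE], 1, rank))
    })
    agg <- do.call(cbind, ranked)
    acc[, , r] <- suppressWarnings(stats::cor(t(agg)))
  }
  med <- apply(acc, c(1, 2), stats::median)
  dimnames(med) <- list(genes, genes)

  structure(list(rho = med, set_a = sets$a, set_b = sets$b,
                 between_median = between_set_median(med, sets$a, sets$b),
                 within_a_median = within_set_median(med, sets$a),
                 within_b_median = within_set_median(med, sets$b),
                 k = as.integer(k), R = as.integer(R), seed = as.integer(seed)),
            class = "correlation_matrix_result")
}

between_set_median <- function(rho, a, b) {
  sub <- rho[a, b, drop = FALSE]
  same <- outer(a, b, `==`)
  stats::median(sub[!same], na.rm = TRUE)
}

within_set_median <- function(rho, a) {
  if (length(a) < 2) return(NA_real_)
  sub <- rho[a, a, drop = FALSE]
  stats::median(sub[upper.tri(sub)], na.rm = TRUE)
}

#' @export
print.correlation_matrix_result <- function(x, ...) {
  cat(sprintf("correlation_matrix_result: %d x %d genes, median over R = %d (k = %d)\n",
              length(x$set_a), length(x$set_b), x$R, x$k))
  cat(sprintf("  between-set median rho: %.4f\n", x$between_median))
  cat(sprintf("  within-set medians: A %.4f, B %.4f\n",
              x$within_a_median, x$within_b_median))
  invisible(x)
}

#' Gene ordering for correlation heatmaps
#'
#' Average-linkage hierarchical clustering on distance `1 - rho`, intended
#' to be computed once (on the combined-cohort MRN result) and reused for
#' every other heatmap so panels are directly comparable.
#'
#' @param result A `correlation_matrix_result`.
#' @return Character vector of gene ids in display order.
#' @export
cluster_gene_order <- function(result) {
  d <- stats::as.dist(1 - result$rho)
  hc <- stats::hclust(d, method = "average")
  rownames(result$rho)[hc$order]
}

#' Within-cohort set correlation on all samples
#'
#' Spearman correlation of every between-set gene pair across all samples of
#' one cohort; the scalar summary is the median over pairs. Pairs where the
#' same gene appears in both sets are excluded; genes with fewer than two
#' distinct values are dropped and counted.
#'
#' @param residuals A `residual_matrix` (or bare matrix restricted to one
#'   cohort).
#' @param set_a,set_b Character vectors of gene ids.
#' @param cohort Cohort label to analyse; defaults to the only cohort
#'   present.
#' @return List with `median_rho`, `pairs` (|A| x |B| Spearman matrix, NA on
#'   excluded pairs), `n_samples`, `n_dropped_genes`.
#' @export
cohort_set_correlation <- function(residuals, set_a, set_b, cohort = NULL) {
  M <- resid_values(residuals)
  if (inherits(residuals, "residual_matrix")) {
    cohorts <- resid_cohorts(residuals)
    if (is.null(cohort)) {
      u <- unique(cohorts)
      if (length(u) > 1) stop("multiple cohorts present; specify `cohort`")
      cohort <- u
    }
    M <- M[, cohorts == cohort, drop = FALSE]
  }
  if (ncol(M) < 10) stop("cohort has fewer than 10 samples")
  sets <- check_sets(set_a, set_b, M)
  ok <- apply(M[union(sets$a, sets$b), , drop = FALSE], 1,
              function(x) length(unique(x)) >= 2)
  dropped <- sum(!ok)
  a <- sets$a[ok[sets$a]]; b <- sets$b[ok[sets$b]]
  if (length(a) == 0 || length(b) == 0)
    stop("no usable genes after dropping constant genes")
  ra <- t(apply(M[a, , drop = FALSE], 1, rank))
  rb <- t(apply(M[b, , drop = FALSE], 1, rank))
  pairs <- stats::cor(t(ra), t(rb))
  dimnames(pairs) <- list(a, b)
  pairs[outer(a, b, `==`)] <- NA_real_
  list(median_rho = stats::median(pairs, na.rm = TRUE), pairs = pairs,
       n_samples = ncol(M), n_dropped_genes = dropped)
}

# median between-set Spearman for a column subset, NA if degenerate
median_pair_rho <- function(M, a, b, cols) {
  sub <- M[c(a, b), cols, drop = FALSE]
  rk <- t(apply(sub, 1, rank))
  # constant rows have zero rank variance
  if (any(rowSums((rk - (ncol(rk) + 1) / 2)^2) == 0)) return(NA_real_)
  ia <- seq_along(a); ib <- length(a) + seq_along(b)
  rho <- stats::cor(t(rk[ia, , drop = FALSE]), t(rk[ib, , drop = FALSE]))
  rho[outer(a, b, `==`)] <- NA_real_
  stats::median(rho, na.rm = TRUE)
}

#' Bootstrap inference for the median set-pair correlation
#'
#' For every cohort: resample samples with replacement `B` times, recompute
#' the median between-set Spearman correlation, and report the 2.5/97.5
#' percentile confidence interval together with empirical p values. The raw
#' p is the fraction of bootstrap medians on the opposite side of 0 from
#' the observed median (the directional convention of the source
#' methodology); when no bootstrap median crosses 0 the value `1/B` is
#' substituted and the p is flagged as an upper bound. A sign-doubled
#' two-sided p (`p_two = min(1, 2 * p_raw)`) is also reported; it is the
#' quantity that is approximately uniform under a true null, and it is what
#' the package's calibration checks assert. BH-FDR is applied across
#' cohorts (on the raw p, following the source convention).
#'
#' @param residuals A `residual_matrix`.
#' @param set_a,set_b Character vectors of gene ids.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param fdr_level Level for the significance call.
#' @param max_redraws Degenerate resamples (a gene constant) are redrawn at
#'   most this many times each before being skipped.
#' @return A `set_pair_summary` data.frame with one row per cohort: columns
#'   `cohort`, `median_rho`, `ci_lo`, `ci_hi`, `p_raw`, `p_is_bound`,
#'   `p_two`, `fdr`, `call` (`positive` / `negative` / `ns`), `n_samples`,
#'   `n_redraws`.
#' @export
bootstrap_median_correlation <- function(residuals, set_a, set_b, B = 1000L,
                                         seed = 1L, fdr_level = 0.05,
                                         max_redraws = 50L) {
  M <- resid_values(residuals)
  cohorts <- resid_cohorts(residuals)
  sets <- check_sets(set_a, set_b, M)
  set.seed(seed)
  rows <- lapply(unique(cohorts), function(ch) {
    cols <- which(cohorts == ch)
    n <- length(cols)
    obs <- median_pair_rho(M, sets$a, sets$b, cols)
    boot <- numeric(B)
    redraws <- 0L
    for (bi in seq_len(B)) {
      val <- NA_real_
      for (tr in seq_len(max_redraws)) {
        val <- median_pair_rho(M, sets$a, sets$b, sample(cols, n, replace = TRUE))
        if (!is.na(val)) break
        redraws <- redraws + 1L
      }
      boot[bi] <- val
    }
    boot <- boot[!is.na(boot)]
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    if (obs == 0) {
      p_raw <- 1; bound <- FALSE
    } else {
      frac <- if (obs < 0) mean(boot > 0) else mean(boot < 0)
      bound <- frac == 0
      p_raw <- if (bound) 1 / B else frac
    }
    data.frame(cohort = ch, median_rho = obs, ci_lo = ci[1], ci_hi = ci[2],
               p_raw = p_raw, p_is_bound = bound,
               p_two = min(1, 2 * p_raw), n_samples = n,
               n_redraws = redraws, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- fdr_adjust(out$p_raw)
  out$call <- ifelse(out$fdr < fdr_level,
                     ifelse(out$median_rho > 0, "positive", "negative"), "ns")
  class(out) <- c("set_pair_summary", "data.frame")
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @export
print.set_pair_summary <- function(x, ...) {
  cat(sprintf("set_pair_summary over %d cohort(s), B = %d bootstrap resamples\n",
              nrow(x), attr(x, "B")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Genes passing the expression filter
#'
#' "Expressed" genes are those whose median TPM across all samples of all
#' cohorts exceeds the threshold; by default only nuclear genes qualify, as
#' the panels this filter feeds stand in for random nuclear genes.
#'
#' @param tpm_values A `normalized_matrix` with method `"TPM"`.
#' @param threshold Median-TPM cutoff (default 5).
#' @param nuclear_only Restrict to genes annotated nuclear.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(tpm_values, threshold = 5, nuclear_only = TRUE) {
  stopifnot(inherits(tpm_values, "normalized_matrix"))
  med <- apply(tpm_values$values, 1, stats::median)
  ids <- rownames(tpm_values$values)[med > threshold]
  if (nuclear_only)
    ids <- intersect(ids, tpm_values$genes$gene_id[tpm_values$genes$origin == "nuclear"])
  ids
}

#' Random-gene-panel null for an observed set-pair correlation
#'
#' Replaces `set_b` with `n_iter` random panels of `panel_size` genes drawn
#' from the eligible pool (expressed nuclear genes outside both sets),
#' recomputes the median set-vs-panel correlation per panel, and
#' standardizes the observed set-A-vs-set-B median against the null panel
#' medians: `Z = (observed - mean(null)) / sd(null)`. Normality of the 100
#' medians (expected under the central limit theorem) is checked with a
#' Shapiro-Wilk test; p values come from the normal CDF (two-sided by
#' default, one-sided also reported) and are BH-adjusted across cohorts.
#'
#' @param residuals A `residual_matrix`.
#' @param set_a,set_b Character vectors of gene ids.
#' @param eligible Pool of gene ids the panels are drawn from (see
#'   [expressed_genes()]); genes in either set are removed from the pool.
#' @param panel_size Genes per random panel.
#' @param n_iter Number of panels.
#' @param seed Integer seed.
#' @return A `null_distribution` data.frame with one row per cohort:
#'   `cohort`, `observed`, `null_mean`, `null_sd`, `z`, `p_two`, `p_one`,
#'   `shapiro_p`, `fdr` (on `p_two`), plus attribute `null_medians` (matrix
#'   cohorts x n_iter).
#' @export
random_gene_null <- function(residuals, set_a, set_b, eligible,
                             panel_size = 126L, n_iter = 100L, seed = 1L) {
  M <- resid_values(residuals)
  cohorts <- resid_cohorts(residuals)
  sets <- check_sets(set_a, set_b, M)
  pool <- setdiff(intersect(eligible, rownames(M)), c(sets$a, sets$b))
  if (length(pool) < panel_size)
    stop("too few eligible genes for the null panel: ", length(pool),
         " available, ", panel_size, " required")
  set.seed(seed)
  u <- unique(cohorts)
  nulls <- matrix(NA_real_, length(u), n_iter, dimnames = list(u, NULL))
  obs <- stats::setNames(numeric(length(u)), u)
  for (ch in u) {
    cols <- which(cohorts == ch)
    obs[ch] <- median_pair_rho(M, sets$a, sets$b, cols)
    for (it in seq_len(n_iter)) {
      panel <- sample(pool, panel_size)
      nulls[ch, it] <- median_pair_rho(M, sets$a, panel, cols)
    }
  }
  mu <- rowMeans(nulls); sdv <- apply(nulls, 1, stats::sd)
  z <- (obs - mu) / sdv
  out <- data.frame(cohort = u, observed = unname(obs), null_mean = unname(mu),
                    null_sd = unname(sdv), z = unname(z),
                    p_two = 2 * stats::pnorm(-abs(z)),
                    p_one = stats::pnorm(-abs(z)),
                    shapiro_p = apply(nulls, 1, function(v) stats::shapiro.test(v)$p.value),
                    stringsAsFactors = FALSE)
  out$fdr <- fdr_adjust(out$p_two)
  class(out) <- c("null_distribution", "data.frame")
  attr(out, "null_medians") <- nulls
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution over %d cohort(s), %d panels each\n",
              nrow(x), ncol(attr(x, "null_medians"))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Matched tumour/normal comparison of set coordination
#'
#' Restricts to cohorts with at least `min_normals` adjacent-normal samples,
#' builds donor-matched 1:1 tumour/normal pairs (one tumour retained at
#' random when several match; normals without a tumour dropped and
#' counted), then within each cohort and class normalizes by
#' median-of-ratios, regresses the design covariates out, and computes the
#' median between-set Spearman correlation. The bootstrapped standard error
#' is the standard deviation of medians over `n_subsets` draws of 90% of
#' the samples; significance calls per class come from
#' [bootstrap_median_correlation()], and the cross-cohort 2x2 table of
#' significant-positive calls (tumour vs normal) is tested with Fisher's
#' exact test.
#'
#' @param cm A [count_matrix()] holding both classes.
#' @param metadata Metadata with `sample_class` (`primary_tumor` /
#'   `adjacent_normal`), `donor_id`, `cohort`.
#' @param set_a,set_b Character vectors of gene ids.
#' @param min_normals Minimum adjacent-normal samples per cohort.
#' @param design A [design_spec()] of confounders to regress out.
#' @param B Bootstrap resamples for the significance call.
#' @param n_subsets 90% subsets for the standard error.
#' @param seed Integer seed.
#' @param fdr_level Level for significance calls.
#' @return A `matched_pair_result`: list with `per_cohort` (data.frame:
#'   cohort, class, median_rho, boot_se, call), `table` (2x2 matrix of
#'   significant-positive counts), `fisher_p`, `odds_ratio`,
#'   `n_dropped_normals`, `n_cohorts_excluded`.
#' @export
matched_pair_analysis <- function(cm, metadata, set_a, set_b,
                                  min_normals = 10L, design = design_spec(),
                                  B = 1000L, n_subsets = 100L, seed = 1L,
                                  fdr_level = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  md <- metadata[match(colnames(cm$counts), metadata$sample_id), ]
  set.seed(stage_seed(seed, "matching"))

  norm_md <- md[md$sample_class == "adjacent_normal", ]
  sizes <- table(norm_md$cohort)
  keep_cohorts <- names(sizes)[sizes >= min_normals]
  excluded <- setdiff(unique(md$cohort), keep_cohorts)
  if (length(keep_cohorts) == 0) stop("no cohort has enough normal samples")

  pairs <- list(); dropped_normals <- 0L
  for (ch in keep_cohorts) {
    nm <- md[md$cohort == ch & md$sample_class == "adjacent_normal", ]
    tm <- md[md$cohort == ch & md$sample_class == "primary_tumor", ]
    for (i in seq_len(nrow(nm))) {
      cand <- tm$sample_id[tm$donor_id == nm$donor_id[i]]
      if (length(cand) == 0) { dropped_normals <- dropped_normals + 1L; next }
      chosen <- if (length(cand) == 1) cand else sample(cand, 1)
      pairs[[length(pairs) + 1]] <- data.frame(
        cohort = ch, donor_id = nm$donor_id[i],
        normal = nm$sample_id[i], tumor = chosen, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)

  per_class_median <- function(ch, class) {
    sids <- if (class == "primary_tumor") pairs$tumor[pairs$cohort == ch]
            else pairs$normal[pairs$cohort == ch]
    sub <- cm[, sids]
    nm <- apply_scaling(sub, mrn_factors(sub))
    rm_ <- regress_out(nm, md[match(sids, md$sample_id), ], design,
                       scope = "per_cohort")
    rm_
  }

  rows <- list(); sig_pos <- c(primary_tumor = 0L, adjacent_normal = 0L)
  for (class in c("primary_tumor", "adjacent_normal")) {
    res_list <- lapply(keep_cohorts, per_class_median, class = class)
    # one residual_matrix across the class's cohorts for the FDR
    res_all <- structure(list(
      residuals = do.call(cbind, lapply(res_list, `[[`, "residuals")),
      cohorts = unlist(lapply(res_list, `[[`, "cohorts")),
      scope = "per_cohort", dropped_columns = character(0)),
      class = "residual_matrix")
    sps <- bootstrap_median_correlation(res_all, set_a, set_b, B = B,
                                        seed = stage_seed(seed, paste0("boot_", class)),
                                        fdr_level = fdr_level)
    set.seed(stage_seed(seed, paste0("subsets_", class)))
    for (ch in keep_cohorts) {
      Mch <- res_all$residuals[, res_all$cohorts == ch, drop = FALSE]
      n <- ncol(Mch); n90 <- max(3L, floor(0.9 * n))
      sets <- check_sets(set_a, set_b, Mch)
      meds <- vapply(seq_len(n_subsets), function(i)
        median_pair_rho(Mch, sets$a, sets$b, sample(n, n90)), numeric(1))
      row <- sps[sps$cohort == ch, ]
      rows[[length(rows) + 1]] <- data.frame(
        cohort = ch, class = class, median_rho = row$median_rho,
        boot_se = stats::sd(meds, na.rm = TRUE), p_raw = row$p_raw,
        fdr = row$fdr, call = row$call, n_pairs = n,
        stringsAsFactors = FALSE)
      if (row$call == "positive") sig_pos[class] <- sig_pos[class] + 1L
    }
  }
  per_cohort <- do.call(rbind, rows)
  nc <- length(keep_cohorts)
  tab <- matrix(c(sig_pos["primary_tumor"], nc - sig_pos["primary_tumor"],
                  sig_pos["adjacent_normal"], nc - sig_pos["adjacent_normal"]),
                2, 2, byrow = TRUE,
                dimnames = list(c("tumor", "normal"),
                                c("sig_positive", "not_sig_positive")))
  fish <- fisher_exact_2x2(tab)
  structure(list(per_cohort = per_cohort, table = tab,
                 fisher_p = fish$p_value, odds_ratio = fish$odds_ratio,
                 n_dropped_normals = dropped_normals,
                 n_cohorts_excluded = length(excluded)),
            class = "matched_pair_result")
}

#' @export
print.matched_pair_result <- function(x, ...) {
  cat("matched_pair_result\n")
  print(x$table)
  cat(sprintf("Fisher exact p = %.4g (odds ratio %.3g)\n",
              x$fisher_p, x$odds_ratio))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by summing, over the hypergeometric support defined by
#' the table margins, the probabilities of all tables at most as probable
#' as the observed one. The sample odds ratio `(ad)/(bc)` is reported
#' alongside. A zero margin yields p = 1 by convention, flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p_value`, `odds_ratio`, `degenerate` (zero-margin
#'   flag).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_; n2 <- b + d
  orr <- (a * d) / (b * c_)
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0)
    return(list(p_value = 1, odds_ratio = orr, degenerate = TRUE))
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(support, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), odds_ratio = orr, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q values via [stats::p.adjust()]; empty input returns empty
#' output.
#'
#' @param p_values Numeric vector of p values in (0, 1].
#' @return Numeric vector of q values.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
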