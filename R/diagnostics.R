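#' Composition-bias curves across cohorts and normalizations
#'
#' Quantifies the compositional artifact the way the motivating analyses
#' do: for each cohort and each normalization method, the median
#' between-set Spearman correlation (mitochondrial vs nuclear set), the
#' mean over random panels of the median mt-vs-panel correlation, and the
#' mean over random panels of the median within-panel correlation, each
#' reported against the cohort's mean and coefficient of variation of the
#' mitochondrial read fraction. Under total-count normalizations (TPM,
#' FPKM) the mt-vs-nuclear medians turn negative and the random-random
#' medians positive as the mt fraction grows; under MRN/TMM both stay near
#' zero.
#'
#' @param cm A [count_matrix()].
#' @param metadata Sample metadata with `sample_id` and `cohort`.
#' @param mt_set,nu_set Character vectors of gene ids (e.g. the 13
#'   mtDNA-encoded and 126 nuclear OXPHOS genes).
#' @param methods Normalization methods to compare (subset of the six).
#' @param design A [design_spec()] regressed out within each cohort before
#'   correlation.
#' @param n_panels Random panels per cohort/method.
#' @param rr_panel_size Genes per random-random panel.
#' @param eligible Pool for random panels; defaults to all nuclear genes.
#' @param seed Integer seed.
#' @return A `cohort_bias_summary` data.frame: `cohort`, `method`,
#'   `mt_mean`, `mt_cv`, `rho_mt_nu`, `rho_mt_random`, `rho_random_random`,
#'   `n_samples`.
#' @export
bias_curves <- function(cm, metadata, mt_set, nu_set,
                        methods = c("TPM", "CPM_EXCL", "UQ", "MRN", "TMM"),
                        design = design_spec(), n_panels = 20L,
                        rr_panel_size = 100L, eligible = NULL, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(methods) == 0) stop("method list must not be empty")
  methods <- match.arg(methods, c("TPM", "FPKM", "CPM_EXCL", "UQ", "MRN", "TMM"),
                       several.ok = TRUE)
  md <- metadata[match(colnames(cm$counts), metadata$sample_id), ]
  if (length(unique(md$cohort)) < 2)
    stop("bias curves need at least 2 cohorts")
  mt_set <- resolve_set(mt_set, cm); nu_set <- resolve_set(nu_set, cm)
  if (is.null(eligible))
    eligible <- cm$genes$gene_id[cm$genes$origin == "nuclear"]
  eligible <- resolve_set(eligible, cm)
  frac <- mt_fraction(cm, mt_set)

  rows <- list()
  for (ch in unique(md$cohort)) {
    sel <- md$sample_id[md$cohort == ch]
    sub <- cm[, sel]
    f <- frac[sel]
    for (method in methods) {
      nm <- normalize_counts(sub, method)
      rm_ <- regress_out(nm, md[md$cohort == ch, ], design, scope = "per_cohort")
      ranks <- t(apply(rm_$residuals, 1, rank))
      keep <- apply(rm_$residuals, 1, function(x) length(unique(x)) >= 2)
      C <- matrix(NA_real_, nrow(ranks), nrow(ranks),
                  dimnames = list(rownames(ranks), rownames(ranks)))
      C[keep, keep] <- stats::cor(t(ranks[keep, , drop = FALSE]))
      rho_mt_nu <- between_set_median(C, mt_set, nu_set)
      set.seed(stage_seed(seed, paste0("panels_", ch, "_", method)))
      pool_mt <- setdiff(eligible, mt_set)
      mtr <- vapply(seq_len(n_panels), function(i) {
        panel <- sample(pool_mt, min(length(nu_set), length(pool_mt)))
        between_set_median(C, mt_set, panel)
      }, numeric(1))
      rrr <- vapply(seq_len(n_panels), function(i) {
        panel <- sample(pool_mt, min(rr_panel_size, length(pool_mt)))
        within_set_median(C, panel)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        cohort = ch, method = method, mt_mean = mean(f),
        mt_cv = stats::sd(f) / mean(f), rho_mt_nu = rho_mt_nu,
        rho_mt_random = mean(mtr), rho_random_random = mean(rrr),
        n_samples = length(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_bias_summary", "data.frame")
  out
}

#' @export
print.cohort_bias_summary <- function(x, ...) {
  cat("cohort_bias_summary:\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot composition-bias curves
#'
#' Median correlation against cohort mean mt fraction, one panel per
#' normalization method.
#'
#' @param x A `cohort_bias_summary`.
#' @param outcome Which column to plot (`"rho_mt_nu"`, `"rho_mt_random"` or
#'   `"rho_random_random"`).
#' @param ... Further graphical arguments passed to [graphics::plot()].
#' @export
plot.cohort_bias_summary <- function(x, outcome = "rho_mt_nu", ...) {
  methods <- unique(x$method)
  old <- graphics::par(mfrow = c(1, length(methods)))
  on.exit(graphics::par(old))
  for (m in methods) {
    sub <- x[x$method == m, ]
    graphics::plot(sub$mt_mean, sub[[outcome]], xlab = "mean mt fraction",
                   ylab = outcome, main = m, ylim = c(-1, 1), pch = 19, ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Regression of cohort-level correlation on mt-fraction statistics
#'
#' Fits, for one normalization method, ordinary least squares of the
#' per-cohort median correlation on (a) the cohort mean mt fraction and (b)
#' mean, CV and their interaction, reporting slopes, R-squared, the
#' Spearman rank correlation with the mean, and p values. This mirrors the
#' observation that the artifact strength is predicted by both the level
#' and the spread of the mt fraction.
#'
#' @param summaries A `cohort_bias_summary` (one method) or data.frame with
#'   `mt_mean`, `mt_cv` and the outcome column.
#' @param outcome Outcome column name (default `"rho_mt_nu"`).
#' @return A `bias_regression` list with elements `mean_model` and
#'   `full_model` (each: coefficients, r_squared, p_values), plus
#'   `spearman_rho` and `spearman_p` of outcome vs mean.
#' @export
bias_regression <- function(summaries, outcome = "rho_mt_nu") {
  df <- as.data.frame(summaries)
  if (length(unique(df$method)) > 1)
    stop("bias_regression expects a single method; subset the summary first")
  if (nrow(df) < 4) stop("need at least 4 cohorts")
  y <- df[[outcome]]
  report <- function(fit) {
    sm <- summary(fit)
    co <- sm$coefficients
    aliased <- sm$aliased
    list(coefficients = stats::coef(fit), r_squared = sm$r.squared,
         p_values = stats::setNames(co[, 4], rownames(co)),
         aliased_dropped = names(aliased)[aliased])
  }
  m1 <- stats::lm(y ~ mt_mean, data = df)
  m2 <- stats::lm(y ~ mt_mean * mt_cv, data = df)
  sp <- suppressWarnings(stats::cor.test(df$mt_mean, y, method = "spearman"))
  structure(list(mean_model = report(m1), full_model = report(m2),
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n_cohorts = nrow(df), outcome = outcome),
            class = "bias_regression")
}

#' @export
print.bias_regression <- function(x, ...) {
  cat(sprintf("bias_regression of %s over %d cohorts\n", x$outcome, x$n_cohorts))
  cat(sprintf("  ~ mean:           slope %.3f, R^2 %.3f, p %.3g\n",
              x$mean_model$coefficients[["mt_mean"]], x$mean_model$r_squared,
              x$mean_model$p_values[["mt_mean"]]))
  cat(sprintf("  ~ mean * cv:      R^2 %.3f\n", x$full_model$r_squared))
  cat(sprintf("  Spearman rho vs mean: %.3f (p %.3g)\n",
              x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Per-sample signature score
#'
#' Mean over the signature genes of the per-gene standardized (z-scored
#' across samples), variance-stabilized expression. The default transform
#' `log2(x + 1)` is a variance-stabilizing approximation appropriate for
#' normalized pseudocounts; genes with zero variance are excluded and
#' counted. A proliferation signature scored this way gives a
#' proliferative-index-style ranking of samples.
#'
#' @param normalized A `normalized_matrix` (MRN pseudocounts recommended) or
#'   bare matrix.
#' @param signature_set Character vector of gene ids.
#' @param transform `"log2"` (default) or `"none"`.
#' @return A `signature_score`: named numeric vector of per-sample scores
#'   with attributes `signature_size`, `n_excluded`, `transform`.
#' @export
signature_score <- function(normalized, signature_set,
                            transform = c("log2", "none")) {
  transform <- match.arg(transform)
  M <- if (inherits(normalized, "normalized_matrix")) normalized$values else
    as.matrix(normalized)
  sig <- intersect(as.character(signature_set), rownames(M))
  if (length(sig) == 0) stop("no signature gene present in the matrix")
  X <- M[sig, , drop = FALSE]
  if (transform == "log2") X <- log2(X + 1)
  v <- apply(X, 1, stats::sd)
  excluded <- sum(v == 0)
  X <- X[v > 0, , drop = FALSE]
  if (nrow(X) == 0) stop("no usable signature gene (all zero variance)")
  Z <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  structure(colMeans(Z), class = "signature_score",
            signature_size = nrow(X), n_excluded = excluded,
            transform = transform)
}

#' Cohort mean expression matrix
#'
#' Mean normalized expression of every gene within each cohort (MRN
#' pseudocounts in the reference workflow), the input to
#' [meta_correlation()].
#'
#' @param normalized A `normalized_matrix` or bare matrix.
#' @param cohorts Character vector of cohort labels per sample.
#' @return Genes x cohorts matrix of means.
#' @export
cohort_mean_expression <- function(normalized, cohorts) {
  M <- if (inherits(normalized, "normalized_matrix")) normalized$values else
    as.matrix(normalized)
  stopifnot(length(cohorts) == ncol(M))
  u <- unique(cohorts)
  out <- vapply(u, function(ch) rowMeans(M[, cohorts == ch, drop = FALSE]),
                numeric(nrow(M)))
  dimnames(out) <- list(rownames(M), u)
  out
}

#' Meta-correlation of gene expression with a cohort-level outcome
#'
#' Correlates (Spearman) each gene's cohort mean expression with a
#' cohort-level outcome — typically the observed per-cohort mt-nuclear
#' coordination — and returns BH-adjusted p values and the ranked top/bottom
#' gene lists. Genes constant across cohorts are dropped and reported.
#' Downstream enrichment of the lists is out of scope here; the lists are
#' emitted as plain id vectors.
#'
#' @param mean_expr Genes x cohorts matrix from [cohort_mean_expression()].
#' @param cohort_outcome Named numeric vector aligned to the cohort columns.
#' @param top_n Size of the top/bottom lists (capped at the gene count with
#'   a warning).
#' @return A `meta_correlation_result`: data.frame (`gene_id`, `rho`,
#'   `p_value`, `fdr`) sorted by `rho`, with attributes `top`, `bottom`,
#'   `n_dropped`.
#' @export
meta_correlation <- function(mean_expr, cohort_outcome, top_n = 1000L) {
  stopifnot(ncol(mean_expr) >= 4)
  if (!is.null(names(cohort_outcome)))
    cohort_outcome <- cohort_outcome[colnames(mean_expr)]
  stopifnot(length(cohort_outcome) == ncol(mean_expr))
  keep <- apply(mean_expr, 1, function(x) length(unique(x)) >= 2)
  n_dropped <- sum(!keep)
  X <- mean_expr[keep, , drop = FALSE]
  tests <- apply(X, 1, function(x)
    suppressWarnings(stats::cor.test(x, cohort_outcome, method = "spearman")))
  rho <- vapply(tests, function(t) unname(t$estimate), numeric(1))
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  out <- data.frame(gene_id = rownames(X), rho = rho, p_value = p,
                    fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out <- out[order(-out$rho), ]
  if (top_n > nrow(out)) {
    warning("top_n larger than gene count; capped at ", nrow(out))
    top_n <- nrow(out)
  }
  structure(out, class = c("meta_correlation_result", "data.frame"),
            top = utils::head(out$gene_id, top_n),
            bottom = rev(utils::tail(out$gene_id, top_n)),
            n_dropped = n_dropped)
}

#' Variance in an outcome explained by predictor expression
#'
#' Simple OLS R-squared and F-test p for a single predictor, or the joint
#' R-squared of a small predictor set (e.g. the five NF-kB subunit genes
#' against per-tissue OXPHOS coordination).
#'
#' @param predictor_expr Numeric vector, or samples x predictors matrix.
#' @param outcome Numeric vector aligned to the samples.
#' @return List with `r_squared`, `p_value`, `n`.
#' @export
variance_explained <- function(predictor_expr, outcome) {
  X <- as.matrix(predictor_expr)
  stopifnot(nrow(X) == length(outcome), nrow(X) >= 4)
  if (any(apply(X, 2, stats::sd) == 0)) stop("zero-variance predictor")
  fit <- stats::lm(outcome ~ X)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = nrow(X))
}
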