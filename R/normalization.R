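#' Normalization methods and the compositional artifact
#'
#' @description
#' Six library normalizations are implemented from their definitions. TPM
#' and FPKM scale by the total read count, which makes every value in a
#' sample depend on every other gene: when a dominant transcript block (for
#' example the mitochondrial genes) varies across samples, all other genes
#' are pushed in the opposite direction, which is the composition artifact
#' this package quantifies. Upper-quartile, median-of-ratios and TMM scaling
#' are insensitive to a minority of highly expressed transcripts.
#'
#' @name normalization
NULL

new_normalized_matrix <- function(values, method, cm, excluded = character(0)) {
  structure(list(values = values, method = method,
                 genes = cm$genes, samples = colnames(values),
                 excluded = excluded),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

check_libraries <- function(cm) {
  tot <- colSums(cm$counts)
  if (any(tot == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[tot == 0], collapse = ", "))
  tot
}

#' FPKM: fragments per kilobase of transcript per million mapped reads
#'
#' `value = count * 1e9 / (length_bp * sample_total_count)`. Column sums are
#' not constant across samples, unlike TPM.
#'
#' @param cm A [count_matrix()].
#' @return A `normalized_matrix` with method tag `"FPKM"`.
#' @export
fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- check_libraries(cm)
  v <- cm$counts * 1e9 / outer(cm$genes$length_bp, tot)
  new_normalized_matrix(v, "FPKM", cm)
}

#' TPM: transcripts per million
#'
#' Computed directly from counts and lengths as length-normalized rates
#' rescaled to sum to 1e6 per sample. This is algebraically identical to
#' rescaling FPKM by the sample FPKM total
#' (`TPM_i = FPKM_i / sum_j FPKM_j * 1e6`), a property asserted in the test
#' suite to 1e-9 relative. Per-sample sums are exactly 1e6, which is what
#' makes TPM zero-sum across genes: a gene's TPM can fall only because other
#' genes' TPM rises.
#'
#' @param cm A [count_matrix()].
#' @return A `normalized_matrix` with method tag `"TPM"`.
#' @export
tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  check_libraries(cm)
  rate <- cm$counts / cm$genes$length_bp
  v <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  new_normalized_matrix(v, "TPM", cm)
}

#' CPM with a gene set excluded from the denominator
#'
#' Counts per million where the scaling total omits an excluded set
#' (typically the mtDNA-encoded genes, or a dominant haemoglobin/protease
#' block): non-excluded genes are scaled by `1e6 / (library total minus the
#' excluded set's counts)`; the excluded genes themselves are scaled by the
#' full library total. No length normalization is applied — for correlation
#' analysis, which never compares genes within a sample, this is equivalent
#' to a length-normalized version.
#'
#' @param cm A [count_matrix()].
#' @param excluded_set Character vector of gene ids to drop from the
#'   denominator. Empty set reduces to plain CPM.
#' @return A `normalized_matrix` with method tag `"CPM_EXCL"`.
#' @export
cpm_excluding <- function(cm, excluded_set) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- check_libraries(cm)
  excluded_set <- resolve_set(excluded_set, cm)
  ei <- rownames(cm$counts) %in% excluded_set
  tot_excl <- tot - colSums(cm$counts[ei, , drop = FALSE])
  if (any(tot_excl == 0))
    stop("exclusion leaves zero remaining counts in sample(s): ",
         paste(colnames(cm$counts)[tot_excl == 0], collapse = ", "))
  v <- cm$counts
  v[!ei, ] <- sweep(v[!ei, , drop = FALSE], 2, tot_excl, `/`) * 1e6
  v[ei, ] <- sweep(v[ei, , drop = FALSE], 2, tot, `/`) * 1e6
  new_normalized_matrix(v, "CPM_EXCL", cm, excluded = excluded_set)
}

new_scaling_factors <- function(factors, lib_size, method, raw = NULL) {
  structure(list(factors = factors, lib_size = lib_size, method = method,
                 raw = raw), class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("scaling_factors (%s) for %d samples\n", x$method,
              length(x$factors)))
  print(utils::head(data.frame(sample = names(x$factors),
                               factor = unname(x$factors),
                               lib_size = unname(x$lib_size)), 6))
  invisible(x)
}

#' Upper-quartile scaling factors
#'
#' The per-sample scale is the 75th percentile (linear-interpolation
#' quantile) of the sample's non-zero counts. Normalization factors are the
#' quartiles relative to library size, rescaled so their geometric mean is 1
#' across samples, matching the convention of mainstream normalization
#' software so that factors are comparable across runs.
#'
#' @param cm A [count_matrix()].
#' @return A `scaling_factors` object; `raw` carries the unscaled quartiles.
#' @export
uq_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- check_libraries(cm)
  uq <- apply(cm$counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) stop("all-zero sample in upper-quartile scaling")
    stats::quantile(nz, 0.75, names = FALSE)  # type = 7, linear interpolation
  })
  f <- uq / lib
  f <- f / exp(mean(log(f)))
  new_scaling_factors(f, lib, "UQ", raw = uq)
}

#' Median-of-ratios (MRN / RLE) scaling factors
#'
#' The reference expression of each gene is its geometric mean across
#' samples, computed over the genes with strictly positive counts in every
#' sample; the sample scale is the median across those genes of the ratio of
#' the sample's count to the reference. Because the median ignores a
#' minority of extreme ratios, a dominant transcript block does not drag the
#' factor with it — the property that makes MRN safe for correlation
#' analysis.
#'
#' @param cm A [count_matrix()].
#' @return A `scaling_factors` object whose `factors` element holds the size
#'   factors (divide counts by these to obtain normalized pseudocounts).
#' @export
mrn_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  pos <- rowSums(cm$counts > 0) == ncol(cm$counts)
  if (!any(pos))
    stop("median-of-ratios undefined: no gene with positive counts in all samples")
  x <- cm$counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(x)))
  # median of ratios taken on the log scale: identical to the plain median
  # for an odd number of reference genes, geometric middle for an even one
  sf <- exp(apply(log(x / ref), 2, stats::median))
  new_scaling_factors(sf, lib, "MRN")
}

#' TMM scaling factors (trimmed mean of M values)
#'
#' Implemented from the algorithm's published description. The reference
#' sample is the one whose upper quartile of depth-normalized non-zero
#' counts is closest to the mean such quartile. For every other sample,
#' per-gene log2 ratios M and log2 abundances A are computed on
#' depth-normalized counts over genes positive in both sample and reference;
#' both tails of M (30%) and of A (5%) are trimmed; the factor is 2 raised
#' to the precision-weighted mean of the surviving M values, with weights
#' the inverse asymptotic binomial variances. Factors are rescaled to
#' geometric mean 1.
#'
#' @param cm A [count_matrix()].
#' @param trim_m,trim_a Tail trim fractions for M and A.
#' @param ref Optional reference sample (id or index); by default the sample
#'   whose non-zero upper quartile of depth-normalized counts is closest to
#'   the mean such quartile.
#' @return A `scaling_factors` object; `raw` records the reference sample.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- check_libraries(cm)
  n_s <- ncol(cm$counts)
  if (is.null(ref)) {
    uq_rel <- apply(cm$counts, 2, function(x) {
      nz <- x[x > 0]
      if (length(nz) == 0) stop("all-zero sample in TMM scaling")
      stats::quantile(nz, 0.75, names = FALSE)
    }) / lib
    ref_i <- which.min(abs(uq_rel - mean(uq_rel)))
  } else {
    ref_i <- if (is.character(ref)) match(ref, colnames(cm$counts)) else as.integer(ref)
    if (is.na(ref_i) || ref_i < 1 || ref_i > n_s) stop("invalid reference sample")
  }

  f <- vapply(seq_len(n_s), function(s) {
    if (s == ref_i) return(1)
    tmm_pair_factor(cm$counts[, s], cm$counts[, ref_i], lib[s], lib[ref_i],
                    trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(cm$counts)
  new_scaling_factors(f, lib, "TMM", raw = list(reference = colnames(cm$counts)[ref_i]))
}

# single-pair TMM: doubly trimmed, precision-weighted mean of M
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]
  n <- length(m)
  if (n == 0 || max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (sum(keep2) < 3)
    stop("TMM: fewer than 3 genes survive trimming")
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  w <- w[fin]
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f) || abs(log2(f)) < 1e-10) f <- 1
  f
}

#' Apply scaling factors to counts
#'
#' For UQ and TMM the normalized value is
#' `count * 1e6 / (library_size * factor)`; for MRN it is the pseudocount
#' `count / size_factor`.
#'
#' @param cm A [count_matrix()].
#' @param factors A `scaling_factors` object from [uq_factors()],
#'   [mrn_factors()] or [tmm_factors()].
#' @return A `normalized_matrix` tagged with the factors' method.
#' @export
apply_scaling <- function(cm, factors) {
  stopifnot(inherits(cm, "count_matrix"), inherits(factors, "scaling_factors"))
  if (!identical(names(factors$factors), colnames(cm$counts)))
    stop("scaling factors do not match the samples of the count matrix")
  v <- if (factors$method == "MRN") {
    sweep(cm$counts, 2, factors$factors, `/`)
  } else {
    sweep(cm$counts, 2, factors$lib_size * factors$factors, `/`) * 1e6
  }
  new_normalized_matrix(v, factors$method, cm)
}

#' Normalize counts by any of the six supported methods
#'
#' Convenience dispatcher used by the diagnostics and the pipeline stages.
#'
#' @param cm A [count_matrix()].
#' @param method One of `"TPM"`, `"FPKM"`, `"CPM_EXCL"`, `"UQ"`, `"MRN"`,
#'   `"TMM"`.
#' @param excluded_set Gene ids for `"CPM_EXCL"` (defaults to the
#'   mitochondrial genes of `cm`).
#' @return A `normalized_matrix`.
#' @export
normalize_counts <- function(cm, method = c("TPM", "FPKM", "CPM_EXCL", "UQ",
                                            "MRN", "TMM"),
                             excluded_set = NULL) {
  method <- match.arg(method)
  switch(method,
         TPM = tpm(cm),
         FPKM = fpkm(cm),
         CPM_EXCL = {
           if (is.null(excluded_set))
             excluded_set <- cm$genes$gene_id[cm$genes$origin == "mitochondrial"]
           cpm_excluding(cm, excluded_set)
         },
         UQ = apply_scaling(cm, uq_factors(cm)),
         MRN = apply_scaling(cm, mrn_factors(cm)),
         TMM = apply_scaling(cm, tmm_factors(cm)))
}

#' Per-sample mitochondrial read fraction
#'
#' The share of each sample's total read count carried by the mitochondrial
#' gene set — the latent quantity whose between-sample variance drives the
#' compositional artifact.
#'
#' @param cm A [count_matrix()].
#' @param mt_set Gene ids to treat as mitochondrial; defaults to the genes
#'   annotated `origin == "mitochondrial"`.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
mt_fraction <- function(cm, mt_set = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(mt_set))
    mt_set <- cm$genes$gene_id[cm$genes$origin == "mitochondrial"]
  mt_set <- resolve_set(mt_set, cm)
  if (length(mt_set) == 0) stop("validation error: empty mitochondrial set")
  tot <- check_libraries(cm)
  colSums(cm$counts[rownames(cm$counts) %in% mt_set, , drop = FALSE]) / tot
}
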