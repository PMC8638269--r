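# Independent brute-force oracles, coded directly from the definitions and
# kept free of any package internals.

# median-of-ratios size factors: geometric-mean reference over genes positive
# in every sample; per-sample factor is the middle ratio (geometric middle
# when the reference gene count is even)
oracle_mrn <- function(counts) {
  keep <- c()
  for (g in seq_len(nrow(counts)))
    if (all(counts[g, ] > 0)) keep <- c(keep, g)
  sf <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ratios <- c()
    for (g in keep) {
      gm <- prod(counts[g, ])^(1 / ncol(counts))
      ratios <- c(ratios, counts[g, s] / gm)
    }
    r <- sort(ratios)
    k <- length(r)
    sf[s] <- if (k %% 2 == 1) r[(k + 1) / 2] else sqrt(r[k / 2] * r[k / 2 + 1])
  }
  names(sf) <- colnames(counts)
  sf
}

# TMM against a given reference column: doubly trimmed (30% of M tails, 5% of
# A tails), precision-weighted mean of per-gene log2 ratios on
# depth-normalized counts, factors rescaled to geometric mean one
oracle_tmm <- function(counts, ref_col) {
  libs <- colSums(counts)
  one_pair <- function(s) {
    if (s == ref_col) return(1)
    f <- c()
    M <- c(); A <- c(); W <- c()
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, s]; r <- counts[g, ref_col]
      if (o > 0 && r > 0) {
        po <- o / libs[s]; pr <- r / libs[ref_col]
        # evaluate the log ratio as one expression so that genes with
        # mathematically equal ratios remain exactly tied in rank
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        W <- c(W, (libs[s] - o) / (libs[s] * o) + (libs[ref_col] - r) / (libs[ref_col] * r))
      }
    }
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    lo_m <- floor(0.3 * n) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(0.05 * n) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(M); ra_ <- rank(A)
    num <- 0; den <- 0
    for (g in seq_len(n)) {
      if (rm_[g] >= lo_m && rm_[g] <= hi_m && ra_[g] >= lo_a && ra_[g] <= hi_a) {
        num <- num + M[g] / W[g]
        den <- den + 1 / W[g]
      }
    }
    2^(num / den)
  }
  f <- vapply(seq_len(ncol(counts)), one_pair, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, using the factorial form of the hypergeometric mass
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  mass <- function(x) {
    # P(table with top-left = x) under fixed margins
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, mass, numeric(1))
  p_obs <- mass(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small count_matrix builder for toy cases
toy_cm <- function(counts, lengths = NULL, origin = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  if (is.null(origin)) origin <- rep("nuclear", nrow(counts))
  count_matrix(counts, lengths = lengths, origin = origin)
}

# ids used by the simulator's gene panel
sim_mt_ids <- function() sprintf("MT-%02d", 1:13)
sim_nu_ids <- function() sprintf("NUOX-%03d", 1:126)
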