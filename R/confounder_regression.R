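#' Midpoint of an age bracket
#'
#' Donor ages in GTEx-style metadata are released as decade brackets
#' (`"50-59"`); the bracket midpoint is used as a numeric covariate.
#'
#' @param bracket Character string `"lo-hi"`.
#' @return Numeric midpoint `(lo + hi) / 2`.
#' @export
age_midpoint <- function(bracket) {
  m <- regmatches(bracket, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", bracket))[[1]]
  if (length(m) != 3)
    stop("parse error: age bracket must look like 'lo-hi', got '", bracket, "'")
  (as.numeric(m[2]) + as.numeric(m[3])) / 2
}

#' Specify a confounder design
#'
#' @param covariates Character vector of metadata column names to adjust
#'   for. The `age_bracket` column is parsed to numeric bracket midpoints
#'   automatically; character/factor columns enter as categorical,
#'   numeric columns as numeric.
#' @param interact_with_cohort Covariates whose effect is allowed to differ
#'   by cohort (combined scope only).
#' @param blocks Categorical blocking factors added in combined scope
#'   (typically `donor_id` and `batch`).
#' @return A `design_spec` list.
#' @export
design_spec <- function(covariates = character(0),
                        interact_with_cohort = covariates,
                        blocks = character(0)) {
  structure(list(covariates = covariates,
                 interact_with_cohort = intersect(interact_with_cohort, covariates),
                 blocks = blocks),
            class = "design_spec")
}

# covariate columns -> numeric design columns (no intercept)
design_columns <- function(metadata, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (!cv %in% names(metadata))
      stop("design covariate not in metadata: ", cv)
    x <- metadata[[cv]]
    if (cv == "age_bracket")
      x <- vapply(as.character(x), age_midpoint, numeric(1))
    if (is.numeric(x)) {
      cols[[cv]] <- matrix(x, ncol = 1, dimnames = list(NULL, cv))
    } else {
      x <- factor(x)
      if (nlevels(x) > 1) {
        mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(x)[-1])
        cols[[cv]] <- mm
      }
    }
  }
  if (length(cols) == 0) return(matrix(numeric(0), nrow(metadata), 0))
  do.call(cbind, cols)
}

# greedy rank-preserving column selection: first occurrence kept
drop_aliased <- function(X, tol = 1e-9) {
  if (ncol(X) == 0) return(list(X = X, dropped = character(0)))
  keep <- logical(ncol(X))
  q <- NULL
  r <- 0
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(which(keep), j), drop = FALSE]
    if (qr(cand, tol = tol)$rank > r) {
      keep[j] <- TRUE
      r <- r + 1
    }
  }
  list(X = X[, keep, drop = FALSE], dropped = colnames(X)[!keep])
}

#' Regress known confounders out of normalized expression
#'
#' Fits, for every gene, an ordinary-least-squares model of normalized
#' expression on the design covariates and returns the residual matrix used
#' by the correlation engine. In `per_cohort` scope an independent model is
#' fitted within each cohort; in `combined` scope one model is fitted across
#' all samples with covariate-by-cohort interactions plus the categorical
#' blocking factors (donor, batch). Aliased design columns are dropped
#' deterministically (first occurrence kept) and reported.
#'
#' Residuals are computed on the normalized values in their natural scale;
#' the downstream statistics are rank-based, so any within-cohort monotone
#' rescaling is immaterial.
#'
#' @param normalized A `normalized_matrix` (or bare genes-by-samples
#'   matrix).
#' @param metadata Sample metadata data.frame with a `cohort` column and one
#'   row per sample, aligned by `sample_id`.
#' @param design A [design_spec()].
#' @param scope `"per_cohort"` or `"combined"`.
#' @return A `residual_matrix`: list with `residuals` (genes x samples),
#'   `cohorts` (named vector), `dropped_columns`, `r_squared` (per gene)
#'   and `scope`.
#' @export
regress_out <- function(normalized, metadata,
                        design = design_spec(), scope = c("per_cohort", "combined")) {
  scope <- match.arg(scope)
  Y <- if (inherits(normalized, "normalized_matrix")) normalized$values else
    as.matrix(normalized)
  if (!all(colnames(Y) %in% metadata$sample_id))
    stop("metadata missing rows for some samples")
  metadata <- metadata[match(colnames(Y), metadata$sample_id), ]
  cohorts <- stats::setNames(as.character(metadata$cohort), metadata$sample_id)

  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  dropped <- character(0)
  ss_tot <- numeric(nrow(Y)); ss_res <- numeric(nrow(Y))

  fit_block <- function(Ysub, Xsub) {
    X <- cbind(`(Intercept)` = 1, Xsub)
    da <- drop_aliased(X)
    if (ncol(da$X) >= ncol(Ysub))
      stop("more parameters (", ncol(da$X), ") than samples (", ncol(Ysub),
           ") after design expansion; reduce the design")
    qrX <- qr(da$X)
    list(res = t(qr.resid(qrX, t(Ysub))), dropped = da$dropped)
  }

  if (scope == "per_cohort") {
    for (ch in unique(cohorts)) {
      sel <- which(cohorts == ch)
      X <- design_columns(metadata[sel, , drop = FALSE], design$covariates)
      fb <- fit_block(Y[, sel, drop = FALSE], X)
      res[, sel] <- fb$res
      if (length(fb$dropped) > 0)
        dropped <- c(dropped, paste0(ch, ":", fb$dropped))
      ss_res <- ss_res + rowSums(fb$res^2)
      ss_tot <- ss_tot + rowSums(sweep(Y[, sel, drop = FALSE], 1,
                                       rowMeans(Y[, sel, drop = FALSE]))^2)
    }
  } else {
    X <- design_columns(metadata, design$covariates)
    coh <- factor(cohorts)
    parts <- list()
    if (nlevels(coh) > 1) {
      cm_ <- stats::model.matrix(~coh)[, -1, drop = FALSE]
      colnames(cm_) <- paste0("cohort", levels(coh)[-1])
      parts$cohort <- cm_
    }
    if (ncol(X) > 0) {
      parts$main <- X
      inter_cols <- design_columns(metadata, design$interact_with_cohort)
      if (ncol(inter_cols) > 0 && nlevels(coh) > 1) {
        icols <- lapply(levels(coh)[-1], function(l) {
          m <- inter_cols * (coh == l)
          colnames(m) <- paste0(colnames(inter_cols), ":cohort", l)
          m
        })
        parts$inter <- do.call(cbind, icols)
      }
    }
    for (b in design$blocks) {
      bm <- design_columns(metadata, b)
      parts[[paste0("block_", b)]] <- bm
    }
    Xfull <- if (length(parts)) do.call(cbind, parts) else
      matrix(numeric(0), nrow(metadata), 0)
    fb <- fit_block(Y, Xfull)
    res[, ] <- fb$res
    dropped <- fb$dropped
    ss_res <- rowSums(fb$res^2)
    ss_tot <- rowSums(sweep(Y, 1, rowMeans(Y))^2)
  }

  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  structure(list(residuals = res, cohorts = cohorts,
                 dropped_columns = dropped,
                 r_squared = stats::setNames(r2, rownames(Y)),
                 scope = scope, design = design),
            class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix (%s scope): %d genes x %d samples, %d cohort(s)\n",
              x$scope, nrow(x$residuals), ncol(x$residuals),
              length(unique(x$cohorts))))
  if (length(x$dropped_columns) > 0)
    cat("  aliased columns dropped:", length(x$dropped_columns), "\n")
  invisible(x)
}
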