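#' Construct a validated count matrix
#'
#' The central container of the package: a gene-by-sample matrix of raw
#' (non-negative integer) read counts together with the per-gene annotation
#' needed for rate normalization (transcript length) and for the
#' mitochondrial/nuclear split that drives the composition-bias analyses.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param lengths Numeric vector of transcript lengths in base pairs, one per
#'   gene (named or in row order). All values must be >= 1.
#' @param origin Character vector, `"mitochondrial"` or `"nuclear"`, one per
#'   gene.
#' @param symbols Optional character vector of display symbols; defaults to
#'   the gene ids.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `genes` (data.frame with `gene_id`, `symbol`,
#'   `length_bp`, `origin`) and `samples` (character vector).
#' @export
count_matrix <- function(counts, lengths, origin, symbols = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("validation error: duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("validation error: duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts))
    stop("format error: counts must be numeric")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("format error: negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (any(!is.finite(counts)))
    stop("format error: non-finite count entries")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("format error: counts must be integers")
  storage.mode(counts) <- "double"  # double storage avoids int overflow in sums

  lengths <- as.numeric(align_gene_vector(lengths, rownames(counts), "lengths"))
  names(lengths) <- rownames(counts)
  if (any(lengths < 1)) stop("validation error: all lengths must be >= 1")
  origin <- align_gene_vector(origin, rownames(counts), "origin")
  if (!all(origin %in% c("mitochondrial", "nuclear")))
    stop("validation error: origin must be 'mitochondrial' or 'nuclear'")
  if (is.null(symbols)) symbols <- rownames(counts)
  symbols <- align_gene_vector(symbols, rownames(counts), "symbols")

  structure(list(
    counts = counts,
    genes = data.frame(gene_id = rownames(counts), symbol = unname(symbols),
                       length_bp = unname(lengths), origin = unname(origin),
                       stringsAsFactors = FALSE),
    samples = colnames(counts)
  ), class = "count_matrix")
}

align_gene_vector <- function(x, ids, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(ids, names(x))
    if (length(miss) > 0)
      stop("validation error: ", what, " missing for genes: ",
           paste(utils::head(miss, 5), collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop("validation error: ", what, " has length ", length(x),
         " but there are ", length(ids), " genes")
  }
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  n_mt <- sum(x$genes$origin == "mitochondrial")
  cat(sprintf("count_matrix: %d genes (%d mitochondrial) x %d samples\n",
              nrow(x$counts), n_mt, length(x$samples)))
  cat(sprintf("  total counts: %.3g (median library %.3g)\n",
              sum(x$counts), stats::median(colSums(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x A `count_matrix`.
#' @param i Gene ids or indices (optional).
#' @param j Sample ids or indices (optional).
#' @param ... Ignored.
#' @return A `count_matrix` restricted to the requested genes/samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cm <- x$counts[i, j, drop = FALSE]
  gi <- match(rownames(cm), x$genes$gene_id)
  count_matrix(cm,
               lengths = x$genes$length_bp[gi],
               origin = x$genes$origin[gi],
               symbols = x$genes$symbol[gi])
}

#' Read a count matrix from disk
#'
#' Supports the tab-separated dialect common to GTEx/TCGA-style dumps (first
#' column `gene_id`, header row of sample ids) and MatrixMarket triplet files
#' with sidecar row/column name files (`<stem>.rownames.txt`,
#' `<stem>.colnames.txt`, one id per line).
#'
#' @param path Path to the counts TSV or `.mtx` file.
#' @param annotation_path Path to an annotation TSV with columns `gene_id`,
#'   `symbol`, `length_bp`, `origin`.
#' @return A validated [count_matrix()]. Genes in the counts file that are
#'   absent from the annotation abort the read with a named list.
#' @export
read_counts <- function(path, annotation_path) {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "length_bp", "origin")
  if (!all(need %in% names(ann)))
    stop("format error: annotation must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("validation error: duplicate gene_id in annotation")

  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rownames.txt"))
    colnames(m) <- readLines(paste0(stem, ".colnames.txt"))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1] != "gene_id")
      stop("format error: first column of counts TSV must be 'gene_id'")
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("format error: non-numeric count entries")
    rownames(m) <- tab$gene_id
  }

  unknown <- setdiff(rownames(m), ann$gene_id)
  if (length(unknown) > 0)
    stop("validation error: genes absent from annotation: ",
         paste(unknown, collapse = ", "))
  ai <- match(rownames(m), ann$gene_id)
  count_matrix(m, lengths = ann$length_bp[ai], origin = ann$origin[ai],
               symbols = ann$symbol[ai])
}

#' Write a count matrix to disk
#'
#' @param cm A `count_matrix`.
#' @param path Output path; `.mtx` suffix selects MatrixMarket triplet output
#'   with sidecar name files, anything else the TSV dialect of
#'   [read_counts()].
#' @param annotation_path Optional path for the companion annotation TSV.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(cm, path, annotation_path = NULL) {
  paths <- path
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(cm$counts), paste0(stem, ".rownames.txt"))
    writeLines(colnames(cm$counts), paste0(stem, ".colnames.txt"))
    paths <- c(path, paste0(stem, ".rownames.txt"), paste0(stem, ".colnames.txt"))
  } else {
    tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(annotation_path)) {
    utils::write.table(cm$genes, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, annotation_path)
  }
  invisible(paths)
}

#' Read gene sets from GMT or plain-text files
#'
#' GMT lines are `name<TAB>description<TAB>id1<TAB>id2...`; a plain file (one
#' id per line) becomes a single set named after the file stem. Duplicate ids
#' within a set are dropped with a warning count; empty sets are an error.
#'
#' @param path File path.
#' @param annotation Optional `count_matrix` or character vector of known gene
#'   ids; ids not found there are kept in the catalogue but flagged in
#'   `unresolved` so they can be excluded from computation.
#' @return A `gene_set_catalog`: list of character vectors with attributes
#'   `unresolved` and `n_duplicates`.
#' @export
read_gene_sets <- function(path, annotation = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("validation error: empty gene-set file")
  is_gmt <- any(grepl("\t", lines))
  if (is_gmt) {
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop("format error: GMT line with fewer than 3 fields")
      stats::setNames(list(f[-(1:2)]), f[1])
    })
    sets <- do.call(c, sets)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(lines), nm)
  }
  gene_set_catalog(sets, annotation = annotation)
}

#' Construct a gene-set catalogue
#'
#' @param sets Named list of character vectors of gene ids.
#' @inheritParams read_gene_sets
#' @return A `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, annotation = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("validation error: all gene sets must be named")
  n_dup <- 0L
  sets <- lapply(sets, function(s) {
    s <- as.character(s)
    d <- sum(duplicated(s))
    if (d > 0) n_dup <<- n_dup + d
    unique(s)
  })
  if (n_dup > 0)
    warning(sprintf("%d duplicate gene id(s) removed from gene sets", n_dup))
  if (any(lengths(sets) == 0))
    stop("validation error: empty gene set: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  known <- NULL
  if (inherits(annotation, "count_matrix")) known <- annotation$genes$gene_id
  else if (is.character(annotation)) known <- annotation
  unresolved <- if (is.null(known)) character(0) else
    unique(unlist(lapply(sets, setdiff, y = known)))
  structure(sets, class = "gene_set_catalog",
            unresolved = unresolved, n_duplicates = n_dup)
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("gene_set_catalog with", length(x), "set(s):\n")
  for (nm in names(x)) cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  unres <- attr(x, "unresolved")
  if (length(unres) > 0)
    cat("  unresolved against annotation:", length(unres), "id(s)\n")
  invisible(x)
}

#' Resolve a gene set against a count matrix
#'
#' Unresolvable ids are retained in the catalogue for reporting but excluded
#' from computation; this helper returns the computable subset.
#'
#' @param set Character vector of gene ids (or a catalogue element).
#' @param cm A `count_matrix`.
#' @return Character vector of ids present in `cm`.
#' @export
resolve_set <- function(set, cm) intersect(as.character(set), cm$genes$gene_id)

#' Analysis configuration
#'
#' Bundles the resampling and filtering parameters used across the pipeline so
#' that every output can record them alongside the RNG seed.
#'
#' @param normalization One of `"TPM"`, `"FPKM"`, `"CPM_EXCL"`, `"UQ"`,
#'   `"MRN"`, `"TMM"`.
#' @param subsample_k Samples drawn per cohort in the combined analysis.
#' @param iterations Number of subsampling iterations (the median over these
#'   is reported).
#' @param bootstrap_reps Bootstrap resamples for within-cohort inference.
#' @param null_panel_size Genes per random panel in the random-gene null.
#' @param null_iterations Number of random panels.
#' @param expression_threshold Median-TPM cutoff defining "expressed" genes.
#' @param fdr_level Significance level applied to BH-adjusted p values.
#' @param seed Integer seed from which all stage seeds are derived.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(normalization = "MRN", subsample_k = 100L,
                            iterations = 100L, bootstrap_reps = 1000L,
                            null_panel_size = 126L, null_iterations = 100L,
                            expression_threshold = 5, fdr_level = 0.05,
                            seed = 1L) {
  stopifnot(normalization %in% c("TPM", "FPKM", "CPM_EXCL", "UQ", "MRN", "TMM"),
            subsample_k >= 1, iterations >= 1, bootstrap_reps >= 1,
            null_panel_size >= 1, null_iterations >= 1, fdr_level > 0,
            fdr_level < 1)
  structure(list(normalization = normalization,
                 subsample_k = as.integer(subsample_k),
                 iterations = as.integer(iterations),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 null_panel_size = as.integer(null_panel_size),
                 null_iterations = as.integer(null_iterations),
                 expression_threshold = expression_threshold,
                 fdr_level = fdr_level, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Derive a stage-specific seed from the master seed
#'
#' All randomness flows from one master seed through named substreams, one
#' per pipeline stage, so that re-running a single stage reproduces exactly
#' the stream it saw in the full run.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"bootstrap"`).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Write result tables and a run summary
#'
#' Every data.frame (or coercible result object) in `results` becomes a TSV in
#' `out_dir`; a `run_summary.json` records the configuration, seed and a
#' config hash so outputs are auditable and re-runs with the same seed and
#' configuration are byte-identical.
#'
#' @param results Named list of result objects (data.frames or objects with
#'   an `as.data.frame` method). May be empty.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @return Invisibly, a data.frame manifest of files written.
#' @export
write_tables <- function(results, out_dir, config = analysis_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(format(df, digits = 15, trim = TRUE), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- unclass(config)
  hash <- sum(utf8ToInt(paste(names(cfg), unlist(cfg), collapse = ";",
                              sep = "=")) * 31^(seq_along(utf8ToInt(paste(
                                names(cfg), unlist(cfg), collapse = ";",
                                sep = "=")))%% 7)) %% 2147483647
  summary_file <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(config = cfg, seed = cfg$seed,
                            config_hash = hash,
                            n_tables = length(files),
                            r_version = paste(R.version$major, R.version$minor,
                                              sep = ".")),
                       summary_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(data.frame(file = c(files, summary_file),
                       kind = c(rep("table", length(files)), "summary"),
                       stringsAsFactors = FALSE))
}
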