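#' Per-cell quality-control statistics
#'
#' Computes, for every cell, the number of detected genes, total UMIs, the
#' percentage of counts on mitochondrial genes and the percentage of counts
#' falling in the cell's 500 highest-count genes (a library-complexity
#' statistic; `min(500, n_genes)` features are used).
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param mito_genes character vector of mitochondrial gene symbols; defaults
#'   to symbols starting with `mt-` (mouse) or `MT-` (human). Misses against
#'   the gene universe produce a warning.
#' @param top_n number of top features for the complexity statistic.
#' @return data.frame (one row per cell): `n_genes`, `n_umis`, `pct_mito`,
#'   `pct_top500`, `zero_count` flag. Zero-count cells get 0 for the
#'   percentage fields and are flagged.
#' @export
compute_cell_qc <- function(counts, mito_genes = NULL, top_n = 500) {
  x <- as.matrix(counts)
  if (is.null(mito_genes)) {
    mito_genes <- grep("^(mt-|MT-)", rownames(x), value = TRUE)
  } else {
    miss <- setdiff(mito_genes, rownames(x))
    if (length(miss))
      warning(length(miss), " mito genes absent from the gene universe")
    mito_genes <- intersect(mito_genes, rownames(x))
  }
  n_umis <- colSums(x)
  n_genes <- colSums(x > 0)
  mito <- if (length(mito_genes)) colSums(x[mito_genes, , drop = FALSE]) else 0
  top <- apply(x, 2, function(v) {
    k <- min(top_n, sum(v > 0))
    if (k == 0) return(0)
    sum(sort(v, decreasing = TRUE)[seq_len(k)])
  })
  zero <- n_umis == 0
  qc <- data.frame(
    n_genes = n_genes, n_umis = n_umis,
    pct_mito = ifelse(zero, 0, 100 * mito / pmax(n_umis, 1)),
    pct_top500 = ifelse(zero, 0, 100 * top / pmax(n_umis, 1)),
    zero_count = zero)
  rownames(qc) <- colnames(x)
  qc
}

#' Sequential cell filtering
#'
#' Applies the QC removal rules in order: (1) cells above the mitochondrial
#' maximum, (2) cells missing a required covariate (e.g. no cell-cycle
#' information), (3) cells with feature counts above the upper percentile,
#' (4) cells below the lower percentile. Percentile cutoffs are computed on
#' the cells surviving the earlier rules (type-7 empirical quantiles);
#' removal is strict (`>` / `<`), so ties at the cutoff are kept.
#'
#' @param qc data.frame from [compute_cell_qc()].
#' @param mito_max maximum mitochondrial percentage (default 5).
#' @param upper_pct,lower_pct feature-count percentiles (defaults 99 and 1).
#' @param has_covariates optional logical vector (TRUE = covariates present).
#' @param thresholds optional list with `hi` and `lo` absolute feature-count
#'   cutoffs from a previous run; when supplied the percentile estimation is
#'   skipped, making the filter a fixed (idempotent) rule.
#' @return list: `keep` (logical mask), `log` (data.frame rule / removed)
#'   and `thresholds` (the absolute cutoffs used).
#' @export
filter_cells <- function(qc, mito_max = 5, upper_pct = 99, lower_pct = 1,
                         has_covariates = NULL, thresholds = NULL) {
  if (nrow(qc) == 0) stop("empty input: no cells to filter")
  keep <- rep(TRUE, nrow(qc))
  log <- data.frame(rule = character(), removed = integer())
  note <- function(rule, removed)
    rbind(log, data.frame(rule = rule, removed = removed))

  drop <- keep & qc$pct_mito > mito_max
  keep <- keep & !drop
  log <- note("pct_mito", sum(drop))

  if (!is.null(has_covariates)) {
    drop <- keep & !has_covariates
    keep <- keep & !drop
  } else drop <- rep(FALSE, nrow(qc))
  log <- note("missing_covariates", sum(drop))

  hi <- if (is.null(thresholds))
    stats::quantile(qc$n_genes[keep], upper_pct / 100, type = 7)
  else thresholds$hi
  drop <- keep & qc$n_genes > hi
  keep <- keep & !drop
  log <- note("upper_percentile", sum(drop))

  lo <- if (is.null(thresholds))
    stats::quantile(qc$n_genes[keep], lower_pct / 100, type = 7)
  else thresholds$lo
  drop <- keep & qc$n_genes < lo
  keep <- keep & !drop
  log <- note("lower_percentile", sum(drop))

  list(keep = keep, log = log, thresholds = list(hi = unname(hi),
                                                 lo = unname(lo)))
}

#' Gene detection filter
#'
#' @param counts genes x cells matrix.
#' @param min_cells gene kept iff nonzero in at least this many cells
#'   (default 10).
#' @return logical keep mask over genes.
#' @export
filter_genes <- function(counts, min_cells = 10) {
  stopifnot(min_cells >= 1)
  if (methods::is(counts, "sparseMatrix")) {
    Matrix::rowSums(counts > 0) >= min_cells
  } else {
    rowSums(counts > 0) >= min_cells
  }
}

#' Demultiplex hashtag-oligo counts
#'
#' Centered log-ratio (CLR) normalization per cell (log(count + 1) minus the
#' mean log(count + 1) across tags), k-means clustering of the CLR profiles
#' with k = number of tags, and per-tag thresholding: the background cluster
#' for a tag is the cluster with the lowest mean CLR for that tag, and a cell
#' is positive for the tag iff its CLR exceeds the `positive_quantile`
#' empirical quantile of that background cluster. Cells positive for zero
#' tags are `negative`, for one tag singlets (named by tag), for two or more
#' `doublet`.
#'
#' @param hto_counts tags x cells count matrix.
#' @param positive_quantile background quantile cutoff (default 0.999).
#' @param seed k-means seed (default 42).
#' @param max_retries re-initializations allowed on a degenerate (empty
#'   cluster) k-means solution.
#' @return list: `call` (character per cell), `clr` (tags x cells matrix),
#'   `n_positive` (integer per cell).
#' @export
demux_hto <- function(hto_counts, positive_quantile = 0.999, seed = 42,
                      max_retries = 5) {
  x <- as.matrix(hto_counts)
  if (nrow(x) < 2) stop("need at least 2 HTO tags")
  lg <- log1p(x)
  clr <- sweep(lg, 2, colMeans(lg), "-")
  set.seed(seed)
  km <- NULL
  for (r in seq_len(max_retries)) {
    km <- tryCatch(stats::kmeans(t(clr), centers = nrow(x), nstart = 10),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", nrow(x),
                        " nonempty clusters")
  pos <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  for (tg in seq_len(nrow(x))) {
    cl_means <- tapply(clr[tg, ], km$cluster, mean)
    bg <- as.integer(names(which.min(cl_means)))
    thr <- stats::quantile(clr[tg, km$cluster == bg], positive_quantile,
                           type = 7)
    pos[tg, ] <- clr[tg, ] > thr
  }
  npos <- colSums(pos)
  call <- rep("negative", ncol(x))
  call[npos >= 2] <- "doublet"
  one <- npos == 1
  call[one] <- rownames(x)[apply(pos[, one, drop = FALSE], 2, which.max)]
  names(call) <- colnames(x)
  list(call = call, clr = clr, n_positive = npos)
}
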