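#' Pipeline configuration with published defaults
#'
#' Collects every tunable threshold of the pipeline in one flat list. The
#' defaults are the values used throughout the original neutrophil continuum
#' analysis: QC cuts (5% mitochondrial maximum, 1st/99th feature percentiles,
#' genes in >= 10 cells), the residual-variance cutoff of 1.3 for highly
#' variable genes, 50 computed / 20 used principal components, signature
#' thresholds (Moran's I >= 0.2, mean expression >= 0.1, Spearman rho cut at
#' +/-0.2 with the stable band \[-0.1, 0.1\]), adaptive-bin minima (5 per
#' tissue, 30 total, sweep step 1e-5), k = 10 gene clusters with 10 Lloyd
#' iterations, a Fisher background of 20,000 genes, top-50 TF selection, and
#' the hashtag demultiplexing settings (positive quantile 0.999, seed 42).
#'
#' @param ... name = value overrides for any default listed above.
#' @return A named list of class `nt_config`.
#' @examples
#' cfg <- nt_config(hvg_cutoff = 1.5)
#' cfg$hvg_cutoff
#' @export
nt_config <- function(...) {
  cfg <- list(
    # cell / gene QC
    mito_max        = 5,     # % mitochondrial UMIs above which a cell is removed
    upper_pct       = 99,    # feature-count percentile above which cells are removed
    lower_pct       = 1,     # feature-count percentile below which cells are removed
    gene_min_cells  = 10,    # gene kept iff nonzero in >= this many cells
    # HTO demultiplexing
    positive_quantile = 0.999,
    demux_seed        = 42,
    # normalization
    scale_factor    = 1e4,   # counts-per-cell target before log1p
    # HVG / dimensionality reduction
    hvg_cutoff      = 1.3,
    n_pcs_total     = 50,
    n_pcs_use       = 20,
    n_dc            = 10,
    k_local         = NULL,  # local kernel bandwidth neighbour; NULL = min(100, n/10)
    # signature thresholds
    moran_min       = 0.2,
    mean_expr_min   = 0.1,
    rho_pos         = 0.2,
    rho_neg         = -0.2,
    rho_stable      = 0.1,
    knn_k           = 15,
    # adaptive binning
    bin_step        = 1e-5,
    min_per_tissue  = 5,
    min_total       = 30,
    # gene dynamics
    kmeans_k        = 10,
    kmeans_iter     = 10,
    # module score
    score_bins      = 25,
    score_ctrl      = 100,
    # TF enrichment
    fisher_background = 20000,
    top_n_tf          = 50,
    # cell-cycle pairs
    pair_q          = 0.7,
    pair_max        = 50,
    # classifier
    prior_epsilon   = 1e-10,
    # dip test
    dip_boot        = 2000,
    # root selection
    root_quantile   = 0.99,
    seed            = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "nt_config")
}

#' Write / read a flat key-value configuration file
#'
#' Serializes an `nt_config` to a two-column TSV (`key<TAB>value`). `NULL`
#' entries are written as the empty string and read back as `NULL`.
#'
#' @param config an `nt_config` list.
#' @param path file path.
#' @return `read_run_config` returns an `nt_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "nt_config"))
  vals <- vapply(config, function(v) if (is.null(v)) "" else as.character(v), "")
  utils::write.table(data.frame(key = names(config), value = vals),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  defaults <- nt_config()
  out <- defaults
  for (i in seq_len(nrow(tab))) {
    key <- tab$key[i]; val <- tab$value[i]
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    if (identical(val, "")) { out[key] <- list(NULL); next }
    proto <- defaults[[key]]
    out[[key]] <- if (is.numeric(proto) || is.null(proto)) as.numeric(val) else val
  }
  out$seed <- as.integer(out$seed)
  structure(out, class = "nt_config")
}
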