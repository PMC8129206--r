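#' Fit the maturation continuum ("neutrotime") to a count matrix
#'
#' The central model fit of the package. Starting from a QC-filtered genes x
#' cells UMI count matrix it (1) log-normalizes, (2) selects highly variable
#' genes by residual variance after technical-covariate regression,
#' (3) computes 50 principal components, (4) forms the 1 - Pearson
#' correlation distance over the first 20 components, (5) builds a
#' density-normalized diffusion map, (6) anchors pseudotime at a root
#' (precursor) cell set via diffusion distance and rescales it to `[0, 1]`,
#' and (7) extracts the continuum gene signature (per-gene Spearman
#' correlation with pseudotime, Moran's I over a kNN graph of the diffusion
#' coordinates, mean expression, and the positive / negative / stable class
#' labels feeding the closed-form continuum score).
#'
#' @param counts genes x cells non-negative integer matrix (already
#'   cell- and gene-filtered; see [compute_cell_qc()], [filter_cells()],
#'   [filter_genes()]).
#' @param tissue optional per-cell tissue/condition labels (used by `plot`).
#' @param root_cells explicit character vector of root cell names; if
#'   `NULL`, roots are the top quantile of `preneu_score`.
#' @param preneu_score optional named per-cell precursor score (e.g. a
#'   [module_score()] over precursor marker genes).
#' @param covariates optional data.frame of per-cell technical covariates
#'   (`n_umis`, `s_minus_g2m`, `pct_mito`); computed from the counts when
#'   missing (with `s_minus_g2m = 0`).
#' @param config an [nt_config()]; every threshold of the fit lives there.
#' @param pseudotime_method `"diffusion_distance"` (default; diffusion
#'   distance to the root centroid) or `"dc1_rank"` (rank along the first
#'   diffusion component, oriented away from the root).
#' @return An object of class `neutrotime`: list with `neutrotime`,
#'   `pseudotime_raw`, `root_cells`, `signature` (data.frame), `hvg`,
#'   `pca`, `dm` (diffusion coordinates + eigenvalues), `tissue`,
#'   `mean_expr`, `config`, `n_cells`, `n_genes`.
#' @seealso [predict.neutrotime()], [plot.neutrotime()], [neutrotime_s()]
#' @export
neutrotime <- function(counts, tissue = NULL, root_cells = NULL,
                       preneu_score = NULL, covariates = NULL,
                       config = nt_config(),
                       pseudotime_method = c("diffusion_distance",
                                             "dc1_rank")) {
  pseudotime_method <- match.arg(pseudotime_method)
  x <- as.matrix(counts)
  if (is.null(colnames(x))) colnames(x) <- paste0("cell_", seq_len(ncol(x)))
  expr <- lognormalize(x, config$scale_factor)

  if (is.null(covariates)) {
    qc <- compute_cell_qc(x)
    covariates <- data.frame(n_umis = qc$n_umis, s_minus_g2m = 0,
                             pct_mito = qc$pct_mito)
  }
  hvg <- select_hvg(x, covariates, cutoff = config$hvg_cutoff)
  sel <- rownames(hvg)[hvg$selected]
  need <- config$n_pcs_use + 1
  if (length(sel) < need) {
    warning("only ", length(sel), " genes above the residual-variance ",
            "cutoff; using the top ", need, " genes instead")
    sel <- rownames(hvg)[order(hvg$residual_variance,
                               decreasing = TRUE)][seq_len(need)]
  }

  pca <- run_pca(expr[sel, , drop = FALSE], config$n_pcs_total)
  pc_use <- pca$coords[, seq_len(min(config$n_pcs_use, ncol(pca$coords))),
                       drop = FALSE]
  D <- correlation_distance(pc_use)
  dm <- diffusion_map(D, n_dc = config$n_dc, k_local = config$k_local)

  if (is.null(root_cells))
    root_cells <- select_root(preneu_score, quantile = config$root_quantile)
  pt <- if (pseudotime_method == "diffusion_distance") {
    pseudotime_from_root(dm$coords, dm$eigenvalues, root_cells)
  } else {
    dc1 <- dm$coords[, 1]
    idx <- match(root_cells, rownames(dm$coords))
    if (anyNA(idx)) stop("unknown root cell(s)")
    if (mean(dc1[idx]) > stats::median(dc1)) dc1 <- -dc1
    raw <- rank(dc1)
    nt <- (raw - min(raw)) / (max(raw) - min(raw))
    list(pseudotime_raw = stats::setNames(raw, rownames(dm$coords)),
         neutrotime = stats::setNames(nt, rownames(dm$coords)))
  }

  rho <- gene_time_correlation(expr, pt$neutrotime)
  graph <- knn_graph(dm$coords, k = min(config$knn_k, ncol(x) - 1))
  mi <- morans_i(expr, graph)
  mean_expr <- rowMeans(expr)
  signature <- tryCatch(
    select_signature_genes(
      stats::setNames(rho$rho, rownames(rho)), mi$moran_i, mean_expr,
      moran_min = config$moran_min, mean_expr_min = config$mean_expr_min,
      rho_pos = config$rho_pos, rho_neg = config$rho_neg,
      rho_stable = config$rho_stable),
    error = function(e) {
      warning("signature unavailable: ", conditionMessage(e))
      NULL
    })

  structure(list(
    neutrotime = pt$neutrotime, pseudotime_raw = pt$pseudotime_raw,
    root_cells = root_cells, signature = signature, hvg = hvg,
    pca = pca, dm = dm, tissue = tissue, mean_expr = mean_expr,
    moran = mi, rho = stats::setNames(rho$rho, rownames(rho)),
    config = config, n_cells = ncol(x), n_genes = nrow(x),
    pseudotime_method = pseudotime_method), class = "neutrotime")
}

#' @rdname neutrotime
#' @param x,object a `neutrotime` fit.
#' @param ... unused.
#' @method print neutrotime
#' @export
print.neutrotime <- function(x, ...) {
  cat("Maturation continuum fit (neutrotime)\n")
  cat(sprintf("  %d cells x %d genes; %d highly variable genes\n",
              x$n_cells, x$n_genes, sum(x$hvg$selected)))
  cat(sprintf("  root set: %d cells; pseudotime method: %s\n",
              length(x$root_cells), x$pseudotime_method))
  if (!is.null(x$signature)) {
    tb <- table(x$signature$class)
    cat(sprintf("  signature: %d positive / %d negative / %d stable genes\n",
                tb["positive"], tb["negative"], tb["stable"]))
  } else cat("  signature: unavailable\n")
  invisible(x)
}

#' @rdname neutrotime
#' @method summary neutrotime
#' @export
summary.neutrotime <- function(object, ...) {
  out <- list(
    n_cells = object$n_cells, n_genes = object$n_genes,
    n_hvg = sum(object$hvg$selected),
    n_root = length(object$root_cells),
    eigenvalues = object$dm$eigenvalues,
    root_mean_neutrotime = mean(object$neutrotime[object$root_cells]),
    signature_counts = if (!is.null(object$signature))
      table(object$signature$class) else NULL,
    tissue_counts = if (!is.null(object$tissue)) table(object$tissue) else NULL)
  class(out) <- "summary.neutrotime"
  out
}

#' @method print summary.neutrotime
#' @export
print.summary.neutrotime <- function(x, ...) {
  cat("neutrotime fit summary\n")
  cat(sprintf("  cells: %d   genes: %d   HVGs: %d\n",
              x$n_cells, x$n_genes, x$n_hvg))
  cat(sprintf("  root cells: %d (mean neutrotime %.3f)\n",
              x$n_root, x$root_mean_neutrotime))
  cat("  leading diffusion eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n")
  if (!is.null(x$signature_counts)) {
    cat("  signature classes:\n")
    print(x$signature_counts)
  }
  invisible(x)
}

#' Extract the continuum gene signature from a fit
#'
#' @param object a `neutrotime` fit.
#' @param ... unused.
#' @return The signature data.frame (gene, rho, moran_i, mean_expr, class).
#' @method coef neutrotime
#' @export
coef.neutrotime <- function(object, ...) object$signature

#' @rdname neutrotime
#' @method fitted neutrotime
#' @export
fitted.neutrotime <- function(object, ...) object$neutrotime

#' Project new expression data onto the fitted continuum
#'
#' Computes the closed-form continuum score (neutrotime-S) of new samples
#' from the fitted gene signature: log-normalized expression for single
#' cells, raw counts for bulk samples (with optional ortholog mapping).
#'
#' @param object a `neutrotime` fit with a non-NULL signature.
#' @param newdata genes x samples matrix: log-normalized expression
#'   (`type = "cells"`) or raw bulk counts (`type = "bulk"`).
#' @param type `"cells"` or `"bulk"`.
#' @param ortholog optional named vector mapping `newdata` symbols to
#'   signature symbols (bulk only).
#' @param ... unused.
#' @return named numeric vector of per-sample scores.
#' @export
predict.neutrotime <- function(object, newdata, type = c("cells", "bulk"),
                               ortholog = NULL, ...) {
  type <- match.arg(type)
  if (is.null(object$signature)) stop("fit has no gene signature")
  if (type == "cells") {
    neutrotime_s(newdata, object$signature)
  } else {
    project_bulk(newdata, object$signature, ortholog = ortholog)$score
  }
}

#' Plot cell density along the fitted continuum
#'
#' Kernel density of cells along neutrotime, one curve per tissue label.
#'
#' @param x a `neutrotime` fit (needs `tissue` labels; a single pooled curve
#'   is drawn otherwise).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.neutrotime <- function(x, ...) {
  labels <- if (is.null(x$tissue)) rep("all", x$n_cells) else x$tissue
  d <- density_along_pseudotime(x$neutrotime, labels)
  graphics::matplot(d$grid, t(d$density), type = "l", lty = 1,
                    xlab = "neutrotime", ylab = "relative cell density", ...)
  graphics::legend("top", legend = rownames(d$density),
                   col = seq_len(nrow(d$density)), lty = 1, bty = "n")
  invisible(x)
}
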