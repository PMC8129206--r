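#' Spearman correlation of each gene with pseudotime
#'
#' Ranks use average ties; zero-variance genes get rho = 0 and are flagged.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param neutrotime per-cell pseudotime.
#' @return data.frame per gene: `rho`, `flagged` (zero variance).
#' @export
gene_time_correlation <- function(expr, neutrotime) {
  e <- as.matrix(expr)
  stopifnot(ncol(e) == length(neutrotime))
  rt <- rank(neutrotime)
  re <- t(apply(e, 1, rank))
  flat <- apply(e, 1, function(r) stats::var(r) == 0)
  rho <- suppressWarnings(as.vector(stats::cor(t(re), rt)))
  rho[flat] <- 0
  data.frame(rho = rho, flagged = flat, row.names = rownames(e))
}

#' k-nearest-neighbour graph from an embedding
#'
#' Binary, directed kNN adjacency (no self edges) from Euclidean distances
#' in the supplied coordinates (diffusion components or principal
#' components).
#'
#' @param coords cells x d coordinate matrix.
#' @param k neighbours per cell (default 15).
#' @return sparse cells x cells adjacency matrix (`w_ij = 1` iff j is one of
#'   i's k nearest neighbours).
#' @export
knn_graph <- function(coords, k = 15) {
  m <- as.matrix(coords)
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of cells")
  d2 <- as.matrix(stats::dist(m))^2
  diag(d2) <- Inf
  idx <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(idx)), x = 1,
                              dims = c(n, n),
                              dimnames = list(rownames(m), rownames(m)))
  adj
}

#' Moran's I spatial autocorrelation per gene
#'
#' `I = (N/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `W = sum_ij w_ij`, computed for every gene over a cell-cell
#' neighbour graph. Zero-variance genes get I = 0 and are flagged; isolated
#' nodes trigger a warning.
#'
#' @param expr genes x cells expression matrix.
#' @param graph cells x cells (sparse) weight matrix, e.g. [knn_graph()].
#' @return data.frame per gene: `moran_i`, `flagged`.
#' @export
morans_i <- function(expr, graph) {
  e <- as.matrix(expr)
  w <- graph
  stopifnot(ncol(e) == nrow(w))
  if (any(Matrix::rowSums(w) + Matrix::colSums(w) == 0))
    warning("graph contains isolated nodes")
  n <- ncol(e)
  W <- sum(w)
  z <- e - rowMeans(e)
  num <- rowSums(as.matrix(z %*% w) * z)
  den <- rowSums(z^2)
  flat <- den == 0
  i <- (n / W) * num / den
  i[flat] <- 0
  data.frame(moran_i = i, flagged = flat, row.names = rownames(e))
}

#' Select the continuum gene signature
#'
#' Eligibility requires Moran's I >= `moran_min` and mean expression >=
#' `mean_expr_min`; eligible genes are then classed by their Spearman
#' correlation with pseudotime: `rho >= rho_pos` = positive (N+),
#' `rho <= rho_neg` = negative (N-), `|rho| <= rho_stable` = stable (N0);
#' everything else (including the 0.1-0.2 gap) is unused.
#'
#' @param rho per-gene Spearman correlation (named or aligned vectors).
#' @param moran_i per-gene Moran's I.
#' @param mean_expr per-gene mean log-normalized expression.
#' @param moran_min,mean_expr_min,rho_pos,rho_neg,rho_stable thresholds
#'   (defaults 0.2, 0.1, 0.2, -0.2, 0.1).
#' @return data.frame per gene: `rho`, `moran_i`, `mean_expr`, `class` in
#'   `positive` / `negative` / `stable` / `unused`. Errors if any of the
#'   three classes is empty (the continuum score is then undefined).
#' @export
select_signature_genes <- function(rho, moran_i, mean_expr,
                                   moran_min = 0.2, mean_expr_min = 0.1,
                                   rho_pos = 0.2, rho_neg = -0.2,
                                   rho_stable = 0.1) {
  stopifnot(length(rho) == length(moran_i), length(rho) == length(mean_expr))
  eligible <- moran_i >= moran_min & mean_expr >= mean_expr_min
  cls <- rep("unused", length(rho))
  cls[eligible & rho >= rho_pos] <- "positive"
  cls[eligible & rho <= rho_neg] <- "negative"
  cls[eligible & abs(rho) <= rho_stable] <- "stable"
  for (c in c("positive", "negative", "stable"))
    if (!any(cls == c))
      stop("signature class '", c, "' is empty; continuum score undefined")
  data.frame(rho = rho, moran_i = moran_i, mean_expr = mean_expr,
             class = cls, row.names = names(rho))
}

#' Continuum score from gene expression (neutrotime-S)
#'
#' For each sample (cell or bulk sample):
#' `score = (sum_{g in N+} e(g) - sum_{g in N-} e(g)) / sum_{g in N0} e(g)`.
#' Use log-normalized expression for single cells and raw counts for bulk.
#' Signature genes missing from the expression matrix are dropped with a
#' warning; a non-positive denominator yields `NA` (flagged).
#'
#' @param expr genes x samples expression matrix.
#' @param signature data.frame from [select_signature_genes()] (rownames =
#'   genes, column `class`).
#' @return named numeric vector of per-sample scores.
#' @export
neutrotime_s <- function(expr, signature) {
  e <- as.matrix(expr)
  sets <- split(rownames(signature), signature$class)
  pick <- function(cl) {
    g <- sets[[cl]]
    miss <- setdiff(g, rownames(e))
    if (length(miss))
      warning(length(miss), " ", cl, " signature gene(s) missing; dropped")
    found <- intersect(g, rownames(e))
    if (!length(found))
      stop("no ", cl, " signature gene present in the expression matrix")
    found
  }
  np <- pick("positive"); nn <- pick("negative"); n0 <- pick("stable")
  num <- colSums(e[np, , drop = FALSE]) - colSums(e[nn, , drop = FALSE])
  den <- colSums(e[n0, , drop = FALSE])
  bad <- den <= 0
  if (any(bad)) warning(sum(bad), " sample(s) with non-positive denominator")
  score <- num / den
  score[bad] <- NA_real_
  score
}

#' Expression-matched gene module score
#'
#' Tirosh-style score: genes are binned into `n_bins` by average expression;
#' for every gene of the set, `n_ctrl` control genes are sampled (with
#' replacement) from its bin; the score of a cell is the mean expression of
#' the set minus the mean expression of the pooled controls.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param gene_set character vector; intersected with the gene universe
#'   (warning below 2 genes, score still defined).
#' @param n_bins expression bins (default 25).
#' @param n_ctrl control genes per set gene (default 100).
#' @param seed sampling seed.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  e <- as.matrix(expr)
  set <- intersect(gene_set, rownames(e))
  if (!length(set)) stop("gene set has no overlap with the gene universe")
  if (length(set) < 2) warning("gene set has fewer than 2 genes after intersection")
  avg <- rowMeans(e)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(e)
  set.seed(seed)
  ctrl <- unlist(lapply(set, function(g) {
    pool <- names(bins)[bins == bins[g]]
    sample(pool, n_ctrl, replace = TRUE)
  }))
  colMeans(e[set, , drop = FALSE]) - colMeans(e[ctrl, , drop = FALSE])
}

#' Project bulk samples onto the continuum score
#'
#' Applies [neutrotime_s()] with raw counts after mapping bulk gene symbols
#' through an optional ortholog table. Errors when fewer than half of the
#' signature genes are found.
#'
#' @param bulk_counts genes x samples raw count matrix.
#' @param signature data.frame from [select_signature_genes()].
#' @param ortholog optional named vector (bulk symbol -> signature symbol).
#' @param groups optional per-sample group labels; group means reported.
#' @return list: `score` (per sample), `group_means` (or NULL).
#' @export
project_bulk <- function(bulk_counts, signature, ortholog = NULL,
                         groups = NULL) {
  b <- as.matrix(bulk_counts)
  if (!is.null(ortholog)) {
    hit <- rownames(b) %in% names(ortholog)
    b <- b[hit, , drop = FALSE]
    rownames(b) <- unname(ortholog[rownames(b)])
    b <- rowsum(b, group = rownames(b), reorder = FALSE)
  }
  sig_genes <- rownames(signature)[signature$class != "unused"]
  found <- mean(sig_genes %in% rownames(b))
  if (found < 0.5)
    stop("only ", round(100 * found), "% of signature genes found in bulk data")
  score <- suppressWarnings(neutrotime_s(b, signature))
  gm <- NULL
  if (!is.null(groups)) gm <- tapply(score, groups, mean, na.rm = TRUE)
  list(score = score, group_means = gm)
}

#' Adaptive binning of cells along pseudotime
#'
#' Sweeps the pseudotime axis left to right, growing the current bin in
#' increments of `step` until it contains at least `min_per_tissue` cells of
#' every (sufficiently populated) tissue and at least `min_total` cells,
#' then closes it. A final bin that cannot satisfy the minima is merged
#' backward into its predecessor. Tissues with fewer than `min_per_tissue`
#' cells overall are excluded from the per-tissue constraint with a warning.
#'
#' @param neutrotime per-cell pseudotime in `[0, 1]`.
#' @param tissue per-cell tissue label.
#' @param step sweep increment (default 1e-5); intended to be smaller than
#'   the smallest positive gap between adjacent pseudotime values (a
#'   warning is raised otherwise and nearer cells enter the same
#'   increment).
#' @param min_per_tissue,min_total bin minima (defaults 5 and 30).
#' @param expr optional genes x cells log-normalized matrix; per-bin
#'   per-tissue mean expression is then computed.
#' @return list: `bin` (integer per cell), `table` (per-bin boundaries and
#'   counts), `mean_expr` (list bin -> tissue x genes matrix, or NULL).
#' @export
adaptive_bins <- function(neutrotime, tissue, step = 1e-5,
                          min_per_tissue = 5, min_total = 30, expr = NULL) {
  stopifnot(length(neutrotime) == length(tissue))
  nt <- neutrotime
  gaps <- diff(sort(unique(nt)))
  if (length(gaps) && step >= min(gaps))
    warning("step is not smaller than the smallest pseudotime gap (",
            format(min(gaps)), "); cells closer than one step enter the ",
            "same increment")
  tissue <- as.character(tissue)
  tt <- table(tissue)
  constrained <- names(tt)[tt >= min_per_tissue]
  if (length(constrained) < length(tt))
    warning("tissue(s) excluded from the per-tissue constraint: ",
            paste(setdiff(names(tt), constrained), collapse = ", "))
  ord <- order(nt)
  bin <- integer(length(nt))
  b <- 1L
  members <- integer(0)
  for (i in ord) {
    members <- c(members, i)
    cnt <- table(factor(tissue[members], levels = constrained))
    if (length(members) >= min_total && all(cnt >= min_per_tissue)) {
      bin[members] <- b
      b <- b + 1L
      members <- integer(0)
    }
  }
  if (length(members)) {
    # tail that cannot satisfy the minima: merge backward
    bin[members] <- max(1L, b - 1L)
  }
  nb <- max(bin)
  # bin boundaries snapped to the sweep grid
  upper <- vapply(seq_len(nb), function(k) {
    ceiling(max(nt[bin == k]) / step) * step
  }, numeric(1))
  tab <- data.frame(bin = seq_len(nb),
                    upper = upper,
                    n_total = as.vector(table(factor(bin, levels = seq_len(nb)))))
  for (ti in constrained)
    tab[[paste0("n_", ti)]] <- vapply(seq_len(nb), function(k)
      sum(bin == k & tissue == ti), integer(1))
  me <- NULL
  if (!is.null(expr)) {
    e <- as.matrix(expr)
    me <- lapply(seq_len(nb), function(k) {
      sel <- bin == k
      t(vapply(constrained, function(ti) {
        rowMeans(e[, sel & tissue == ti, drop = FALSE])
      }, numeric(nrow(e))))
    })
  }
  list(bin = bin, table = tab, mean_expr = me)
}

#' Cluster gene dynamics along pseudotime
#'
#' Genes (rows, each min-max scaled to `[0, 1]`) are clustered with Lloyd's
#' k-means over cells ordered by pseudotime, mirroring the published
#' settings (k = 10, ten iterations).
#'
#' @param expr genes x cells expression matrix with cells ordered by
#'   pseudotime.
#' @param k number of clusters (default 10); must not exceed the gene count.
#' @param n_iter Lloyd iterations (default 10).
#' @param seed seed for the initial centers.
#' @param centers optional explicit initial centers (k x cells matrix).
#' @return list: `cluster` (named per gene), `sizes`, `centers` (k x cells
#'   mean trends), `withinss_total`.
#' @export
kmeans_gene_dynamics <- function(expr, k = 10, n_iter = 10, seed = 1L,
                                 centers = NULL) {
  e <- as.matrix(expr)
  if (k > nrow(e)) stop("k exceeds the number of genes")
  rng <- apply(e, 1, function(r) diff(range(r)))
  rng[rng == 0] <- 1
  z <- (e - apply(e, 1, min)) / rng
  set.seed(seed)
  if (is.null(centers)) centers <- z[sample(nrow(z), k), , drop = FALSE]
  km <- suppressWarnings(
    stats::kmeans(z, centers = centers, iter.max = n_iter,
                  algorithm = "Lloyd"))
  list(cluster = stats::setNames(km$cluster, rownames(e)),
       sizes = km$size, centers = km$centers,
       withinss_total = km$tot.withinss)
}

#' Smooth per-gene expression trends along pseudotime
#'
#' Penalized regression splines (GAM with GCV-selected smoothness, standard
#' settings) of expression on pseudotime, evaluated on a fixed grid.
#'
#' @param expr genes x cells expression matrix.
#' @param neutrotime per-cell pseudotime.
#' @param grid_n grid resolution over `[0, 1]` (default 100).
#' @return list: `grid`, `fitted` (genes x grid matrix).
#' @export
smooth_gene_trend <- function(expr, neutrotime, grid_n = 100) {
  e <- as.matrix(expr)
  if (ncol(e) < 30) stop("need at least 30 cells")
  grid <- seq(0, 1, length.out = grid_n)
  fitted <- t(apply(e, 1, function(y) {
    if (stats::var(y) == 0) return(rep(y[1], grid_n))
    dat <- data.frame(y = y, t = neutrotime)
    fit <- mgcv::gam(y ~ s(t), data = dat)
    as.vector(stats::predict(fit, newdata = data.frame(t = grid)))
  }))
  rownames(fitted) <- rownames(e)
  list(grid = grid, fitted = fitted)
}
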