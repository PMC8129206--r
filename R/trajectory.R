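#' Log-normalize UMI counts
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`
#' (natural log). 10,000 is the de facto scale of the droplet toolchain.
#'
#' @param counts genes x cells count matrix.
#' @param scale_factor per-cell target sum (default 1e4).
#' @return dense genes x cells matrix of log-normalized expression.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  x <- as.matrix(counts)
  tot <- colSums(x)
  tot[tot == 0] <- 1
  log1p(sweep(x, 2, scale_factor / tot, "*"))
}

#' Select highly variable genes by residual variance
#'
#' Per gene, regresses log1p counts on the technical covariates (number of
#' UMIs, S-minus-G2M cell-cycle score, mitochondrial percentage) by ordinary
#' least squares, estimates a per-gene negative-binomial overdispersion from
#' the count-scale residuals by method of moments, and computes the variance
#' of the Pearson-scaled residuals. A gene is selected iff this residual
#' variance exceeds `cutoff` (default 1.3): genes whose variation is
#' explained by the covariates sit near (or below) 1, genes with real
#' biological structure rise above it.
#'
#' @param counts genes x cells count matrix.
#' @param covariates data.frame with columns among `n_umis`, `s_minus_g2m`,
#'   `pct_mito` (any subset; all finite).
#' @param cutoff residual-variance cutoff (default 1.3).
#' @return data.frame per gene: `residual_variance`, `selected`. Genes with
#'   zero variance get residual variance 0 and are never selected.
#' @export
select_hvg <- function(counts, covariates, cutoff = 1.3) {
  x <- as.matrix(counts)
  cov <- as.matrix(covariates)
  if (!all(is.finite(cov))) stop("covariates must be finite")
  # scale covariates for numerical stability; log the UMI count
  if ("n_umis" %in% colnames(cov)) cov[, "n_umis"] <- log(cov[, "n_umis"] + 1)
  X <- cbind(intercept = 1, scale(cov))
  X[is.na(X)] <- 0  # constant covariate columns
  y <- t(log1p(x))                       # cells x genes
  qrX <- qr(X)
  fit <- qr.fitted(qrX, y)               # cells x genes fitted log1p values
  mu <- expm1(fit)
  mu[mu < 1e-8] <- 1e-8
  # back-transforming log-scale fits underestimates count-scale means
  # (Jensen); rescale each gene so its fitted means average to the observed
  # mean count
  gmean <- rowMeans(x)
  mu <- sweep(mu, 2, gmean / pmax(colMeans(mu), 1e-8), "*")
  mu[mu < 1e-8] <- 1e-8
  raw <- t(x) - mu                       # count-scale residuals
  # method-of-moments NB dispersion per gene: var = mu + phi mu^2. A
  # per-gene estimate would absorb the biological variance and flatten
  # every residual to ~1, so the technical overdispersion is pooled as a
  # robust lower quantile of the per-gene estimates.
  phi <- pmax(0, colSums(raw^2 - mu) / colSums(mu^2))
  phi_tech <- stats::quantile(phi[rowMeans(x) > 0], 0.25, type = 7,
                              na.rm = TRUE)
  pearson <- raw / sqrt(mu + phi_tech * mu^2)
  rv <- apply(pearson, 2, stats::var)
  gene_var <- apply(x, 1, stats::var)
  rv[gene_var == 0] <- 0
  data.frame(residual_variance = rv, selected = rv > cutoff,
             row.names = rownames(x))
}

#' Principal component analysis of the expression matrix
#'
#' Genes are centred and unit-scaled before the decomposition. Component
#' signs are fixed so that each component's largest-absolute-loading gene
#' has a positive loading, making the result deterministic.
#'
#' @param expr genes x cells expression matrix (typically HVG-restricted
#'   log-normalized values).
#' @param n_components number of components (default 50); reduced with a
#'   warning when fewer cells (or genes) are available.
#' @return list: `coords` (cells x components), `sdev`, `loadings`
#'   (genes x components), `var_explained`.
#' @export
run_pca <- function(expr, n_components = 50) {
  e <- as.matrix(expr)
  v <- apply(e, 1, stats::var)
  e <- e[v > 0, , drop = FALSE]
  z <- t(scale(t(e)))  # gene-wise center + unit scale
  maxc <- min(ncol(e) - 1, nrow(e))
  if (n_components > maxc) {
    warning("reducing n_components from ", n_components, " to ", maxc)
    n_components <- maxc
  }
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                    flip, "*")
  list(coords = coords, sdev = pc$sdev[seq_len(n_components)],
       loadings = loadings,
       var_explained = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2))
}

#' Correlation distance between cells
#'
#' `D_ij = 1 - Pearson(pc_i, pc_j)` over the per-cell coordinate vectors
#' (the first 20 principal components in the standard pipeline). Cells with
#' a zero-variance coordinate vector get the maximal distance 2 to all other
#' cells (flagged via attribute) and 0 on the diagonal.
#'
#' @param coords cells x d coordinate matrix.
#' @return symmetric cells x cells distance matrix in `[0, 2]` with zero
#'   diagonal; attribute `flagged` holds indices of degenerate cells.
#' @export
correlation_distance <- function(coords) {
  m <- as.matrix(coords)
  sds <- apply(m, 1, stats::sd)
  flat <- which(sds == 0)
  D <- 1 - stats::cor(t(m))
  if (length(flat)) {
    D[flat, ] <- 2
    D[, flat] <- 2
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2
  attr(D, "flagged") <- flat
  D
}

#' Density-normalized diffusion map
#'
#' Builds a Gaussian kernel with per-cell local bandwidth (the distance to
#' the `k_local`-th neighbour), applies alpha = 1 density normalization
#' (dividing the kernel by the product of its row sums) so the embedding is
#' insensitive to sampling density, forms the symmetric normalized operator
#' and returns its leading eigenpairs with the trivial constant eigenvector
#' removed.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param n_dc number of diffusion components to keep (default 10).
#' @param k_local neighbour rank used for the local bandwidth; default
#'   `min(100, n/10)` (at least 2).
#' @return list: `coords` (cells x n_dc diffusion components), `eigenvalues`
#'   (decreasing, all <= 1).
#' @export
diffusion_map <- function(D, n_dc = 10, k_local = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal")
  if (is.null(k_local)) k_local <- max(2, min(100, floor(n / 10)))
  sigma <- apply(D, 1, function(r) sort(r)[k_local + 1])  # skip self
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  K <- exp(-D^2 / outer(sigma, sigma))
  # connectivity check on the thresholded kernel graph
  comp <- graph_components(K > 1e-12)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("kernel graph is disconnected (component sizes: ",
         paste(sizes, collapse = ", "), ")")
  }
  q <- rowSums(K)
  W <- K / outer(q, q)        # alpha = 1 density normalization
  d <- rowSums(W)
  A <- W / sqrt(outer(d, d))  # symmetric normalized operator
  eig <- eigen(A, symmetric = TRUE)
  keep <- seq(2, min(n_dc + 1, n))  # drop trivial constant eigenvector
  phi <- eig$vectors[, keep, drop = FALSE] / sqrt(d)
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  rownames(phi) <- rownames(D)
  colnames(phi) <- paste0("DC", seq_along(keep))
  list(coords = phi, eigenvalues = eig$values[keep])
}

# connected components of a logical adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Select trajectory root cells
#'
#' Roots are either an explicit cell list or the cells above a quantile of a
#' precursor (preNeu) score — by default the top 1%.
#'
#' @param preneu_score named numeric vector of per-cell precursor scores.
#' @param cells optional explicit character vector of root cell names
#'   (passed through unchanged).
#' @param quantile score quantile above which cells are roots (default 0.99);
#'   0 selects every cell (degenerate, warned).
#' @return character vector of root cell names.
#' @export
select_root <- function(preneu_score = NULL, cells = NULL, quantile = 0.99) {
  if (!is.null(cells)) {
    if (!length(cells)) stop("empty root set")
    return(cells)
  }
  if (is.null(preneu_score)) stop("need a preNeu score or an explicit cell list")
  if (quantile <= 0) warning("quantile <= 0 selects every cell")
  thr <- stats::quantile(preneu_score, quantile, type = 7)
  roots <- names(preneu_score)[preneu_score >= thr]
  if (!length(roots)) stop("empty root set")
  roots
}

#' Root-anchored pseudotime from a diffusion map
#'
#' Raw pseudotime is the diffusion distance to the root-cell centroid:
#' Euclidean distance in the space of diffusion components scaled by
#' `lambda_k / (1 - lambda_k)`. It is then rescaled to `[0, 1]`
#' ("neutrotime"), anchored at the root.
#'
#' @param dm_coords cells x k diffusion components.
#' @param eigenvalues their eigenvalues.
#' @param root_cells character vector (or indices) of root cells.
#' @return list: `pseudotime_raw`, `neutrotime` (both named per cell).
#' @export
pseudotime_from_root <- function(dm_coords, eigenvalues, root_cells) {
  phi <- as.matrix(dm_coords)
  if (!length(root_cells)) stop("root set is empty")
  w <- eigenvalues / (1 - eigenvalues)
  w[!is.finite(w) | w < 0] <- max(w[is.finite(w) & w > 0], 1)
  scaled <- sweep(phi, 2, w, "*")
  idx <- if (is.character(root_cells)) match(root_cells, rownames(phi)) else root_cells
  if (anyNA(idx)) stop("unknown root cell(s)")
  centroid <- colMeans(scaled[idx, , drop = FALSE])
  raw <- sqrt(colSums((t(scaled) - centroid)^2))
  rng <- range(raw)
  if (rng[2] <= rng[1]) stop("degenerate embedding: pseudotime range is zero")
  nt <- (raw - rng[1]) / (rng[2] - rng[1])
  names(raw) <- names(nt) <- rownames(phi)
  list(pseudotime_raw = raw, neutrotime = nt)
}

#' Principal curve through a point cloud
#'
#' Hastie-Stuetzle iteration: the arclength parameter is initialized on the
#' first coordinate, then the algorithm alternates between smoothing each
#' coordinate against arclength (cubic smoothing spline with fixed effective
#' degrees of freedom) and projecting every point onto the resulting
#' polyline, re-parameterizing by arclength. Iteration stops when the mean
#' squared change of the fitted points falls below `tol`.
#'
#' @param coords cells x d coordinate matrix (d >= 2).
#' @param max_iter maximum iterations (default 30); non-convergence returns
#'   the last iterate with a warning.
#' @param tol convergence tolerance on mean squared projection change.
#' @param df effective degrees of freedom of the coordinate smoother.
#' @param orient_by optional numeric vector; the arclength sign is flipped
#'   so its correlation with this vector is positive.
#' @return list: `arclength` (named per cell), `converged`, `n_iter`.
#' @export
principal_curve <- function(coords, max_iter = 30, tol = 1e-4, df = 5,
                            orient_by = NULL) {
  xm <- as.matrix(coords)
  if (ncol(xm) < 2) stop("need at least 2 dimensions")
  n <- nrow(xm)
  lambda <- xm[, 1]
  fitted_old <- xm
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ord <- order(lambda)
    # smooth each coordinate against the current parameter
    fitted <- vapply(seq_len(ncol(xm)), function(j) {
      sp <- stats::smooth.spline(lambda, xm[, j], df = df)
      stats::predict(sp, lambda)$y
    }, numeric(n))
    curve <- fitted[ord, , drop = FALSE]
    # project points onto the polyline through the ordered fitted points
    proj <- project_to_polyline(xm, curve)
    lambda <- proj$arclength
    delta <- mean((fitted - fitted_old)^2)
    fitted_old <- fitted
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("principal curve did not converge in ", max_iter,
                          " iterations")
  if (!is.null(orient_by) &&
      stats::cor(lambda, orient_by, method = "spearman") < 0)
    lambda <- max(lambda) - lambda
  names(lambda) <- rownames(xm)
  list(arclength = lambda, converged = converged, n_iter = it)
}

# orthogonal projection of points onto a polyline; returns arclength of the
# projection foot per point
project_to_polyline <- function(points, vertices) {
  nv <- nrow(vertices)
  seg <- diff(vertices)                      # (nv-1) x d
  seg_len2 <- rowSums(seg^2)
  seg_len2[seg_len2 == 0] <- 1e-12
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))  # arclength at each vertex
  n <- nrow(points)
  arc <- numeric(n)
  for (i in seq_len(n)) {
    dp <- sweep(vertices[-nv, , drop = FALSE], 2, points[i, ], "-")
    tpar <- pmin(1, pmax(0, -rowSums(dp * seg) / seg_len2))
    foot <- vertices[-nv, , drop = FALSE] + seg * tpar
    d2 <- rowSums(sweep(foot, 2, points[i, ], "-")^2)
    j <- which.min(d2)
    arc[i] <- cum[j] + tpar[j] * sqrt(seg_len2[j])
  }
  list(arclength = arc)
}

#' Hartigan's dip test of unimodality
#'
#' The dip statistic is the minimum over unimodal (convex-then-concave)
#' distribution functions of the sup-distance to the empirical CDF, computed
#' by a band formulation: for each candidate modal atom the greatest convex
#' minorant (left) and least concave majorant (right) of the empirical-CDF
#' band are monotonized and their worst violation halved. The p-value is
#' Monte Carlo: the fraction of uniform(0,1) samples of the same size whose
#' dip is at least the observed one.
#'
#' @param values numeric vector (>= 4 finite values; fewer, or all-identical
#'   values, give dip 0 and p 1).
#' @param n_boot Monte-Carlo replicates (default 2000).
#' @param seed integer seed for the replicates.
#' @return list: `dip`, `p_value`, `n`.
#' @export
dip_test <- function(values, n_boot = 2000, seed = 1L) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4 || length(unique(x)) == 1)
    return(list(dip = 0, p_value = 1, n = n))
  obs <- dip_stat(x)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)),
                  numeric(1))
  p <- (1 + sum(boots >= obs)) / (n_boot + 1)
  list(dip = obs, p_value = p, n = n)
}

#' Dip statistic
#'
#' @rdname dip_test
#' @export
dip_stat <- function(values) {
  x <- sort(values[is.finite(values)])
  u <- unique(x)
  if (length(u) == 1) return(0)
  cnt <- cumsum(tabulate(match(x, u), nbins = length(u))) / length(x)
  dip_stat_cpp(u, cnt)
}

#' Kernel density of cells along pseudotime per label
#'
#' Gaussian kernel density on `[0, 1]` per label, renormalized (trapezoid
#' rule) to integrate to 1 over the unit interval.
#'
#' @param neutrotime per-cell pseudotime in `[0, 1]`.
#' @param labels per-cell label (tissue); labels with fewer than 2 cells are
#'   skipped with a warning.
#' @param bandwidth kernel bandwidth; default `stats::bw.nrd0` per label.
#' @param n_grid grid resolution (default 512).
#' @return list: `grid`, `density` (labels x grid matrix).
#' @export
density_along_pseudotime <- function(neutrotime, labels, bandwidth = NULL,
                                     n_grid = 512) {
  stopifnot(length(neutrotime) == length(labels))
  grid <- seq(0, 1, length.out = n_grid)
  labs <- unique(as.character(labels))
  dens <- matrix(NA_real_, length(labs), n_grid,
                 dimnames = list(labs, NULL))
  for (l in labs) {
    v <- neutrotime[labels == l]
    if (length(v) < 2) {
      warning("label ", l, " has fewer than 2 cells; skipped")
      next
    }
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(v) else bandwidth
    d <- stats::density(v, bw = bw, from = 0, to = 1, n = n_grid)
    area <- sum((d$y[-1] + d$y[-n_grid]) / 2) * (grid[2] - grid[1])
    dens[l, ] <- d$y / area
  }
  list(grid = grid, density = dens)
}
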