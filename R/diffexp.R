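# rank-sum test for one gene: normal approximation with tie and continuity
# correction. Returns the rank-sum statistic of group 1 and the two-sided p.
ranksum_test <- function(x, g1) {
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  r <- rank(x)
  W <- sum(r[g1])
  mu <- n1 * (n + 1) / 2
  ties <- table(x)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(c(W = W, p = 1))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  c(W = W, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# natural-log fold change of group means on the normalized-count scale with
# a pseudocount of 1 (expression is log1p-normalized on input)
avg_logfc <- function(expr, in_group) {
  m1 <- rowMeans(expm1(expr[, in_group, drop = FALSE]))
  m0 <- rowMeans(expm1(expr[, !in_group, drop = FALSE]))
  log((m1 + 1) / (m0 + 1))
}

#' Wilcoxon rank-sum marker detection
#'
#' One-vs-rest (or all pairwise) two-tailed rank-sum tests with normal
#' approximation and tie correction. Genes are pre-filtered by detection
#' fraction and absolute log fold change before testing; p-values are
#' Bonferroni-corrected over the full gene universe. Fold changes are
#' natural-log ratios of group means (computed on the de-logged normalized
#' counts, pseudocount 1), matching the droplet marker-detection dialect.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param groups per-cell group labels (>= 2 groups; groups under
#'   `min_cells` cells are skipped with a warning).
#' @param mode `"one_vs_rest"` (default) or `"pairwise"`.
#' @param logfc_min minimum absolute log fold change (default 0.25).
#' @param min_pct minimum detection fraction in either side (default 0.1).
#' @param alpha adjusted-p threshold for the reported table (default 0.05).
#' @param min_cells minimum group size (default 3).
#' @return data.frame: gene, comparison, avg_logFC, pct_in, pct_out, W, p,
#'   p_adj, direction — only rows passing the active thresholds.
#' @export
wilcoxon_markers <- function(expr, groups, mode = c("one_vs_rest", "pairwise"),
                             logfc_min = 0.25, min_pct = 0.1, alpha = 0.05,
                             min_cells = 3) {
  mode <- match.arg(mode)
  e <- as.matrix(expr)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  small <- gl[vapply(gl, function(g) sum(groups == g), 0L) < min_cells]
  if (length(small)) {
    warning("group(s) below minimum size skipped: ",
            paste(small, collapse = ", "))
    gl <- setdiff(gl, small)
  }
  G <- nrow(e)  # Bonferroni over the full gene universe
  comparisons <- if (mode == "one_vs_rest") {
    lapply(gl, function(g) list(name = paste0(g, "_vs_rest"),
                                in_mask = groups == g,
                                cells = rep(TRUE, ncol(e))))
  } else {
    cmb <- utils::combn(gl, 2, simplify = FALSE)
    lapply(cmb, function(pr) list(name = paste0(pr[1], "_vs_", pr[2]),
                                  in_mask = groups == pr[1],
                                  cells = groups %in% pr))
  }
  out <- list()
  for (cmp in comparisons) {
    sub <- e[, cmp$cells, drop = FALSE]
    inm <- cmp$in_mask[cmp$cells]
    lfc <- avg_logfc(sub, inm)
    pct_in <- rowMeans(sub[, inm, drop = FALSE] > 0)
    pct_out <- rowMeans(sub[, !inm, drop = FALSE] > 0)
    test_idx <- which((pct_in >= min_pct | pct_out >= min_pct) &
                        abs(lfc) >= logfc_min)
    if (!length(test_idx)) next
    res <- t(vapply(test_idx, function(i) ranksum_test(sub[i, ], inm),
                    c(W = 0, p = 0)))
    p_adj <- pmin(1, res[, "p"] * G)
    keep <- p_adj <= alpha
    if (!any(keep)) next
    idx <- test_idx[keep]
    out[[cmp$name]] <- data.frame(
      gene = rownames(e)[idx], comparison = cmp$name,
      avg_logFC = lfc[idx], pct_in = pct_in[idx], pct_out = pct_out[idx],
      W = res[keep, "W"], p = res[keep, "p"], p_adj = p_adj[keep],
      direction = ifelse(lfc[idx] > 0, "up", "down"),
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(gene = character(), comparison = character(),
                      avg_logFC = numeric(), pct_in = numeric(),
                      pct_out = numeric(), W = numeric(), p = numeric(),
                      p_adj = numeric(), direction = character()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Shared and condition-specific response programs
#'
#' A gene belongs to the shared set of a group of conditions iff its average
#' log fold change versus the common control is at least `logfc_min` (or at
#' most `-logfc_min`) in every condition, with the same direction, and the
#' worst (maximum) adjusted p-value across conditions is at most `alpha`.
#'
#' @param tables named list of per-condition data.frames with columns
#'   `gene`, `avg_logFC`, `p_adj` (all versus the same control).
#' @param logfc_min conjunction fold-change threshold (default 0.5).
#' @param alpha threshold on the worst-case adjusted p (default 0.05).
#' @return data.frame: gene, direction, min_abs_logFC, max_p_adj,
#'   n_conditions.
#' @export
conserved_response <- function(tables, logfc_min = 0.5, alpha = 0.05) {
  if (!length(tables)) stop("no condition tables supplied")
  genes <- Reduce(intersect, lapply(tables, function(t) t$gene))
  if (!length(genes))
    return(data.frame(gene = character(), direction = character(),
                      min_abs_logFC = numeric(), max_p_adj = numeric(),
                      n_conditions = integer()))
  lfc <- vapply(tables, function(t) t$avg_logFC[match(genes, t$gene)],
                numeric(length(genes)))
  pad <- vapply(tables, function(t) t$p_adj[match(genes, t$gene)],
                numeric(length(genes)))
  lfc <- matrix(lfc, nrow = length(genes))
  pad <- matrix(pad, nrow = length(genes))
  up <- rowSums(lfc >= logfc_min) == ncol(lfc)
  dn <- rowSums(lfc <= -logfc_min) == ncol(lfc)
  worst <- apply(pad, 1, max)
  keep <- (up | dn) & worst <= alpha
  data.frame(gene = genes[keep],
             direction = ifelse(up[keep], "up", "down"),
             min_abs_logFC = apply(abs(lfc), 1, min)[keep],
             max_p_adj = worst[keep],
             n_conditions = ncol(lfc),
             row.names = NULL)
}

#' Moderated two-group differential expression for bulk counts
#'
#' A precision-weighted moderated linear model: log2 counts per million with
#' a 0.5 offset; a lowess trend of sqrt residual standard deviation against
#' mean log count supplies per-observation precision weights; per-gene
#' weighted least squares; empirical-Bayes variance moderation with prior
#' degrees of freedom and scale estimated by method of moments on the
#' log-variances; moderated t and Benjamini-Hochberg adjustment.
#'
#' @param counts genes x samples raw count matrix.
#' @param group two-level factor/character of sample groups.
#' @param logfc_gate,fdr_gate reporting gates (defaults 1 and 0.05; set to
#'   `NULL` to report every gene).
#' @param lowess_span span of the mean-variance trend (default 0.5).
#' @param d0 optional prior degrees of freedom override (estimated when
#'   `NULL`; `0` disables moderation, giving the ordinary t-test).
#' @return list: `table` (per gene: log2FC, t, p, p_adj, reported flag,
#'   ordered as input minus excluded genes), `d0`, `s0_sq`.
#' @export
moderated_bulk_de <- function(counts, group, logfc_gate = 1, fdr_gate = 0.05,
                              lowess_span = 0.5, d0 = NULL) {
  x <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("design must have exactly two groups")
  if (any(table(group) < 2)) stop("need >= 2 samples per group")
  lib <- colSums(x)
  logcpm <- log2(sweep(x + 0.5, 2, (lib + 1) / 1e6, "/"))
  # exclude genes with zero variance in both groups
  v1 <- apply(logcpm[, group == levels(group)[1], drop = FALSE], 1, stats::var)
  v2 <- apply(logcpm[, group == levels(group)[2], drop = FALSE], 1, stats::var)
  excluded <- v1 == 0 & v2 == 0
  if (any(excluded))
    message(sum(excluded), " zero-variance gene(s) excluded")
  y <- logcpm[!excluded, , drop = FALSE]
  X <- stats::model.matrix(~group)
  n <- ncol(y); df_resid <- n - 2
  # first pass: unweighted fits for the mean-variance trend
  fit0 <- stats::lm.fit(X, t(y))
  s <- sqrt(colSums(fit0$residuals^2) / df_resid)
  abar <- rowMeans(y)
  lo <- stats::lowess(abar, sqrt(s), f = lowess_span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2)
  # per-observation weights from the trend evaluated at fitted values
  fitted0 <- t(fit0$fitted.values)
  w <- matrix(1 / pmax(trend(fitted0), 0.05)^4, nrow(y), n)
  # weighted least squares per gene
  G <- nrow(y)
  beta <- se_unscaled <- sg2 <- numeric(G)
  for (i in seq_len(G)) {
    wi <- w[i, ]
    f <- stats::lm.wfit(X, y[i, ], wi)
    beta[i] <- f$coefficients[2]
    R <- qr.R(f$qr)
    xtxinv <- chol2inv(R)
    se_unscaled[i] <- sqrt(xtxinv[2, 2])
    sg2[i] <- sum(wi * f$residuals^2) / df_resid
  }
  mom <- moment_prior(sg2, df_resid)
  if (is.null(d0)) d0 <- mom$d0
  s0_sq <- mom$s0_sq
  post <- if (is.finite(d0) && d0 > 0) {
    (d0 * s0_sq + df_resid * sg2) / (d0 + df_resid)
  } else if (is.infinite(d0)) rep(s0_sq, G) else sg2
  df_total <- if (is.finite(d0)) df_resid + d0 else 1e6
  tstat <- beta / (se_unscaled * sqrt(post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p_adj <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(y), log2FC = beta, t = tstat,
                    p = p, p_adj = p_adj, row.names = NULL)
  tab$reported <- if (is.null(logfc_gate) || is.null(fdr_gate)) TRUE else
    abs(tab$log2FC) >= logfc_gate & tab$p_adj <= fdr_gate
  list(table = tab, d0 = d0, s0_sq = s0_sq)
}

# method-of-moments fit of the scaled-F prior for gene variances: on the
# log scale, var(log s^2) = trigamma(d/2) + trigamma(d0/2); the mean gives
# the prior scale.
moment_prior <- function(sg2, df_resid) {
  z <- log(pmax(sg2, 1e-12))
  ev <- stats::var(z) - trigamma(df_resid / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(d0 = Inf,
                s0_sq = exp(mean(z) + digamma(df_resid / 2) -
                              log(df_resid / 2))))
  }
  d0 <- 2 * inv_trigamma(ev)
  mu <- mean(z) - digamma(df_resid / 2) + log(df_resid / 2) +
    digamma(d0 / 2) - log(d0 / 2)
  list(d0 = d0, s0_sq = exp(mu))
}

# invert trigamma by Newton iteration (cf. the standard moderated-t fit)
inv_trigamma <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Mean log fold change of a gene list between two timepoints
#'
#' Per gene, `delta = log1p(e_t1) - log1p(e_t0)`; the mean over the listed
#' genes is returned. Genes absent from the matrix are dropped with a
#' warning.
#'
#' @param bulk_expr genes x samples expression/count matrix.
#' @param t0,t1 column names or indices of the two timepoints.
#' @param gene_list character vector of genes.
#' @return list: `mean_logfc`, `per_gene` (named vector).
#' @export
timepoint_foldchange <- function(bulk_expr, t0, t1, gene_list) {
  b <- as.matrix(bulk_expr)
  miss <- setdiff(gene_list, rownames(b))
  if (length(miss)) warning(length(miss), " gene(s) absent; dropped")
  g <- intersect(gene_list, rownames(b))
  if (!length(g)) stop("no listed gene present")
  delta <- log1p(b[g, t1]) - log1p(b[g, t0])
  list(mean_logfc = mean(delta), per_gene = delta)
}
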