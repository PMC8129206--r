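#' Build multinomial population priors from reference profiles
#'
#' Each reference population's mean-expression vector is restricted to the
#' genes detected in the dataset, renormalized to probabilities, floored at
#' `epsilon` (so zero-probability genes cannot force minus-infinity
#' log-likelihoods) and renormalized again. Populations with an all-zero
#' overlap are excluded with a warning.
#'
#' @param reference `ReferenceProfiles` list (`profiles` populations x genes,
#'   `lineage`, `retain`), e.g. from [read_profile_table()] or
#'   [simulate_reference_profiles()].
#' @param detected_genes character vector of genes present in the dataset.
#' @param epsilon flooring value for zero probabilities (default 1e-10).
#' @return list: `p` (populations x genes probability matrix, rows sum to 1),
#'   `lineage`, `retain`.
#' @export
build_priors <- function(reference, detected_genes, epsilon = 1e-10) {
  prof <- reference$profiles
  genes <- intersect(colnames(prof), detected_genes)
  if (length(genes) == 0) stop("no detected gene overlaps the reference")
  m <- prof[, genes, drop = FALSE]
  tot <- rowSums(m)
  dead <- tot <= 0
  if (any(dead)) {
    warning("excluding ", sum(dead), " population(s) with all-zero overlap")
    m <- m[!dead, , drop = FALSE]
    tot <- tot[!dead]
  }
  p <- m / tot
  p[p == 0] <- epsilon
  p <- p / rowSums(p)
  list(p = p, lineage = reference$lineage[rownames(p)],
       retain = reference$retain)
}

#' Classify cells against reference populations (multinomial model)
#'
#' The log-likelihood of cell `x` under population `c` is
#' `sum_g x_g log p(g|c)` (the multinomial likelihood up to a count-only
#' constant). Each cell is assigned to its argmax population; ties are broken
#' by the first population in declared order and logged via an attribute.
#' Cells with zero total counts over the prior genes are flagged unassigned
#' (`NA`).
#'
#' @param counts genes x cells non-negative integer matrix.
#' @param priors result of [build_priors()].
#' @return list: `loglik` (cells x populations matrix), `assignment`
#'   (character per cell, `NA` = unassigned), `margin` (loglik gap between
#'   best and second-best).
#' @export
classify_cells <- function(counts, priors) {
  x <- as.matrix(counts)
  genes <- intersect(rownames(x), colnames(priors$p))
  x <- x[genes, , drop = FALSE]
  lp <- t(log(priors$p[, genes, drop = FALSE]))  # genes x populations
  ll <- crossprod(x, lp)                          # cells x populations
  tot <- colSums(x)
  best <- max.col(ll, ties.method = "first")
  assignment <- rownames(priors$p)[best]
  assignment[tot == 0] <- NA_character_
  n_ties <- sum(apply(ll, 1, function(r) sum(r == max(r)) > 1) & tot > 0)
  ord <- apply(ll, 1, function(r) sort(r, decreasing = TRUE)[1:2])
  margin <- ord[1, ] - ord[2, ]
  names(assignment) <- names(margin) <- colnames(x)
  structure(list(loglik = ll, assignment = assignment, margin = margin),
            n_ties = n_ties)
}

#' Roll population assignments up to lineages and retain target populations
#'
#' @param assignments character vector of population assignments (`NA`
#'   allowed for unassigned cells, which are dropped).
#' @param priors result of [build_priors()]; its `retain` list defines the
#'   populations to keep and `lineage` must cover every assigned population.
#' @return logical keep mask (FALSE for unassigned cells). Empty retain
#'   intersection yields an all-FALSE mask with a warning.
#' @export
rollup_and_retain <- function(assignments, priors) {
  known <- assignments[!is.na(assignments)]
  bad <- setdiff(unique(known), names(priors$lineage))
  if (length(bad))
    stop("assignment(s) not in lineage map: ", paste(bad, collapse = ", "))
  keep <- !is.na(assignments) & assignments %in% priors$retain
  if (!any(keep))
    warning("no cell assigned to a retained population")
  keep
}

#' Train cell-cycle marker gene pairs (pairs method)
#'
#' Selects, for every phase, ordered gene pairs `(g1, g2)` whose expression
#' difference is positive in at least `q` of that phase's cells and negative
#' in at least `q` of the cells of every other phase. Pairs are ranked by
#' their worst-case frequency margin and capped at `max_pairs` per phase.
#' This is a deliberately simplified variant of the published pairs
#' classifier: threshold-frequency selection on labelled reference cells
#' replaces the original training pipeline, since downstream stages only
#' consume the S and G2M scores and their difference.
#'
#' @param expr genes x cells expression matrix of labelled reference cells.
#' @param phases character/factor vector of phase labels per cell (e.g.
#'   `G1`, `S`, `G2M`).
#' @param q frequency threshold in (0.5, 1\] (default 0.7).
#' @param max_pairs cap per phase (default 50).
#' @param candidate_genes optional restriction of the genes considered; by
#'   default the 100 most variable genes.
#' @return named list (one element per phase) of two-column character
#'   matrices of (g1, g2) pairs.
#' @export
train_marker_pairs <- function(expr, phases, q = 0.7, max_pairs = 50,
                               candidate_genes = NULL) {
  expr <- as.matrix(expr)
  phases <- as.character(phases)
  ph <- unique(phases)
  if (length(ph) < 2) stop("need at least 2 phases")
  if (is.null(candidate_genes)) {
    v <- apply(expr, 1, stats::var)
    candidate_genes <- rownames(expr)[order(v, decreasing = TRUE)]
    candidate_genes <- candidate_genes[seq_len(min(100, length(candidate_genes)))]
  }
  e <- expr[candidate_genes, , drop = FALSE]
  g <- nrow(e)
  # frequency of x_g1 > x_g2 per phase, for all ordered pairs
  freq <- lapply(ph, function(p) {
    ep <- e[, phases == p, drop = FALSE]
    n <- ncol(ep)
    f <- matrix(0, g, g)
    # f[i, j] = fraction of p-cells with e_i > e_j  (ties count as not >)
    for (i in seq_len(g)) f[i, ] <- colSums(ep[i, ] > t(ep)) / n
    f
  })
  names(freq) <- ph
  out <- list()
  for (p in ph) {
    pos <- freq[[p]]
    negmax <- Reduce(pmax, freq[setdiff(ph, p)])
    ok <- which(pos >= q & (1 - negmax) >= q, arr.ind = TRUE)
    ok <- ok[ok[, 1] != ok[, 2], , drop = FALSE]
    if (nrow(ok) == 0)
      stop("no qualifying gene pairs for phase ", p)
    margin <- pmin(pos[ok], (1 - negmax)[ok])
    ord <- order(margin, decreasing = TRUE)
    ok <- ok[ord[seq_len(min(max_pairs, nrow(ok)))], , drop = FALSE]
    out[[p]] <- cbind(g1 = candidate_genes[ok[, 1]],
                      g2 = candidate_genes[ok[, 2]])
  }
  out
}

#' Score cell-cycle phase from marker pairs
#'
#' The score of a cell for phase `P` is the fraction of `P` pairs with
#' `x_g1 > x_g2`; ties count one half. The assigned phase is the argmax; the
#' covariate `s_minus_g2m = S - G2M` is returned when both phases are scored.
#'
#' @param counts genes x cells matrix (raw counts or normalized expression).
#' @param pairs result of [train_marker_pairs()].
#' @return data.frame per cell: one score column per phase in `[0, 1]`,
#'   `phase` (argmax), and `s_minus_g2m` if phases `S` and `G2M` exist.
#' @export
score_phase <- function(counts, pairs) {
  x <- as.matrix(counts)
  if (!length(pairs) || any(!vapply(pairs, nrow, 0L)))
    stop("pairs must be nonempty for every phase")
  scores <- vapply(pairs, function(pp) {
    pp <- pp[pp[, 1] %in% rownames(x) & pp[, 2] %in% rownames(x), ,
             drop = FALSE]
    if (nrow(pp) == 0) return(rep(0.5, ncol(x)))
    a <- x[pp[, 1], , drop = FALSE]
    b <- x[pp[, 2], , drop = FALSE]
    colMeans((a > b) + 0.5 * (a == b))
  }, numeric(ncol(x)))
  scores <- matrix(scores, ncol = length(pairs),
                   dimnames = list(colnames(x), names(pairs)))
  phase <- colnames(scores)[max.col(scores, ties.method = "first")]
  out <- data.frame(scores, phase = phase, check.names = FALSE)
  if (all(c("S", "G2M") %in% colnames(scores)))
    out$s_minus_g2m <- scores[, "S"] - scores[, "G2M"]
  rownames(out) <- colnames(x)
  out
}
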