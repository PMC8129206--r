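#' Fisher-exact enrichment of a gene list against a TF-target library
#'
#' For every TF, a 2x2 table is formed over a fixed background universe
#' (default 20,000 genes): list-and-target overlap, list-only, target-only,
#' remainder. The p-value is the one-sided hypergeometric upper tail
#' (probability of an overlap at least as large), computed in log space.
#'
#' @param gene_list character vector (nonempty; symbols).
#' @param library named list TF -> character vector of target genes.
#' @param background background universe size (default 20000); must be at
#'   least the size of the union of list and targets.
#' @return named numeric vector of per-TF p-values.
#' @export
fisher_enrichment <- function(gene_list, library, background = 20000) {
  gene_list <- unique(gene_list)
  if (!length(gene_list)) stop("gene list is empty")
  vapply(library, function(targets) {
    targets <- unique(targets)
    if (background < length(union(gene_list, targets)))
      stop("background smaller than the union of list and targets")
    k <- length(intersect(gene_list, targets))
    stats::phyper(k - 1, m = length(targets),
                  n = background - length(targets),
                  k = length(gene_list), lower.tail = FALSE)
  }, numeric(1))
}

#' Aggregate per-library enrichment into mean-rank TF activity
#'
#' Within each library, TFs are ranked ascending by p-value (average ranks
#' for ties). A TF's score is the mean of its ranks over the libraries that
#' contain it (the MeanRank aggregation); regulatory activity is
#' `log(1 / mean_rank)`, so rank 1 gives activity 0 and activity decreases
#' strictly with the mean rank.
#'
#' @param p_tables named list of per-library p-value vectors (named by TF),
#'   e.g. several [fisher_enrichment()] results.
#' @return data.frame per TF: `mean_rank`, `activity`, `n_libraries`,
#'   sorted by mean rank. TFs present in no library are absent.
#' @export
mean_rank <- function(p_tables) {
  if (!length(p_tables)) stop("need at least one library")
  ranks <- lapply(p_tables, function(p) stats::setNames(rank(p), names(p)))
  tfs <- unique(unlist(lapply(ranks, names)))
  rk <- vapply(tfs, function(tf) {
    r <- unlist(lapply(ranks, function(x) x[tf]))
    r <- r[!is.na(r)]
    c(mean(r), length(r))
  }, numeric(2))
  out <- data.frame(tf = tfs, mean_rank = rk[1, ],
                    activity = log(1 / rk[1, ]),
                    n_libraries = as.integer(rk[2, ]), row.names = NULL)
  out[order(out$mean_rank), ]
}

#' Flag top transcription factors across two continuum poles
#'
#' Combines the `top_n` TFs by overall activity (maximum of the early and
#' late activities) with the `top_n` TFs by absolute activity difference,
#' deduplicated; each flagged TF is labelled `early` or `late` by the sign
#' of its activity difference.
#'
#' @param activity_early,activity_late data.frames from [mean_rank()] (or
#'   named numeric activity vectors) over a shared TF universe.
#' @param top_n selection depth (default 50; capped at the TF count).
#' @return data.frame: tf, activity_early, activity_late, difference,
#'   label, flagged_by (`top`, `difference` or `both`).
#' @export
top_tf_selection <- function(activity_early, activity_late, top_n = 50) {
  as_vec <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$activity, a$tf) else a
  }
  ae <- as_vec(activity_early)
  al <- as_vec(activity_late)
  tfs <- intersect(names(ae), names(al))
  ae <- ae[tfs]; al <- al[tfs]
  top_n <- min(top_n, length(tfs))
  overall <- pmax(ae, al)
  diff <- ae - al
  set_top <- tfs[order(overall, decreasing = TRUE)[seq_len(top_n)]]
  nonzero <- tfs[abs(diff) > 0]
  set_diff <- nonzero[order(abs(diff[nonzero]),
                            decreasing = TRUE)[seq_len(min(top_n,
                                                           length(nonzero)))]]
  flagged <- union(set_top, set_diff)
  data.frame(tf = flagged,
             activity_early = ae[flagged], activity_late = al[flagged],
             difference = diff[flagged],
             label = ifelse(diff[flagged] > 0, "early",
                            ifelse(diff[flagged] < 0, "late", "shared")),
             flagged_by = ifelse(flagged %in% set_top & flagged %in% set_diff,
                                 "both",
                                 ifelse(flagged %in% set_top, "top",
                                        "difference")),
             row.names = NULL)
}

#' Join inferred TF activity with TF transcript dynamics
#'
#' Matches TF symbols to gene symbols (case-insensitively by default, or
#' through an explicit mapping table) and joins the early/late activities
#' with each TF's Spearman correlation with pseudotime. Unmapped TFs are
#' dropped and reported via an attribute.
#'
#' @param activity data.frame with columns `tf`, `activity_early`,
#'   `activity_late` (e.g. from [top_tf_selection()]).
#' @param gene_rho named numeric vector: per-gene Spearman correlation with
#'   pseudotime.
#' @param mapping optional named vector TF symbol -> gene symbol.
#' @return data.frame: tf, gene, activity_early, activity_late, rho;
#'   attribute `unmapped` lists dropped TFs. Row order follows `activity`.
#' @export
activity_vs_expression <- function(activity, gene_rho, mapping = NULL) {
  tfs <- activity$tf
  gene <- if (!is.null(mapping)) {
    unname(mapping[tfs])
  } else {
    names(gene_rho)[match(toupper(tfs), toupper(names(gene_rho)))]
  }
  ok <- !is.na(gene) & gene %in% names(gene_rho)
  out <- data.frame(tf = tfs[ok], gene = gene[ok],
                    activity_early = activity$activity_early[ok],
                    activity_late = activity$activity_late[ok],
                    rho = unname(gene_rho[gene[ok]]), row.names = NULL)
  attr(out, "unmapped") <- tfs[!ok]
  out
}
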