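#' Configuration for the synthetic maturation continuum
#'
#' Describes a ground-truthed droplet scRNA-seq simulation: cells ordered
#' along a latent maturation time `t` in \[0, 1\] with tissue-specific density
#' (marrow mass early, blood late, spleen broad), gene programs (early =
#' decreasing logistic, late = increasing logistic, transient = Gaussian bump,
#' stable = constant, remainder = low baseline noise genes), negative-binomial
#' UMI noise with lognormal library sizes, a mitochondrial count share, a
#' small proliferating preNeu subpopulation expressing cell-cycle genes,
#' contaminant cells drawn from decoy reference profiles, doublets formed by
#' summing two cells, and hashtag-oligo identities.
#'
#' Defaults emulate the study conditions: a median library of about 1500
#' UMIs, mean mitochondrial fraction 2% so the 5% QC cut removes a small
#' tail, tissue densities Beta(2,6) / Beta(6,2) / Beta(2,2) for marrow /
#' blood / spleen, and a 5% preNeu fraction confined to the early end.
#'
#' @param n_cells_per_tissue named integer vector, cells per tissue.
#' @param n_genes total gene count (programs + cycle + mito + noise).
#' @param frac_early,frac_late,frac_transient,frac_stable gene-program
#'   fractions of `n_genes`; must sum to <= 1, remainder are noise genes.
#' @param logistic_midpoint,logistic_steepness shape of the early/late
#'   logistic programs on t in \[0, 1\].
#' @param transient_peak,transient_width centre range and s.d. of transient
#'   Gaussian bumps.
#' @param lib_mu,lib_sigma lognormal library-size parameters (log counts).
#' @param nb_dispersion per-gene NB overdispersion phi (variance =
#'   mu + phi mu^2); 0 gives deterministic rounded means.
#' @param preneu_fraction fraction of non-contaminant cells that are preNeu
#'   (the earliest cells by latent time).
#' @param n_cycle_genes cell-cycle genes (split between S and G2M blocks).
#' @param cycle_boost multiplicative activity of cycle genes in preNeu cells.
#' @param contaminant_fraction fraction of cells drawn from decoy profiles.
#' @param doublet_rate fraction of cells that are sums of two sampled cells.
#' @param mito_gene_count number of mitochondrial (`mt-`) genes.
#' @param mito_mean_frac mean mitochondrial count fraction (Beta-distributed
#'   per cell).
#' @param mito_high_frac fraction of cells planted with a high-mito tail
#'   (above the 5% QC cut).
#' @param n_hto_tags number of hashtag tags (one per tissue by default use).
#' @param hto_signal,hto_background Poisson rates for own-tag signal and
#'   ambient background.
#' @param tissue_beta named list tissue -> c(shape1, shape2) latent-time Beta
#'   density.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `nt_sim_config`.
#' @export
sim_config <- function(n_cells_per_tissue = c(marrow = 800, blood = 800, spleen = 400),
                       n_genes = 500,
                       frac_early = 0.12, frac_late = 0.12,
                       frac_transient = 0.10, frac_stable = 0.16,
                       logistic_midpoint = 0.5, logistic_steepness = 10,
                       transient_peak = c(0.4, 0.6), transient_width = 0.1,
                       lib_mu = log(1500), lib_sigma = 0.3,
                       nb_dispersion = 0.1,
                       preneu_fraction = 0.05,
                       n_cycle_genes = 30, cycle_boost = 8,
                       contaminant_fraction = 0.05,
                       doublet_rate = 0.02,
                       mito_gene_count = 10, mito_mean_frac = 0.02,
                       mito_high_frac = 0.01,
                       n_hto_tags = 3,
                       hto_signal = 200, hto_background = 5,
                       tissue_beta = list(marrow = c(2, 6), blood = c(6, 2),
                                          spleen = c(2, 2)),
                       seed = 1L) {
  fr <- c(frac_early, frac_late, frac_transient, frac_stable)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("configuration error: program fractions must lie in [0,1] and sum to <= 1")
  for (p in c(preneu_fraction, contaminant_fraction, doublet_rate,
              mito_mean_frac, mito_high_frac))
    if (p < 0 || p > 1) stop("configuration error: proportion outside [0,1]")
  if (n_hto_tags < 2) stop("configuration error: need at least 2 HTO tags")
  n_prog <- floor(n_genes * fr)
  if (n_genes < sum(n_prog) + n_cycle_genes + mito_gene_count)
    stop("configuration error: n_genes too small for requested programs")
  cfg <- as.list(environment())
  cfg$fr <- NULL; cfg$p <- NULL
  cfg$n_early <- n_prog[1]; cfg$n_late <- n_prog[2]
  cfg$n_transient <- n_prog[3]; cfg$n_stable <- n_prog[4]
  cfg$n_prog <- NULL
  structure(cfg, class = "nt_sim_config")
}

# gene annotation table implied by a config: names, program labels, mean-shape
# parameters. Deterministic given the config (shapes drawn from the seed).
sim_gene_plan <- function(config) {
  with(config, {
    n_noise <- n_genes - n_early - n_late - n_transient - n_stable -
      n_cycle_genes - mito_gene_count
    lab <- c(rep("early", n_early), rep("late", n_late),
             rep("transient", n_transient), rep("stable", n_stable),
             rep("cycle_s", ceiling(n_cycle_genes / 2)),
             rep("cycle_g2m", floor(n_cycle_genes / 2)),
             rep("mito", mito_gene_count), rep("noise", n_noise))
    idx <- stats::ave(seq_along(lab), lab, FUN = seq_along)
    gene <- sprintf("%s%s_%03d",
                    ifelse(lab == "mito", "mt-", "g_"),
                    ifelse(lab == "mito", "", lab), idx)
    gene[lab == "mito"] <- sprintf("mt-%03d", idx[lab == "mito"])
    data.frame(gene = gene, program = lab, stringsAsFactors = FALSE)
  })
}

# per-gene amplitude and transient-peak draws, in fixed RNG order so that
# simulate_continuum and simulate_reference_profiles see the same shapes.
# Stable (housekeeping-like) genes sit in a higher abundance range, as they
# do in real cells.
sim_gene_shapes <- function(plan, config) {
  amp <- stats::runif(nrow(plan), 2, 6)
  peak <- stats::runif(nrow(plan), config$transient_peak[1],
                       config$transient_peak[2])
  amp_stable <- stats::runif(nrow(plan), 8, 20)
  amp[plan$program == "stable"] <- amp_stable[plan$program == "stable"]
  list(amp = amp, peak = peak)
}

# expected relative expression (unnormalized) of each non-mito gene at
# latent time t; returns genes x length(t) matrix. Amplitudes vary across
# genes (drawn once from the generator before calling).
sim_program_means <- function(t, plan, config, amp, peak) {
  k <- config$logistic_steepness
  m <- config$logistic_midpoint
  base <- 0.2  # baseline relative expression of every gene
  mu <- matrix(base, nrow(plan), length(t))
  for (i in seq_len(nrow(plan))) {
    mu[i, ] <- base + switch(plan$program[i],
      early     = amp[i] * stats::plogis(-k * (t - m)),
      late      = amp[i] * stats::plogis(k * (t - m)),
      transient = amp[i] * exp(-(t - peak[i])^2 / (2 * config$transient_width^2)),
      stable    = amp[i],
      0)
  }
  rownames(mu) <- plan$gene
  mu
}

#' Simulate a ground-truthed maturation continuum
#'
#' Draws cells along a latent maturation time with tissue-specific Beta
#' densities, builds per-cell expected expression from the gene programs,
#' allocates a per-cell mitochondrial fraction, boosts cell-cycle genes in
#' preNeu cells, replaces a configured fraction of cells by contaminants
#' sampled from decoy reference profiles, overlays doublets by summing two
#' cells' counts, and draws UMI counts from a negative binomial with
#' lognormal library sizes (dispersion 0 gives rounded noise-free means).
#'
#' @param config an [sim_config()] object.
#' @return list with `counts` (genes x cells integer matrix), `cells`
#'   (data.frame: cell, tissue, latent_time, is_preneu, is_contaminant,
#'   is_doublet, hto_identity, hto_identity2, mito_frac, library_size),
#'   `genes` (data.frame: gene, program), and `config`.
#' @examples
#' sim <- simulate_continuum(sim_config(
#'   n_cells_per_tissue = c(marrow = 30, blood = 30), n_genes = 60,
#'   n_cycle_genes = 4, mito_gene_count = 2, seed = 7))
#' dim(sim$counts)
#' @export
simulate_continuum <- function(config) {
  stopifnot(inherits(config, "nt_sim_config"))
  set.seed(config$seed)
  plan <- sim_gene_plan(config)
  n_cells <- sum(config$n_cells_per_tissue)
  tissues <- rep(names(config$n_cells_per_tissue), config$n_cells_per_tissue)

  # per-gene shape draws (fixed order so the seed pins everything)
  shapes <- sim_gene_shapes(plan, config)
  amp <- shapes$amp; peak <- shapes$peak

  # latent time per cell from the tissue densities
  t <- numeric(n_cells)
  for (ti in names(config$n_cells_per_tissue)) {
    sel <- tissues == ti
    b <- config$tissue_beta[[ti]]
    if (is.null(b)) b <- c(2, 2)
    t[sel] <- stats::rbeta(sum(sel), b[1], b[2])
  }

  # contaminants: no latent time, drawn from decoy profiles
  is_cont <- stats::runif(n_cells) < config$contaminant_fraction
  t[is_cont] <- NA_real_

  # preNeu: earliest cells among the non-contaminants
  is_pre <- rep(FALSE, n_cells)
  ok <- which(!is_cont)
  if (config$preneu_fraction > 0 && length(ok)) {
    thr <- stats::quantile(t[ok], config$preneu_fraction, type = 7)
    is_pre[ok] <- t[ok] <= thr
  }

  # expected relative expression
  mu <- sim_program_means(ifelse(is.na(t), 0.5, t), plan, config, amp, peak)
  cyc <- plan$program %in% c("cycle_s", "cycle_g2m")
  mu[cyc, is_pre] <- mu[cyc, is_pre] * config$cycle_boost

  # decoy profiles for contaminants: disjoint marker blocks on noise genes
  decoys <- sim_decoy_profiles(plan, config)
  if (any(is_cont)) {
    which_decoy <- sample(nrow(decoys$profiles), sum(is_cont), replace = TRUE)
    mu[, is_cont] <- t(decoys$profiles[which_decoy, , drop = FALSE])
  }

  # mitochondrial fraction per cell: Beta with mean mito_mean_frac, plus a
  # planted high-mito tail above the QC cut
  mf <- config$mito_mean_frac
  mito_frac <- stats::rbeta(n_cells, mf * 300, (1 - mf) * 300)
  hi <- stats::runif(n_cells) < config$mito_high_frac
  mito_frac[hi] <- stats::runif(sum(hi), 0.07, 0.20)
  is_mito <- plan$program == "mito"
  if (!any(is_mito)) mito_frac[] <- 0
  p <- sweep(mu, 2, colSums(mu), "/")
  p[!is_mito, ] <- sweep(p[!is_mito, , drop = FALSE], 2,
                         (1 - mito_frac) / colSums(p[!is_mito, , drop = FALSE]), "*")
  p[is_mito, ] <- matrix(rep(mito_frac / sum(is_mito), each = sum(is_mito)),
                         nrow = sum(is_mito))

  # library sizes and counts
  lib <- round(stats::rlnorm(n_cells, config$lib_mu, config$lib_sigma))
  mu_counts <- sweep(p, 2, lib, "*")
  if (config$nb_dispersion <= 0) {
    counts <- round(mu_counts)
  } else {
    size <- 1 / config$nb_dispersion
    counts <- matrix(stats::rnbinom(length(mu_counts), mu = as.vector(mu_counts),
                                    size = size),
                     nrow = nrow(mu_counts))
  }

  # HTO identity: one tag per cell, cycling over tissues
  tag <- (match(tissues, names(config$n_cells_per_tissue)) - 1L) %%
    config$n_hto_tags + 1L

  # doublets: replace a cell's counts by the sum of itself and a partner
  is_dbl <- stats::runif(n_cells) < config$doublet_rate
  tag2 <- rep(NA_integer_, n_cells)
  if (any(is_dbl)) {
    partners <- sample(n_cells, sum(is_dbl), replace = TRUE)
    counts[, is_dbl] <- counts[, is_dbl, drop = FALSE] +
      counts[, partners, drop = FALSE]
    other <- tag[partners]
    same <- other == tag[is_dbl]
    other[same] <- (other[same] %% config$n_hto_tags) + 1L
    tag2[is_dbl] <- other
  }

  dimnames(counts) <- list(plan$gene, sprintf("cell_%05d", seq_len(n_cells)))
  cells <- data.frame(
    cell = colnames(counts), tissue = tissues, latent_time = t,
    is_preneu = is_pre, is_contaminant = is_cont, is_doublet = is_dbl,
    hto_identity = tag, hto_identity2 = tag2,
    mito_frac = mito_frac, library_size = lib,
    stringsAsFactors = FALSE)
  list(counts = counts, cells = cells, genes = plan, config = config)
}

# decoy population mean profiles: baseline everywhere, strong disjoint marker
# blocks carved out of the noise genes. Deterministic given the plan.
sim_decoy_profiles <- function(plan, config, n_decoys = 2) {
  noise_idx <- which(plan$program == "noise")
  if (length(noise_idx) < n_decoys * 5)
    stop("configuration error: too few noise genes to build decoy profiles")
  per <- min(20, length(noise_idx) %/% n_decoys)
  profiles <- matrix(0.2, n_decoys, nrow(plan),
                     dimnames = list(paste0("decoy_", seq_len(n_decoys)),
                                     plan$gene))
  blocks <- vector("list", n_decoys)
  for (d in seq_len(n_decoys)) {
    block <- noise_idx[((d - 1) * per + 1):(d * per)]
    profiles[d, block] <- 8
    blocks[[d]] <- plan$gene[block]
  }
  list(profiles = profiles, markers = blocks)
}

#' Simulate reference class-mean profiles for the multinomial classifier
#'
#' Builds a populations x genes mean-expression table in the format of an
#' immune-reference class-mean set: granulocyte-family target populations are
#' stage averages of the continuum programs (an early-stage and a late-stage
#' profile by default), decoy populations express disjoint marker blocks.
#' Returns the lineage map and the retain-list of granulocyte populations.
#'
#' @param config an [sim_config()] object.
#' @param target_names names of granulocyte-stage populations (>= 2).
#' @param n_decoys number of decoy populations (>= 1).
#' @return `ReferenceProfiles` list: `profiles` (populations x genes),
#'   `lineage` (named vector), `retain` (character).
#' @export
simulate_reference_profiles <- function(config,
                                        target_names = c("GN.BM", "GN.Bl"),
                                        n_decoys = 2) {
  stopifnot(inherits(config, "nt_sim_config"))
  if (length(target_names) < 2 || n_decoys < 1)
    stop("need >= 2 target and >= 1 decoy populations")
  set.seed(config$seed)
  plan <- sim_gene_plan(config)
  shapes <- sim_gene_shapes(plan, config)
  amp <- shapes$amp; peak <- shapes$peak
  # stage averages over consecutive windows of t
  k <- length(target_names)
  edges <- seq(0, 1, length.out = k + 1)
  grid <- seq(0.005, 0.995, by = 0.01)
  mu <- sim_program_means(grid, plan, config, amp, peak)
  targets <- t(vapply(seq_len(k), function(i) {
    rowMeans(mu[, grid >= edges[i] & grid <= edges[i + 1], drop = FALSE])
  }, numeric(nrow(plan))))
  rownames(targets) <- target_names
  dec <- sim_decoy_profiles(plan, config, n_decoys)
  profiles <- rbind(targets, dec$profiles)
  lineage <- stats::setNames(c(rep("granulocyte", k),
                               paste0("lineage_", seq_len(n_decoys))),
                             rownames(profiles))
  list(profiles = profiles, lineage = lineage, retain = target_names)
}

#' Simulate hashtag-oligo tag counts
#'
#' Tag counts per cell = Poisson signal on the cell's own tag(s) plus
#' Poisson ambient background on every tag. Doublets carry signal on both of
#' their tags; optional dropout cells receive background only.
#'
#' @param cells the `cells` data.frame from [simulate_continuum()] (columns
#'   `hto_identity`, `hto_identity2`).
#' @param config an [sim_config()] object.
#' @param dropout_rate fraction of cells with no tag signal (negatives).
#' @return tags x cells integer matrix.
#' @export
simulate_hto <- function(cells, config, dropout_rate = 0) {
  stopifnot(inherits(config, "nt_sim_config"))
  if (config$n_hto_tags < 2) stop("configuration error: need >= 2 HTO tags")
  set.seed(config$seed + 1L)
  n <- nrow(cells)
  k <- config$n_hto_tags
  hto <- matrix(stats::rpois(k * n, config$hto_background), k, n,
                dimnames = list(paste0("tag_", seq_len(k)), cells$cell))
  drop <- stats::runif(n) < dropout_rate
  sig1 <- stats::rpois(n, config$hto_signal)
  sig2 <- stats::rpois(n, config$hto_signal)
  for (i in seq_len(n)) {
    if (drop[i]) next
    hto[cells$hto_identity[i], i] <- hto[cells$hto_identity[i], i] + sig1[i]
    if (!is.na(cells$hto_identity2[i]))
      hto[cells$hto_identity2[i], i] <- hto[cells$hto_identity2[i], i] + sig2[i]
  }
  hto
}

#' Write a simulation to disk as standard text bundles
#'
#' Writes the CellRanger-style matrix bundle, a ground-truth cell TSV, a gene
#' program TSV and a reference-profile CSV.
#'
#' @param sim result of [simulate_continuum()].
#' @param path output directory.
#' @param gzip compress the matrix bundle.
#' @export
write_simulation <- function(sim, path, gzip = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mtx_bundle(sim$counts, file.path(path, "matrix"), gzip = gzip)
  write_cell_table(sim$cells, file.path(path, "ground_truth_cells.tsv"))
  write_gene_table(sim$genes, file.path(path, "ground_truth_genes.tsv"))
  ref <- simulate_reference_profiles(sim$config)
  write_profile_table(ref, file.path(path, "reference_profiles.csv"))
  invisible(path)
}
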