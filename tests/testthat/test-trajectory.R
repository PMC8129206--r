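test_that("residual variance flags structured genes and not technical ones", {
  set.seed(41)
  n <- 300
  lib <- rpois(n, 2000)
  counts <- rbind(
    constant = rep(5, n),
    libgene  = round(lib / 100),          # exact function of the covariate
    noise    = rpois(n, 3))
  cov <- data.frame(n_umis = lib, s_minus_g2m = 0, pct_mito = 0)
  hv <- select_hvg(counts, cov)
  expect_equal(hv["constant", "residual_variance"], 0)
  expect_lt(hv["libgene", "residual_variance"], 0.5)
  expect_false(hv["noise", "selected"])
  expect_error(select_hvg(counts, data.frame(n_umis = c(NA, lib[-1]))),
               "finite")
})

test_that("planted program genes outrank noise genes in residual variance", {
  run <- default_pipeline()
  hv <- run$fit$hvg
  prog <- gene_program(rownames(hv))
  rv <- hv$residual_variance
  is_prog <- prog %in% c("early", "late", "transient")
  is_noise <- prog == "noise"
  # AUROC of program vs noise via the rank-sum statistic
  r <- rank(rv[is_prog | is_noise])
  auroc <- (sum(r[is_prog[is_prog | is_noise]]) -
              sum(is_prog) * (sum(is_prog) + 1) / 2) /
    (sum(is_prog) * sum(is_noise))
  expect_gt(auroc, 0.9)
})

test_that("PCA is deterministic, sign-fixed and complete", {
  set.seed(42)
  # rank-1 matrix: the first component explains ~all variance
  u <- rnorm(30); v <- rnorm(80)
  m <- outer(u, v) + matrix(rnorm(2400, sd = 1e-3), 30, 80)
  rownames(m) <- paste0("g", 1:30); colnames(m) <- paste0("c", 1:80)
  p <- run_pca(m, n_components = 5)
  expect_gt(p$var_explained[1], 0.99)
  # reconstruction with all components is exact
  z <- t(scale(t(m)))
  pf <- run_pca(m, n_components = 30)
  rec <- pf$coords %*% t(pf$loadings)
  expect_lt(max(abs(t(rec) - z)), 1e-8)
  # sign convention: the largest loading of each component is positive
  expect_true(all(apply(pf$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_warning(run_pca(m[1:10, 1:5], 50), "reducing")
})

test_that("PC1 tracks the latent maturation time", {
  run <- default_pipeline()
  ok <- !is.na(run$cells$latent_time)
  rho <- cor(run$fit$pca$coords[ok, 1], run$cells$latent_time[ok],
             method = "spearman")
  expect_gt(abs(rho), 0.8)
})

test_that("correlation distance matches its definition", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  D <- correlation_distance(m)
  expect_equal(D["a", "b"], 0)            # proportional rows
  expect_equal(D["a", "c"], 2)            # anti-proportional rows
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  # brute-force double loop on random data
  set.seed(43)
  x <- matrix(rnorm(200), 10, 20)
  D2 <- correlation_distance(x)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 0 else 1 - cor(x[i, ], x[j, ])
    expect_equal(D2[i, j], expected, tolerance = 1e-12)
  }
  # zero-variance rows get the maximal distance, flagged
  x[3, ] <- 7
  D3 <- suppressWarnings(correlation_distance(x))
  expect_equal(attr(D3, "flagged"), 3)
  expect_equal(D3[3, 5], 2)
})

test_that("diffusion map separates blocks and orders a 1-D manifold", {
  set.seed(44)
  blob <- rbind(matrix(rnorm(100, 0), 50, 2),
                matrix(rnorm(100, 10), 50, 2))
  D <- as.matrix(dist(blob))
  dm <- diffusion_map(D, n_dc = 3, k_local = 10)
  s <- sign(dm$coords[, 1])
  expect_true(all(s[1:50] == s[1]) && all(s[51:100] == -s[1]))
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  expect_true(all(dm$eigenvalues <= 1 + 1e-9))

  # points along a line: DC1 recovers the ordering exactly
  x <- seq(0, 1, length.out = 60)
  Dl <- as.matrix(dist(cbind(x, 0 * x)))
  rownames(Dl) <- colnames(Dl) <- paste0("c", 1:60)
  dml <- diffusion_map(Dl, n_dc = 2, k_local = 5)
  o <- order(dml$coords[, 1])
  expect_true(identical(o, 1:60) || identical(o, 60:1))

  expect_error(diffusion_map(matrix(1, 3, 4)), "symmetric")
})

test_that("disconnected kernel graphs are reported with component sizes", {
  D <- matrix(2e6, 6, 6)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  expect_error(diffusion_map(D, n_dc = 2, k_local = 2), "disconnected")
})

test_that("root selection takes explicit lists or score quantiles", {
  expect_equal(select_root(cells = c("a", "b")), c("a", "b"))
  expect_error(select_root(cells = character(0)), "empty")
  sc <- setNames(1:100, paste0("c", 1:100))
  expect_equal(select_root(sc, quantile = 0.99), "c100")
  expect_equal(select_root(sc, quantile = 0.95), paste0("c", 96:100))
  expect_warning(all_cells <- select_root(sc, quantile = 0), "every cell")
  expect_length(all_cells, 100)
  run <- default_pipeline()
  expect_gt(mean(run$cells$is_preneu[match(run$roots, run$cells$cell)]), 0.8)
})

test_that("pseudotime is root-anchored, scaled and rank-stable", {
  run <- default_pipeline()
  fit <- run$fit
  expect_equal(unname(range(fit$neutrotime)), c(0, 1))
  expect_lte(mean(fit$neutrotime[fit$root_cells]), 0.05)
  # positive rescaling of the diffusion coordinates preserves the ranks
  pt2 <- pseudotime_from_root(fit$dm$coords * 3.7, fit$dm$eigenvalues,
                              fit$root_cells)
  expect_equal(rank(pt2$neutrotime), rank(fit$neutrotime))
  expect_error(pseudotime_from_root(fit$dm$coords * 0, fit$dm$eigenvalues,
                                    fit$root_cells), "degenerate")
})

test_that("principal curve recovers arclength on a straight line", {
  set.seed(45)
  t <- runif(100)
  pts <- cbind(3 * t, -2 * t) + matrix(rnorm(200, sd = 1e-4), 100, 2)
  pc <- principal_curve(pts, orient_by = t)
  expect_gt(cor(pc$arclength, t), 0.9999)
  # arclength is the signed position along the line (slope sqrt(13))
  fitline <- lm(pc$arclength ~ t)
  expect_equal(unname(coef(fitline)[2]), sqrt(13), tolerance = 0.05)
  # orientation flag flips the parameter when anti-correlated
  pc2 <- principal_curve(pts, orient_by = -t)
  expect_lt(cor(pc2$arclength, t), 0)
})

test_that("dip statistic matches exact values and the direct minimizer", {
  # closed-form cases: n equal point masses give 1/(2k); degenerate gives 0
  expect_equal(dip_stat((1:8) / 8), 1 / 16)
  expect_equal(dip_stat(rep(c(0, 1), each = 25)), 0.25)
  expect_equal(dip_stat(rep(c(0, 1, 2), each = 5)), 1 / 6)
  expect_equal(dip_stat(rep(3, 10)), 0)
  # random small samples against the constrained Nelder-Mead minimizer
  set.seed(46)
  samples <- replicate(6, round(runif(sample(4:8, 1)), 2), simplify = FALSE)
  for (x in samples) {
    d <- dip_stat(x)
    o <- dip_oracle(x, restarts = 60)
    expect_gte(o, d - 1e-8)      # the oracle is an upper bound
    expect_lt(o - d, 1e-2)       # and a tight one at small n
  }
})

test_that("dip test separates unimodal from bimodal samples", {
  res_null <- dip_test(qunif(ppoints(200)), n_boot = 500, seed = 1)
  expect_gt(res_null$p_value, 0.05)
  res_bi <- dip_test(rep(c(0, 1), each = 250), n_boot = 2000, seed = 1)
  expect_lt(res_bi$p_value, 0.001)
  expect_equal(dip_test(rep(2, 10))$p_value, 1)
})

test_that("neutrotime separates into multiple abundance modes", {
  run <- default_pipeline()
  res <- dip_test(run$fit$neutrotime, n_boot = 500, seed = 7)
  expect_lt(res$p_value, 0.05)
})

test_that("per-label densities integrate to one and order by tissue", {
  set.seed(47)
  d <- density_along_pseudotime(runif(500), rep("all", 500))
  step <- d$grid[2] - d$grid[1]
  area <- sum((d$density[1, -1] + d$density[1, -512]) / 2) * step
  expect_equal(area, 1, tolerance = 1e-3)
  expect_lt(diff(range(d$density[1, d$grid > 0.15 & d$grid < 0.85])), 0.6)

  run <- default_pipeline()
  dl <- density_along_pseudotime(run$fit$neutrotime, run$cells$tissue)
  am <- apply(dl$density, 1, which.max)
  expect_lt(am["marrow"], am["blood"])
  expect_warning(density_along_pseudotime(c(0.1, 0.5, 0.7),
                                          c("a", "a", "b")),
                 "fewer than 2")
})

test_that("pseudotime ranks are invariant under cell permutation", {
  run <- default_pipeline()
  counts <- run$counts
  set.seed(48)
  perm <- sample(ncol(counts))
  fit2 <- suppressWarnings(
    neutrotime(counts[, perm], root_cells = run$roots))
  nt1 <- run$fit$neutrotime
  nt2 <- fit2$neutrotime[names(nt1)]
  expect_equal(rank(nt2), rank(nt1))
})

test_that("noise-free monotone expression yields the exact latent order", {
  cfg <- sim_config(n_cells_per_tissue = c(marrow = 30, blood = 30),
                    n_genes = 60, frac_early = 0.3, frac_late = 0.3,
                    frac_transient = 0, frac_stable = 0.2,
                    nb_dispersion = 0, lib_sigma = 0, lib_mu = log(20000),
                    contaminant_fraction = 0, doublet_rate = 0,
                    preneu_fraction = 0, mito_gene_count = 0,
                    n_cycle_genes = 0, mito_high_frac = 0, seed = 49)
  sim <- simulate_continuum(cfg)
  t <- sim$cells$latent_time
  roots <- sim$cells$cell[rank(t) <= 3]
  fit <- suppressWarnings(neutrotime(sim$counts, root_cells = roots,
                                     config = nt_config(k_local = 5)))
  expect_gt(cor(fit$neutrotime, t, method = "spearman"), 0.999)
})
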