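test_that("gene-pseudotime correlation matches a rank-then-Pearson oracle", {
  set.seed(51)
  nt <- runif(20)
  expr <- rbind(mono = nt^3, inv = -nt, noise = rnorm(20), flat = rep(2, 20))
  res <- gene_time_correlation(expr, nt)
  expect_equal(res["mono", "rho"], 1)
  expect_equal(res["inv", "rho"], -1)
  expect_equal(res["flat", "rho"], 0)
  expect_true(res["flat", "flagged"])
  expect_equal(res["noise", "rho"],
               cor(rank(expr["noise", ]), rank(nt)) , tolerance = 1e-12)
  # an independent (permuted) gene decorrelates at n = 2000
  run <- default_pipeline()
  g <- run$expr[1, sample(ncol(run$expr))]
  rho <- gene_time_correlation(rbind(perm = g), run$fit$neutrotime)["perm", "rho"]
  expect_lt(abs(rho), 0.1)
})

test_that("Moran's I matches double-loop enumeration on small graphs", {
  set.seed(52)
  # all simple graphs up to 10 nodes, random instances
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      w <- matrix(rbinom(n * n, 1, 0.4), n, n)
      diag(w) <- 0
      if (sum(w) == 0) w[1, 2] <- 1
      x <- rnorm(n)
      ours <- suppressWarnings(
        morans_i(matrix(x, 1, n, dimnames = list("g", NULL)),
                 Matrix::Matrix(w, sparse = TRUE)))
      expect_equal(ours["g", "moran_i"], moran_oracle(x, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("Moran's I behaves at the smooth and null extremes", {
  n <- 100
  chain <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n),
                                j = c(2:n, 1:(n - 1)), x = 1,
                                dims = c(n, n))
  grad <- matrix(seq_len(n), 1, n, dimnames = list("g", NULL))
  expect_gt(morans_i(grad, chain)["g", "moran_i"], 0.9)
  const <- matrix(1, 1, n, dimnames = list("flat", NULL))
  res <- morans_i(const, chain)
  expect_equal(res["flat", "moran_i"], 0)
  expect_true(res["flat", "flagged"])
  set.seed(53)
  null_i <- replicate(200, {
    x <- matrix(rnorm(n), 1, n, dimnames = list("g", NULL))
    morans_i(x, chain)["g", "moran_i"]
  })
  expect_lt(abs(mean(null_i) - (-1 / (n - 1))), 0.02)
})

test_that("signature classes follow the threshold scheme exactly", {
  rho <- c(a = 0.15, b = 0.9, c = 0.5, d = -0.5, e = 0.0, f = 0.05,
           g = 0.3)
  mi <- c(a = 0.5, b = 0.19, c = 0.5, d = 0.5, e = 0.5, f = 0.5, g = 0.5)
  me <- c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 0.05, g = 1)
  sig <- select_signature_genes(rho, mi, me)
  expect_equal(sig["a", "class"], "unused")   # rho in the 0.1-0.2 gap
  expect_equal(sig["b", "class"], "unused")   # fails Moran eligibility
  expect_equal(sig["c", "class"], "positive")
  expect_equal(sig["d", "class"], "negative")
  expect_equal(sig["e", "class"], "stable")
  expect_equal(sig["f", "class"], "unused")   # fails mean-expression cut
  expect_equal(sig["g", "class"], "positive")
  # raising the positive threshold shrinks N+ monotonically
  sig2 <- select_signature_genes(rho, mi, me, rho_pos = 0.45)
  np1 <- rownames(sig)[sig$class == "positive"]
  np2 <- rownames(sig2)[sig2$class == "positive"]
  expect_true(all(np2 %in% np1))
  expect_lt(length(np2), length(np1))
  expect_error(select_signature_genes(rho, mi * 0, me), "empty")
})

test_that("planted early and late programs fill the signature classes", {
  run <- default_pipeline()
  sig <- coef(run$fit)
  prog <- gene_program(rownames(sig))
  expect_gt(mean(prog[sig$class == "positive"] == "late"), 0.85)
  expect_gt(mean(prog[sig$class == "negative"] == "early"), 0.85)
  expect_true(all(prog[sig$class == "stable"] %in%
                    c("transient", "stable", "noise")))
})

test_that("the continuum score is scale-free and antisymmetric", {
  sig <- data.frame(class = c("positive", "positive", "negative", "negative",
                              "stable", "stable"),
                    row.names = paste0("g", 1:6))
  e <- matrix(c(2, 3, 2, 3, 4, 1,
                9, 1, 3, 2, 2, 3), 6, 2,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  s <- neutrotime_s(e, sig)
  expect_equal(unname(s["s1"]), 0)          # balanced N+ and N- sums
  expect_equal(neutrotime_s(e * 13, sig), s)  # global scaling drops out
  sig_sw <- sig
  sig_sw$class <- c("negative", "negative", "positive", "positive",
                    "stable", "stable")
  expect_equal(neutrotime_s(e, sig_sw), -s)
  # non-positive denominator flags the sample
  e2 <- e; e2[c("g5", "g6"), "s1"] <- 0
  expect_warning(s2 <- neutrotime_s(e2, sig), "denominator")
  expect_true(is.na(s2["s1"]))
  expect_warning(neutrotime_s(e[-1, ], sig), "missing")
})

test_that("module scores are centred for random sets, high for planted ones", {
  run <- default_pipeline()
  set.seed(54)
  rand_genes <- sample(rownames(run$expr), 30)
  ms <- module_score(run$expr, rand_genes, seed = 55)
  expect_lt(abs(mean(ms)), 0.05)
  cyc <- grep("^g_cycle", rownames(run$expr), value = TRUE)
  msc <- module_score(run$expr, cyc, seed = 55)
  expect_gt(mean(msc[run$cells$is_preneu]), mean(msc[!run$cells$is_preneu]))
  expect_error(module_score(run$expr, "not_a_gene"), "no overlap")
  expect_warning(module_score(run$expr, rownames(run$expr)[1]), "fewer than 2")
})

test_that("bulk projection orders pseudo-bulk samples by latent stage", {
  run <- default_pipeline()
  sig <- coef(run$fit)
  t <- run$cells$latent_time
  q <- cut(t, breaks = quantile(t, seq(0, 1, 0.25), na.rm = TRUE),
           include.lowest = TRUE, labels = FALSE)
  bulk <- sapply(1:4, function(k)
    rowSums(run$counts[, which(q == k), drop = FALSE]))
  colnames(bulk) <- paste0("q", 1:4)
  pr <- project_bulk(bulk, sig)
  expect_true(all(diff(pr$score) > 0))
  # permuting gene labels destroys the ordering: the score spread collapses
  # and the strict quartile ordering is lost in most permutations
  set.seed(56)
  perm_range <- numeric(5)
  increasing <- logical(5)
  for (i in 1:5) {
    bulk_perm <- bulk
    rownames(bulk_perm) <- sample(rownames(bulk))
    pr_perm <- suppressWarnings(project_bulk(bulk_perm, sig))
    perm_range[i] <- diff(range(pr_perm$score))
    increasing[i] <- all(diff(pr_perm$score) > 0)
  }
  expect_lt(max(perm_range), 0.1 * diff(range(pr$score)))
  expect_false(all(increasing))
  # missing most signature genes is an error
  expect_error(project_bulk(bulk[1:40, ], sig), "signature genes")
})

test_that("adaptive bins satisfy both minima and partition the cells", {
  # 90 cells, 3 tissues interleaved evenly: three bins of 30
  nt <- seq_len(90) / 91
  tissue <- rep(c("m", "b", "s"), 30)
  ab <- adaptive_bins(nt, tissue, step = 1e-5)
  expect_equal(unname(ab$table$n_total), c(30, 30, 30))
  expect_equal(max(ab$bin), 3)

  # a tail that cannot close merges backward into the last full bin
  nt2 <- c(nt, 0.995)
  t2 <- c(tissue, "m")
  ab2 <- adaptive_bins(nt2, t2, step = 1e-5)
  expect_equal(sum(ab2$table$n_total), 91)
  expect_true(all(ab2$table$n_total >= 30))

  expect_warning(adaptive_bins(c(0.1, 0.1 + 5e-6, 0.9), c("a", "a", "a"),
                               step = 1e-5, min_per_tissue = 1,
                               min_total = 1), "smallest pseudotime gap")

  run <- default_pipeline()
  abr <- suppressWarnings(
    adaptive_bins(run$fit$neutrotime, run$cells$tissue))
  tiss_cols <- grep("^n_", names(abr$table), value = TRUE)
  tiss_cols <- setdiff(tiss_cols, "n_total")
  expect_true(all(abr$table$n_total >= 30))
  for (cc in tiss_cols) expect_true(all(abr$table[[cc]] >= 5))
  expect_equal(sum(abr$table$n_total), length(run$fit$neutrotime))
})

test_that("gene-dynamics k-means recovers planted trend families", {
  # two perfectly distinct shapes: exact recovery with k = 2
  up <- matrix(rep(seq(0, 1, length.out = 50), 5), 5, 50, byrow = TRUE)
  down <- matrix(rep(seq(1, 0, length.out = 50), 5), 5, 50, byrow = TRUE)
  m <- rbind(up, down)
  rownames(m) <- paste0("g", 1:10)
  km <- kmeans_gene_dynamics(m, k = 2, seed = 1)
  expect_equal(length(unique(km$cluster[1:5])), 1)
  expect_equal(length(unique(km$cluster[6:10])), 1)
  expect_false(km$cluster[1] == km$cluster[6])
  expect_error(kmeans_gene_dynamics(m, k = 11), "exceeds")

  # Lloyd objective is non-increasing in the iteration count
  set.seed(57)
  noisy <- m + matrix(rnorm(500, sd = 0.4), 10, 50)
  rownames(noisy) <- rownames(m)
  init <- (noisy - apply(noisy, 1, min)) /
    apply(noisy, 1, function(r) diff(range(r)))
  centers0 <- init[c(1, 6), ]
  obj <- vapply(1:5, function(it)
    kmeans_gene_dynamics(noisy, k = 2, n_iter = it,
                         centers = centers0)$withinss_total, numeric(1))
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("planted programs fall into distinct dynamic clusters", {
  run <- default_pipeline()
  prog <- gene_program(rownames(run$expr))
  sel <- prog %in% c("early", "late", "transient")
  ord <- order(run$fit$neutrotime)
  km <- kmeans_gene_dynamics(run$expr[sel, ord], k = 4, seed = 2)
  ari <- adjusted_rand_index(km$cluster, prog[sel])
  expect_gt(ari, 0.7)
})

test_that("smoothed trends recover line, constant and peak shapes", {
  set.seed(58)
  nt <- sort(runif(200))
  expr <- rbind(linear = 2 * nt + 1,
                flat = rep(3, 200),
                bump = exp(-(nt - 0.55)^2 / (2 * 0.1^2)) +
                  rnorm(200, sd = 0.05))
  tr <- smooth_gene_trend(expr, nt)
  expect_lt(max(abs(tr$fitted["linear", ] - (2 * tr$grid + 1))), 1e-2)
  expect_lt(diff(range(tr$fitted["flat", ])), 1e-8)
  peak <- tr$grid[which.max(tr$fitted["bump", ])]
  expect_lt(abs(peak - 0.55), 0.1)
  expect_error(smooth_gene_trend(expr[, 1:10], nt[1:10]), "30 cells")
})

test_that("transient genes peak where they were planted", {
  run <- default_pipeline()
  plan <- run$sim$genes
  set.seed(run$sim$config$seed)
  shapes <- neutrotime:::sim_gene_shapes(plan, run$sim$config)
  trans <- which(plan$program == "transient")[1:5]
  genes <- plan$gene[trans]
  # smooth against the true latent time: the planted peak location is in
  # latent units, and estimated pseudotime is only a monotone warp of it
  tr <- smooth_gene_trend(run$expr[genes, , drop = FALSE],
                          run$cells$latent_time)
  for (i in seq_along(genes)) {
    fitted_peak <- tr$grid[which.max(tr$fitted[genes[i], ])]
    expect_lt(abs(fitted_peak - shapes$peak[trans[i]]), 0.1)
  }
})
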