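# independent brute-force oracles used by the unit and acceptance tests;
# each re-derives its quantity from first principles on small instances

# Moran's I by explicit double summation over all node pairs
moran_oracle <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# hypergeometric upper-tail p by direct summation of the pmf
fisher_oracle <- function(k, n_targets, n_list, background) {
  jmax <- min(n_targets, n_list)
  sum(vapply(k:jmax, function(j) {
    exp(lchoose(n_targets, j) + lchoose(background - n_targets, n_list - j) -
          lchoose(background, n_list))
  }, numeric(1)))
}

# two-sided rank-sum p by exhaustive enumeration of group assignments
wilcoxon_oracle <- function(x, g1) {
  n <- length(x)
  n1 <- sum(g1)
  r <- rank(x)
  w_obs <- sum(r[g1])
  mu <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Benjamini-Hochberg by the literal step-up rule
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- rev(cummin(rev(p[o] * n / seq_len(n))))
  adj[o] <- pmin(1, cummin_rev)
  adj
}

# dip statistic by direct numerical minimization over unimodal CDFs:
# for each candidate modal atom, the left (convex) and right (concave)
# branch values are parameterized through positive, monotone slope
# increments so unimodality holds by construction, and the sup-distance to
# the empirical CDF is minimized by Nelder-Mead with restarts. Yields an
# upper bound that is tight at small n.
dip_oracle <- function(x, restarts = 60, seed = 99) {
  x <- sort(x)
  u <- unique(x)
  m <- length(u)
  if (m == 1) return(0)
  n <- length(x)
  cnt <- cumsum(tabulate(match(x, u), nbins = m)) / n
  c0 <- c(0, cnt[-m])
  set.seed(seed)
  best <- Inf
  for (k in seq_len(m)) {
    nl <- k - 1          # left slope params (between points 1..k)
    nr <- m - k          # right slope params
    obj <- function(par) {
      a0 <- stats::plogis(par[1])              # G at u_1 (left start)
      b_gap <- exp(par[2])                     # modal atom height
      g <- numeric(m)
      if (nl > 0) {
        inc <- exp(par[3:(2 + nl)])            # increasing slope increments
        slopes <- cumsum(inc)
        g[1] <- a0
        for (j in seq_len(nl)) g[j + 1] <- g[j] + slopes[j] * (u[j + 1] - u[j])
      } else g[k] <- a0
      a <- g[k]
      b <- a + b_gap
      if (nr > 0) {
        dec <- exp(par[(3 + nl):(2 + nl + nr)])
        slopes <- rev(cumsum(rev(dec)))        # decreasing slopes
        h <- numeric(m)
        h[k] <- b
        for (j in seq_len(nr)) h[k + j] <- h[k + j - 1] +
            slopes[j] * (u[k + j] - u[k + j - 1])
      } else h <- rep(b, m)
      G_hi <- c(g[seq_len(k - 1)], b, if (nr > 0) h[(k + 1):m])  # G(u_j)
      G_lo <- c(g[seq_len(k - 1)], a, if (nr > 0) h[(k + 1):m])  # G(u_j^-)
      # the last term keeps G a valid CDF (beyond u_m, F = 1 and G >= G(u_m))
      max(c(cnt - G_hi, G_lo - c0, G_hi[m] - 1, 0))
    }
    np <- 2 + nl + nr
    for (r in seq_len(restarts)) {
      par0 <- stats::rnorm(np, mean = -1, sd = 1.5)
      val <- tryCatch(
        stats::optim(par0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))$value,
        error = function(e) Inf)
      if (val < best) best <- val
    }
  }
  best
}
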