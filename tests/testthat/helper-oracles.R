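# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force distances, hypergeometric
# enumeration, exhaustive pair counting, hand product-limit arithmetic.

# all-pairs voxel-center distance map (mm); exact reference for the EDT
brute_force_dmap <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0)
  out <- array(Inf, d)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  for (r in seq_len(nrow(fg))) {
    dd <- sqrt(((idx[, 1] - fg[r, 1]) * spacing[1])^2 +
               ((idx[, 2] - fg[r, 2]) * spacing[2])^2 +
               ((idx[, 3] - fg[r, 3]) * spacing[3])^2)
    out <- pmin(out, array(dd, d))
  }
  out
}

# random sparse binary grid for oracle comparisons
random_grid <- function(dims, n_fg, spacing) {
  a <- array(0L, dims)
  a[sample(prod(dims), n_fg)] <- 1L
  ablmargin::voxel_grid(a, spacing)
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# 2x2 tables with the observed margins
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  sum(probs[probs <= stats::dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

# AUC as the exhaustive Mann-Whitney pair count, ties = 1/2
auc_pair_oracle <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# hand product-limit estimate evaluated after each distinct event time
hand_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  vapply(ts, function(t) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <<- s * (1 - d / n)
    s
  }, numeric(1))
}

# textbook two-group log-rank statistic: sum(O - E)^2 / sum(V)
hand_logrank_stat <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Monte-Carlo fraction of an m-mm shell left uncovered by an offset
# ablation sphere; independent check of the closed-form lens algebra
mc_margin_fraction <- function(rt, ra, d, m, n = 2e5) {
  r3 <- (runif(n) * ((rt + m)^3 - rt^3) + rt^3)^(1 / 3)
  u <- 2 * runif(n) - 1
  th <- runif(n) * 2 * pi
  x <- r3 * u
  y <- r3 * sqrt(1 - u^2) * cos(th)
  z <- r3 * sqrt(1 - u^2) * sin(th)
  100 * mean((x - d)^2 + y^2 + z^2 > ra^2)
}
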