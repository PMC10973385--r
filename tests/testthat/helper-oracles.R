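# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Brute-force minimum RMSD over rotations: staged Euler-angle grid
# search, refined twice around the best cell. Independent of the
# SVD-based superposition it cross-checks.
grid_rmsd_oracle <- function(p, q) {
  p <- sweep(p, 2L, colMeans(p))
  q <- sweep(q, 2L, colMeans(q))
  eval_rmsd <- function(a, b, c) {
    sqrt(mean(rowSums((p %*% t(rot_euler(a, b, c)) - q)^2)))
  }
  best <- c(0, 0, 0); best_val <- Inf
  step <- 20
  grid <- list(a = seq(0, 340, step), b = seq(0, 180, step),
               c = seq(0, 340, step))
  for (a in grid$a) for (b in grid$b) for (c in grid$c) {
    v <- eval_rmsd(a, b, c)
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  for (step in c(4, 0.8, 0.16)) {
    for (a in best[1] + seq(-2, 2) * step)
      for (b in best[2] + seq(-2, 2) * step)
        for (c in best[3] + seq(-2, 2) * step) {
          v <- eval_rmsd(a, b, c)
          if (v < best_val) { best_val <- v; best <- c(a, b, c) }
        }
  }
  best_val
}

# torsion angle by the explicit normal-vector construction (acos
# magnitude + triple-product sign), an independent route to the atan2
# formulation used in the package
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# exhaustive per-row nearest-center check by direct string Hamming
# comparison
nearest_center_oracle <- function(msa, centers, row) {
  d <- vapply(centers, function(cc) {
    sum(utf8ToInt(msa$sequences[cc]) != utf8ToInt(msa$sequences[row]))
  }, numeric(1))
  centers[which.min(d)]
}

# 99% binomial confidence interval for a planted proportion
binom99 <- function(p, n) {
  z <- stats::qnorm(0.995)
  half <- z * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
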