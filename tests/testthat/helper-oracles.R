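# Independent brute-force reference implementations used to cross-check
# the package's vectorized code. These deliberately avoid the package's
# own helpers and stay as close to scalar loops / direct formulas as is
# practical.

random_image <- function(a = 16, b = a, lo = 0, hi = 255) {
  matrix(runif(a * b, lo, hi), a, b)
}

# direct formulas for the PFS planes of a membership value vector
oracle_pfs_planes <- function(mu, alpha) {
  neg <- function(x) alpha^2 * (1 - x) / (alpha^2 * (1 - x) + x)
  m <- 1 - neg(mu)
  n <- neg(m)
  list(mu = m, nu = n, pi = sqrt(pmax(0, 1 - m^2 - n^2)))
}

oracle_pfe <- function(mu, alpha) {
  p <- oracle_pfs_planes(mu, alpha)
  d <- abs(p$mu^2 - p$nu^2)
  mean((p$pi^2 + 1 - d) / (p$pi^2 + 1 + d))
}

oracle_alpha_opt <- function(mu, grid) {
  best <- -Inf
  best_a <- NA_real_
  for (a in grid) {
    e <- oracle_pfe(mu, a)
    if (e > best) {
      best <- e
      best_a <- a
    }
  }
  best_a
}

# edge-replication padding by explicit index arithmetic
oracle_pad <- function(m, bh, bw) {
  ap <- ceiling(nrow(m) / bh) * bh
  bp <- ceiling(ncol(m) / bw) * bw
  out <- matrix(0, ap, bp)
  for (i in seq_len(ap)) for (j in seq_len(bp)) {
    out[i, j] <- m[min(i, nrow(m)), min(j, ncol(m))]
  }
  out
}

oracle_fuse_base <- function(p1, p2, bh, bw) {
  a <- nrow(p1); b <- ncol(p1)
  q1 <- oracle_pad(p1, bh, bw); q2 <- oracle_pad(p2, bh, bw)
  out <- matrix(0, nrow(q1), ncol(q1))
  for (r0 in seq(1, nrow(q1), by = bh)) for (c0 in seq(1, ncol(q1), by = bw)) {
    ri <- r0:(r0 + bh - 1); ci <- c0:(c0 + bw - 1)
    b1 <- q1[ri, ci]; b2 <- q2[ri, ci]
    black <- sum(b1 < 0.5) + sum(b2 < 0.5)
    white <- sum(b1 > 0.5) + sum(b2 > 0.5)
    out[ri, ci] <- if (black > white) pmin(b1, b2)
      else if (white > black) pmax(b1, b2)
      else (b1 + b2) / 2
  }
  out[1:a, 1:b]
}

oracle_block_sf <- function(blk) {
  i <- nrow(blk); j <- ncol(blk)
  rf2 <- 0; cf2 <- 0
  for (q in 1:i) for (r in 2:j) rf2 <- rf2 + (blk[q, r] - blk[q, r - 1])^2
  for (q in 2:i) for (r in 1:j) cf2 <- cf2 + (blk[q, r] - blk[q - 1, r])^2
  sqrt(rf2 / (i * j) + cf2 / (i * j))
}

oracle_fuse_detail <- function(d1, d2, bh, bw, th) {
  a <- nrow(d1); b <- ncol(d1)
  q1 <- oracle_pad(d1, bh, bw); q2 <- oracle_pad(d2, bh, bw)
  out <- matrix(0, nrow(q1), ncol(q1))
  for (r0 in seq(1, nrow(q1), by = bh)) for (c0 in seq(1, ncol(q1), by = bw)) {
    ri <- r0:(r0 + bh - 1); ci <- c0:(c0 + bw - 1)
    b1 <- q1[ri, ci]; b2 <- q2[ri, ci]
    s1 <- oracle_block_sf(b1); s2 <- oracle_block_sf(b2)
    out[ri, ci] <- if (s1 > s2 + th) b1 else if (s2 > s1 + th) b2 else (b1 + b2) / 2
  }
  out[1:a, 1:b]
}

# double-loop metric references
oracle_mean <- function(u) sum(u) / length(u)

oracle_sd <- function(u) {
  m <- oracle_mean(u)
  s <- 0
  for (v in u) s <- s + (v - m)^2
  sqrt(s / length(u))
}

oracle_ag <- function(u) {
  a <- nrow(u); b <- ncol(u)
  s <- 0
  for (p in 1:(a - 1)) for (q in 1:(b - 1)) {
    s <- s + sqrt(((u[p, q] - u[p + 1, q])^2 + (u[p, q] - u[p, q + 1])^2) / 2)
  }
  s / ((a - 1) * (b - 1))
}

oracle_sf <- function(u) {
  a <- nrow(u); b <- ncol(u)
  rf2 <- 0; cf2 <- 0
  for (p in 1:a) for (q in 2:b) rf2 <- rf2 + (u[p, q] - u[p, q - 1])^2
  for (p in 2:a) for (q in 1:b) cf2 <- cf2 + (u[p, q] - u[p - 1, q])^2
  sqrt(rf2 / (a * b) + cf2 / (a * b))
}

oracle_msf <- function(u) {
  a <- nrow(u); b <- ncol(u)
  rf2 <- 0; cf2 <- 0; d1 <- 0; d2 <- 0
  for (p in 1:a) for (q in 2:b) rf2 <- rf2 + (u[p, q] - u[p, q - 1])^2
  for (p in 2:a) for (q in 1:b) cf2 <- cf2 + (u[p, q] - u[p - 1, q])^2
  for (p in 2:a) for (q in 2:b) {
    d1 <- d1 + (u[p, q] - u[p - 1, q - 1])^2
    d2 <- d2 + (u[p - 1, q] - u[p, q - 1])^2
  }
  au <- sqrt(d1 / ((a - 1) * (b - 1)))
  bu <- sqrt(d2 / ((a - 1) * (b - 1)))
  sqrt(rf2 / (a * (b - 1)) + cf2 / ((a - 1) * b) + (au + bu)^2)
}

# MI via entropies of table()-based histograms (a distinct code path)
oracle_entropy <- function(q) {
  p <- as.numeric(table(q)) / length(q)
  -sum(p * log2(p))
}

oracle_mi <- function(u, x, bins = 256) {
  qu <- as.integer(round(pmin(pmax(u, 0), 255) / 255 * (bins - 1)))
  qx <- as.integer(round(pmin(pmax(x, 0), 255) / 255 * (bins - 1)))
  oracle_entropy(qu) + oracle_entropy(qx) - oracle_entropy(paste(qu, qx))
}
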