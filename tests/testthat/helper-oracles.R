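# Independent oracle implementations and small fixture builders used
# across the test files.  These deliberately avoid the package's own code
# paths: quantiles by direct cumulative-weight interpolation written from
# the definition, Benjamini-Hochberg by the literal step-up recursion,
# Spearman by hand-computed mid-ranks.

# Brute-force weighted quantile: order statistics, quantile positions
# C_{k-1} / (W - w_k), linear interpolation done by explicit scan.
oracle_weighted_quantile <- function(x, w, q) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- length(x)
  if (n == 1L) return(x)
  W <- sum(w)
  s <- numeric(n)
  for (k in seq_len(n)) s[k] <- sum(w[seq_len(k - 1)]) / (W - w[k])
  if (q <= s[1]) return(x[1])
  if (q >= s[n]) return(x[n])
  for (k in seq_len(n - 1)) {
    if (q >= s[k] && q <= s[k + 1]) {
      if (s[k + 1] == s[k]) return(x[k])
      return(x[k] + (q - s[k]) / (s[k + 1] - s[k]) * (x[k + 1] - x[k]))
    }
  }
}

# Literal Benjamini-Hochberg step-up: p_(m) unchanged, then
# p*_(k) = min(p*_(k+1), m * p_(k) / k), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  adj[m] <- min(1, ps[m])
  if (m > 1) for (k in (m - 1):1) adj[k] <- min(adj[k + 1], m * ps[k] / k, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson correlation of mid-ranks, ranks computed by explicit counting.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Explicit 12-triangle unit cube mesh (outward winding), area exactly 6.
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertex order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6)    # x = 1, normal +x
  )
  triangle_mesh(v, f)
}

# Icosphere: subdivided icosahedron projected onto a sphere of radius r.
icosphere_mesh <- function(r = 5, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  triangle_mesh(v, f)
}

# Small voxelised ball mask.
ball_mask <- function(r, spacing) {
  n <- as.integer(2 * ceiling(r / spacing) + 6)
  ax <- (seq_len(n) - n / 2 - 0.5) * spacing
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  binary_mask((d2 <= r^2) * 1L, spacing = rep(spacing, 3))
}

rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
}

# A flat single-sheet plate mesh (all normals +z), n x n cells.
flat_plate_mesh <- function(extent = 4, n = 4, z = 0) {
  s <- seq(0, extent, length.out = n + 1)
  verts <- as.matrix(expand.grid(x = s, y = s))
  verts <- cbind(verts, z)
  vid <- function(i, j) (j - 1) * (n + 1) + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    a <- vid(i, j); b <- vid(i + 1, j); c_ <- vid(i + 1, j + 1); d <- vid(i, j + 1)
    f <- rbind(f, c(a, b, c_), c(a, c_, d))
  }
  triangle_mesh(verts, f)
}
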