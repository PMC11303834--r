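# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, direct formula evaluation,
# dense per-voxel linear algebra.

# Brute-force Euclidean distance (in voxels) from each probe voxel (rows
# of `probes`, 1-based array indices) to the nearest TRUE voxel of
# `feature`, by exhaustive scan over the feature set.
brute_force_edt_at <- function(feature, probes) {
  fi <- which(feature, arr.ind = TRUE)
  apply(probes, 1, function(p) {
    sqrt(min(colSums((t(fi) - p)^2)))
  })
}

# Dense (non-separable) structure tensor at one voxel: 3-D Gaussian
# derivative kernels applied by direct summation, then tensor smoothing
# by direct 3-D Gaussian summation, mirror boundary. `at` is (iz, iy, ix).
brute_force_structure_tensor_at <- function(a, at, sigma_g, sigma_s,
                                            voxel_size_um = 1) {
  d <- dim(a)
  reflect <- function(i, n) {
    p <- 2 * n
    i <- ((i - 1) %% p + p) %% p
    ifelse(i >= n, p - 1 - i, i) + 1
  }
  k1 <- function(sigma, order) {
    r <- max(1L, ceiling(3 * sigma))
    x <- (-r):r
    g <- exp(-x^2 / (2 * sigma^2))
    if (order == 0) g / sum(g) else { h <- x * g; h / sum(x * h) }
  }
  grad_at <- function(p) {
    kg0 <- k1(sigma_g, 0); kg1 <- k1(sigma_g, 1)
    r <- (length(kg0) - 1) / 2
    off <- (-r):r
    g <- c(0, 0, 0) # (x, y, z)
    for (oz in off) for (oy in off) for (ox in off) {
      val <- a[reflect(p[1] + oz, d[1]), reflect(p[2] + oy, d[2]),
               reflect(p[3] + ox, d[3])]
      wz <- function(k) k[oz + r + 1]
      g[1] <- g[1] + val * kg1[ox + r + 1] * kg0[oy + r + 1] * kg0[oz + r + 1]
      g[2] <- g[2] + val * kg0[ox + r + 1] * kg1[oy + r + 1] * kg0[oz + r + 1]
      g[3] <- g[3] + val * kg0[ox + r + 1] * kg0[oy + r + 1] * kg1[oz + r + 1]
    }
    g / voxel_size_um
  }
  ks <- k1(sigma_s, 0)
  rs <- (length(ks) - 1) / 2
  offs <- (-rs):rs
  TT <- matrix(0, 3, 3)
  for (oz in offs) for (oy in offs) for (ox in offs) {
    w <- ks[oz + rs + 1] * ks[oy + rs + 1] * ks[ox + rs + 1]
    q <- c(at[1] + oz, at[2] + oy, at[3] + ox)
    q <- c(reflect(q[1], d[1]), reflect(q[2], d[2]), reflect(q[3], d[3]))
    g <- grad_at(q)
    TT <- TT + w * (g %o% g)
  }
  TT
}

# Literal step-down Sidak adjustment, written independently: explicit
# sort, exponent per rank, running maximum, inverse permutation.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    raw <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, raw)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Pooled-variance two-sample t statistic and two-sided p, from the
# textbook formula.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Marching-ray layer chords (voxel units): fine fixed-step scan with
# nearest-neighbor label lookup, no bisection. p0 in 0-based voxel
# coordinates (x, y, z); nrm unit (x, y, z).
marching_ray_oracle <- function(lab, p0, nrm, layer_labels, step = 0.01) {
  d <- dim(lab)
  look <- function(p) {
    i <- round(p) + 1
    if (any(i < 1) || i[1] > d[3] || i[2] > d[2] || i[3] > d[1]) return(-1L)
    lab[i[3], i[2], i[1]]
  }
  counts <- setNames(numeric(length(layer_labels)), layer_labels)
  for (sgn in c(-1, 1)) {
    t <- if (sgn == 1) step else 0
    repeat {
      l <- look(p0 + sgn * t * nrm)
      if (l == -1L || !(l %in% layer_labels)) break
      counts[as.character(l)] <- counts[as.character(l)] + step
      t <- t + step
    }
  }
  unname(counts)
}

# angle (deg) between two direction vectors, sign-invariant
angle_between <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(ca, 1)) * 180 / pi
}
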