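# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Dense regular-sampling oracle for segment length per lattice box:
# midpoint-rule points along the segment, each carrying length L/n.
oracle_box_lengths <- function(p0, p1, origin, s, n = 1e5) {
  t <- (seq_len(n) - 0.5) / n
  x <- p0[1] + t * (p1[1] - p0[1])
  y <- p0[2] + t * (p1[2] - p0[2])
  L <- sqrt(sum((p1 - p0)^2))
  col <- floor((x - origin[1]) / s)
  row <- floor((y - origin[2]) / s)
  key <- paste(col, row, sep = ":")
  tab <- table(key)
  tibble::tibble(
    col = as.integer(sub(":.*", "", names(tab))),
    row = as.integer(sub(".*:", "", names(tab))),
    len = as.numeric(tab) * L / n)
}

# Ray-casting point-in-polygon (even-odd rule), independent of mgcv.
oracle_pip <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Whole-polyline mask clipper: plain per-segment loop splitting at polygon
# edge crossings and keeping pieces whose midpoint passes oracle_pip.
oracle_clip_length <- function(pts, poly) {
  total <- 0
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    d <- q - p
    ts <- c(0, 1)
    for (e in seq_len(n)) {
      ev <- b[e, ] - a[e, ]
      den <- d[1] * ev[2] - d[2] * ev[1]
      if (abs(den) < 1e-14) next
      t <- ((a[e, 1] - p[1]) * ev[2] - (a[e, 2] - p[2]) * ev[1]) / den
      u <- ((a[e, 1] - p[1]) * d[2] - (a[e, 2] - p[2]) * d[1]) / den
      if (t > 0 && t < 1 && u >= 0 && u <= 1) ts <- c(ts, t)
    }
    ts <- sort(ts)
    L <- sqrt(sum(d^2))
    for (k in seq_len(length(ts) - 1)) {
      tm <- (ts[k] + ts[k + 1]) / 2
      if (oracle_pip(p[1] + tm * d[1], p[2] + tm * d[2], poly)) {
        total <- total + (ts[k + 1] - ts[k]) * L
      }
    }
  }
  total
}

# Exhaustive two-sample KS p-value: enumerate all C(n+m, n) assignments of
# the pooled sample and count splits with D at least as large as observed.
oracle_ks_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  ks_d <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf_vals(a, grid) - ecdf_vals(b, grid)))
  }
  ecdf_vals <- function(a, grid) {
    vapply(grid, function(g) mean(a <= g), numeric(1))
  }
  d_obs <- ks_d(x, y)
  combos <- utils::combn(n + m, n)
  count <- 0
  for (j in seq_len(ncol(combos))) {
    a <- pooled[combos[, j]]
    b <- pooled[-combos[, j]]
    if (ks_d(a, b) >= d_obs - 1e-12) count <- count + 1
  }
  count / ncol(combos)
}

# Normal-equation OLS, independent of lm().
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Box-class counts by explicit set operations on occupied box index sets.
oracle_box_classes <- function(grid_gfp, grid_rfp, thr = 0) {
  key <- function(g) {
    g <- g[g$length > thr, ]
    paste(g$section_index, g$row, g$col, sep = ":")
  }
  kg <- key(grid_gfp); kr <- key(grid_rfp)
  c(gfp_only = length(setdiff(kg, kr)),
    rfp_only = length(setdiff(kr, kg)),
    both = length(intersect(kg, kr)))
}

# Cluster-robust (per-fiber) standard error of a statistic computed from
# per-point contributions: fibers are the independent units because points
# along one fiber are strongly autocorrelated.
cluster_se_mean <- function(values, cluster) {
  cm <- tapply(values, cluster, mean)
  nc <- length(cm)
  stats::sd(cm) / sqrt(nc)
}
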