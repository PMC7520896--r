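# Planar geometry primitives: polygon tests, segment clipping against a
# region mask, lattice splitting of segments, and union of adjacent-section
# masks. All coordinates are in mm.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Orient a polygon counter-clockwise (positive signed area).
ensure_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

is_simple_polygon <- function(poly, tol = 1e-12) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges sharing a vertex
    if (!length(js)) next
    hit <- segment_pair_intersect(a[i, ], b[i, ], a[js, , drop = FALSE], b[js, , drop = FALSE], tol)
    if (any(hit$valid)) return(FALSE)
  }
  TRUE
}

points_in_polygon <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  if (nrow(pts) == 0) return(logical(0))
  mgcv::in.out(as.matrix(poly), pts)
}

# Intersection of one segment (p0 -> p1) with many segments (a -> b rows).
# Returns parameters t (along p) and u (along a->b) plus a validity flag.
segment_pair_intersect <- function(p0, p1, a, b, tol = 1e-12) {
  d <- p1 - p0
  e <- b - a
  denom <- d[1] * e[, 2] - d[2] * e[, 1]
  wx <- a[, 1] - p0[1]; wy <- a[, 2] - p0[2]
  t <- (wx * e[, 2] - wy * e[, 1]) / denom
  u <- (wx * d[2] - wy * d[1]) / denom
  valid <- abs(denom) > tol & t >= -tol & t <= 1 + tol & u >= -tol & u <= 1 + tol
  list(t = t, u = u, valid = valid)
}

is_convex_polygon <- function(poly, tol = 1e-12) {
  p <- ensure_ccw(poly)
  n <- nrow(p)
  e <- p[c(2:n, 1), , drop = FALSE] - p
  en <- e[c(2:n, 1), , drop = FALSE]
  cr <- e[, 1] * en[, 2] - e[, 2] * en[, 1]
  all(cr > -tol)
}

# Clip a set of segments to the inside of a simple polygon. `seg` is a
# data.frame/matrix with columns x0, y0, x1, y1; extra columns are carried
# through. Returns a tibble of inside pieces with column `seg_id` indexing
# the input row. Fast path for convex masks: segments with both endpoints
# inside are kept whole without edge tests.
clip_segments_to_polygon <- function(seg, poly) {
  seg <- as.data.frame(seg)
  n <- nrow(seg)
  empty <- tibble(seg_id = integer(0), x0 = numeric(0), y0 = numeric(0),
                  x1 = numeric(0), y1 = numeric(0))
  if (n == 0) return(empty)
  poly <- ensure_ccw(as.matrix(poly))
  p_in <- points_in_polygon(cbind(seg$x0, seg$y0), poly)
  q_in <- points_in_polygon(cbind(seg$x1, seg$y1), poly)

  keep_whole <- integer(0)
  need_split <- seq_len(n)
  if (is_convex_polygon(poly)) {
    keep_whole <- which(p_in & q_in)
    need_split <- which(!(p_in & q_in))
  }

  out <- list()
  if (length(keep_whole)) {
    out[[1]] <- tibble(seg_id = keep_whole,
                       x0 = seg$x0[keep_whole], y0 = seg$y0[keep_whole],
                       x1 = seg$x1[keep_whole], y1 = seg$y1[keep_whole])
  }
  if (length(need_split)) {
    sub <- seg[need_split, , drop = FALSE]
    m <- nrow(sub)
    ne <- nrow(poly)
    a <- poly
    b <- poly[c(2:ne, 1), , drop = FALSE]
    # all segment x edge intersection parameters, vectorized over the
    # m x ne pairing
    si <- rep(seq_len(m), each = ne)
    ax <- rep(a[, 1], m); ay <- rep(a[, 2], m)
    ex <- rep(b[, 1] - a[, 1], m); ey <- rep(b[, 2] - a[, 2], m)
    dx <- (sub$x1 - sub$x0)[si]; dy <- (sub$y1 - sub$y0)[si]
    wx <- ax - sub$x0[si]; wy <- ay - sub$y0[si]
    denom <- dx * ey - dy * ex
    t <- (wx * ey - wy * ex) / denom
    u <- (wx * dy - wy * dx) / denom
    ok <- is.finite(t) & abs(denom) > 1e-14 & t > 0 & t < 1 & u >= 0 & u <= 1
    ids <- c(seq_len(m), seq_len(m), si[ok])
    ts <- c(rep(0, m), rep(1, m), t[ok])
    ord <- order(ids, ts)
    ids <- ids[ord]; ts <- ts[ord]
    same <- ids[-length(ids)] == ids[-1]
    i0 <- which(same)
    t0 <- ts[i0]; t1 <- ts[i0 + 1]
    sid <- ids[i0]
    lenfrac <- t1 - t0
    keep <- lenfrac > 1e-12
    t0 <- t0[keep]; t1 <- t1[keep]; sid <- sid[keep]
    mx <- sub$x0[sid] + (t0 + t1) / 2 * (sub$x1 - sub$x0)[sid]
    my <- sub$y0[sid] + (t0 + t1) / 2 * (sub$y1 - sub$y0)[sid]
    inside <- points_in_polygon(cbind(mx, my), poly)
    t0 <- t0[inside]; t1 <- t1[inside]; sid <- sid[inside]
    if (length(sid)) {
      out[[length(out) + 1]] <- tibble(
        seg_id = need_split[sid],
        x0 = sub$x0[sid] + t0 * (sub$x1 - sub$x0)[sid],
        y0 = sub$y0[sid] + t0 * (sub$y1 - sub$y0)[sid],
        x1 = sub$x0[sid] + t1 * (sub$x1 - sub$x0)[sid],
        y1 = sub$y0[sid] + t1 * (sub$y1 - sub$y0)[sid])
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$seg_id)
}

#' Length of a segment inside an axis-aligned square box
#'
#' Computes the Euclidean length of the intersection of the segment
#' `p0 -> p1` with the half-open box `[x, x + size) x [y, y + size)` by
#' parametric (Liang-Barsky) clipping. The half-open convention assigns a
#' boundary-riding point to the box on its higher-index side, so lengths
#' summed over a lattice of such boxes never double-count.
#'
#' @param p0,p1 Numeric length-2 vectors, the segment endpoints (mm).
#' @param box Numeric length-3 vector `c(x, y, size)`: lower-left corner and
#'   side length of the box (mm).
#' @return Length in mm (0 if the segment misses the box).
#' @examples
#' segment_length_in_box(c(0.010, 0.010), c(0.030, 0.010), c(0, 0, 0.04))
#' @export
segment_length_in_box <- function(p0, p1, box) {
  stopifnot(length(p0) == 2, length(p1) == 2, length(box) == 3)
  if (box[3] <= 0) abort("box size must be > 0")
  if (all(p0 == p1)) abort("segment endpoints must be distinct")
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- box[k]; hi <- box[k] + box[3]
    if (d[k] == 0) {
      if (p0[k] < lo || p0[k] >= hi) return(0)
    } else {
      ta <- (lo - p0[k]) / d[k]
      tb <- (hi - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 >= t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

# Split segments at lattice lines x = ox + k*s, y = oy + k*s and return the
# pieces with their box indices. Fully vectorized; zero-length pieces are
# dropped. `seg` needs columns x0, y0, x1, y1.
split_segments_by_lattice <- function(seg, origin, s) {
  n <- nrow(seg)
  if (n == 0) {
    return(tibble(seg_id = integer(0), col = integer(0), row = integer(0),
                  len = numeric(0)))
  }
  ox <- origin[1]; oy <- origin[2]
  dx <- seg$x1 - seg$x0
  dy <- seg$y1 - seg$y0
  seglen <- sqrt(dx^2 + dy^2)

  cross_params <- function(c0, c1, dc, o) {
    lo <- pmin(c0, c1); hi <- pmax(c0, c1)
    kmin <- ceiling((lo - o) / s + 1e-12)
    kmax <- floor((hi - o) / s - 1e-12)
    cnt <- pmax(0L, as.integer(kmax - kmin + 1))
    cnt[dc == 0] <- 0L
    ids <- rep(seq_len(n), cnt)
    if (!length(ids)) return(list(ids = integer(0), t = numeric(0)))
    ks <- sequence(cnt[cnt > 0]) - 1 + rep(kmin[cnt > 0], cnt[cnt > 0])
    t <- (o + ks * s - c0[ids]) / dc[ids]
    list(ids = ids, t = t)
  }
  cx <- cross_params(seg$x0, seg$x1, dx, ox)
  cy <- cross_params(seg$y0, seg$y1, dy, oy)

  ids <- c(seq_len(n), seq_len(n), cx$ids, cy$ids)
  ts <- pmin(pmax(c(rep(0, n), rep(1, n), cx$t, cy$t), 0), 1)
  ord <- order(ids, ts)
  ids <- ids[ord]; ts <- ts[ord]
  same <- ids[-length(ids)] == ids[-1]
  i0 <- which(same)
  sid <- ids[i0]
  t0 <- ts[i0]; t1 <- ts[i0 + 1]
  keep <- (t1 - t0) > 1e-14
  sid <- sid[keep]; t0 <- t0[keep]; t1 <- t1[keep]
  tm <- (t0 + t1) / 2
  mx <- seg$x0[sid] + tm * dx[sid]
  my <- seg$y0[sid] + tm * dy[sid]
  tibble(seg_id = sid,
         col = as.integer(floor((mx - ox) / s)),
         row = as.integer(floor((my - oy) / s)),
         len = (t1 - t0) * seglen[sid])
}

# Union of two overlapping convex-ish simple polygons (Weiler-Atherton
# walk). Handles the identical, contained, and transversally-overlapping
# cases; disjoint polygons are an error because adjacent-section masks must
# overlap to be merged.
poly_union <- function(A, B, tol = 1e-9) {
  A <- ensure_ccw(as.matrix(A)); B <- ensure_ccw(as.matrix(B))
  # identical vertex cycles (possibly rotated)
  if (nrow(A) == nrow(B)) {
    for (off in seq_len(nrow(B))) {
      Brot <- B[c(off:nrow(B), seq_len(off - 1))[seq_len(nrow(B))], , drop = FALSE]
      if (max(abs(A - Brot)) < tol) return(A)
    }
  }
  nA <- nrow(A); nB <- nrow(B)
  eA0 <- A; eA1 <- A[c(2:nA, 1), , drop = FALSE]
  eB0 <- B; eB1 <- B[c(2:nB, 1), , drop = FALSE]

  inter <- list()
  for (i in seq_len(nA)) {
    hit <- segment_pair_intersect(eA0[i, ], eA1[i, ], eB0, eB1, tol = 1e-14)
    ok <- which(hit$valid & hit$t > tol & hit$t < 1 - tol &
                  hit$u > tol & hit$u < 1 - tol)
    for (j in ok) {
      pt <- eA0[i, ] + hit$t[j] * (eA1[i, ] - eA0[i, ])
      inter[[length(inter) + 1]] <- list(ea = i, ta = hit$t[j],
                                         eb = j, tb = hit$u[j], pt = pt)
    }
  }
  if (!length(inter)) {
    if (all(points_in_polygon(A, B))) return(B)
    if (all(points_in_polygon(B, A))) return(A)
    abort("region masks do not overlap; cannot merge disjoint sections")
  }

  # build node lists for each polygon: original vertices plus intersection
  # nodes ordered along each edge, with cross links between twins
  build_nodes <- function(P, nP, which_poly) {
    nodes <- lapply(seq_len(nP), function(i) {
      list(list(pt = P[i, ], inter_id = NA_integer_))
    })
    for (k in seq_along(inter)) {
      it <- inter[[k]]
      e <- if (which_poly == "A") it$ea else it$eb
      t <- if (which_poly == "A") it$ta else it$tb
      nodes[[e]] <- c(nodes[[e]], list(list(pt = it$pt, inter_id = k, t = t)))
    }
    out <- list()
    for (i in seq_len(nP)) {
      grp <- nodes[[i]]
      if (length(grp) > 1) {
        tvals <- vapply(grp[-1], function(z) z$t, numeric(1))
        grp <- c(grp[1], grp[-1][order(tvals)])
      }
      out <- c(out, grp)
    }
    out
  }
  nodesA <- build_nodes(A, nA, "A")
  nodesB <- build_nodes(B, nB, "B")
  posA <- vapply(nodesA, function(z) z$inter_id, integer(1))
  posB <- vapply(nodesB, function(z) z$inter_id, integer(1))

  # start from a vertex of A strictly outside B
  a_out <- which(!points_in_polygon(A, B))
  if (!length(a_out)) {
    # A's vertices all inside B despite crossings; swap roles
    return(poly_union(B, A, tol))
  }
  start_pt <- A[a_out[1], ]
  cur_list <- "A"; nodes <- nodesA; pos <- posA
  cur <- which(vapply(nodesA, function(z) max(abs(z$pt - start_pt)), numeric(1)) < tol)[1]

  out_pts <- list()
  max_steps <- 2 * (length(nodesA) + length(nodesB)) + 4
  for (step in seq_len(max_steps)) {
    node <- nodes[[cur]]
    out_pts[[length(out_pts) + 1]] <- node$pt
    nxt <- if (cur == length(nodes)) 1L else cur + 1L
    node_n <- nodes[[nxt]]
    if (!is.na(node_n$inter_id)) {
      # jump to the twin intersection node in the other polygon
      k <- node_n$inter_id
      if (cur_list == "A") {
        cur_list <- "B"; nodes <- nodesB; pos <- posB
      } else {
        cur_list <- "A"; nodes <- nodesA; pos <- posA
      }
      cur <- which(pos == k)[1]
    } else {
      cur <- nxt
    }
    if (length(out_pts) > 1 &&
        max(abs(nodes[[cur]]$pt - start_pt)) < tol) break
    if (step == max_steps) abort("polygon union walk failed to close")
  }
  res <- do.call(rbind, out_pts)
  # drop consecutive duplicates
  d <- c(TRUE, rowSums(abs(diff(res))) > tol)
  res <- res[d, , drop = FALSE]
  unname(res)
}
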