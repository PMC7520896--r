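test_that("segment length inside a box follows parametric clipping", {
  expect_equal(segment_length_in_box(c(0.010, 0.010), c(0.030, 0.010),
                                     c(0, 0, 0.04)), 0.020)
  # crossing a shared edge: the two halves conserve the full length
  l_left <- segment_length_in_box(c(0.030, 0.010), c(0.050, 0.010),
                                  c(0, 0, 0.04))
  l_right <- segment_length_in_box(c(0.030, 0.010), c(0.050, 0.010),
                                   c(0.04, 0, 0.04))
  expect_equal(l_left, 0.010)
  expect_equal(l_right, 0.010)
  expect_equal(l_left + l_right, 0.020)
  expect_equal(segment_length_in_box(c(1, 1), c(2, 2), c(0, 0, 0.04)), 0)
  expect_error(segment_length_in_box(c(0, 0), c(1, 1), c(0, 0, 0)), "size")
  expect_error(segment_length_in_box(c(1, 1), c(1, 1), c(0, 0, 1)),
               "distinct")
})

test_that("box lengths of random segments match a dense sampling oracle", {
  set.seed(42)
  s <- 0.04
  for (i in 1:200) {
    p0 <- runif(2, 0, 0.2); p1 <- runif(2, 0, 0.2)
    if (all(p0 == p1)) next
    L <- sqrt(sum((p1 - p0)^2))
    orc <- oracle_box_lengths(p0, p1, c(0, 0), s, n = 1e5)
    got <- vapply(seq_len(nrow(orc)), function(j) {
      segment_length_in_box(p0, p1, c(orc$col[j] * s, orc$row[j] * s, s))
    }, numeric(1))
    expect_lt(max(abs(got - orc$len)) / L, 1e-3)
    expect_equal(sum(got), L, tolerance = 1e-9)
  }
})

test_that("a single short trace lands in a single box with its full length", {
  ds <- tiny_dataset()  # one 0.02 mm trace at (-0.41..-0.39, -3.30)
  g <- build_grid(ds, "GFP")
  expect_equal(nrow(g), 2)  # the trace spans a lattice line at -0.40
  expect_equal(grid_mass(g), 0.02, tolerance = 1e-12)
  # a trace fully inside one box
  tr <- ds$traces
  tr$points[[1]] <- cbind(rc = c(-0.431, -0.411), dv = c(-3.31, -3.31))
  ds2 <- fiber_dataset("m", ds$sections, tr, ds$somata)
  g2 <- build_grid(ds2, "GFP")
  expect_equal(nrow(g2), 1)
  expect_equal(g2$length, 0.02, tolerance = 1e-12)
})

test_that("varicose_only filtering drops non-varicose traces", {
  ds <- tiny_dataset()
  tr <- ds$traces
  tr$varicose <- FALSE
  tr$varicosity_positions <- list(numeric(0))
  ds2 <- fiber_dataset("m", ds$sections, tr, ds$somata)
  expect_equal(nrow(build_grid(ds2, "GFP", varicose_only = TRUE)), 0)
  expect_gt(nrow(build_grid(ds2, "GFP", varicose_only = FALSE)), 0)
  expect_error(build_grid(ds, "CFP"), "channel")
})

test_that("grid mass equals independently clipped varicose length", {
  # mask small enough that fibers genuinely cross its boundary
  cfg <- small_config(mask_semiaxes = c(0.28, 0.35))
  ds <- generate_dataset(cfg, 2)
  for (ch in c("GFP", "RFP")) {
    g <- build_grid(ds, ch)
    tr <- ds$traces[ds$traces$channel == ch & ds$traces$varicose, ]
    oracle <- 0
    for (i in seq_len(nrow(tr))) {
      sec <- ds$sections[ds$sections$index == tr$section_index[i], ]
      oracle <- oracle + oracle_clip_length(tr$points[[i]], sec$mask[[1]])
    }
    expect_lt(abs(grid_mass(g) - oracle) / oracle, 1e-6)
    expect_lt(grid_mass(g), total_trace_length(ds, ch, TRUE))
  }
})

test_that("halving the box size refines boxes without moving mass", {
  ds <- generate_dataset(small_config(), 6)
  g1 <- build_grid(ds, "RFP", box_size = 0.04)
  g2 <- build_grid(ds, "RFP", box_size = 0.02)
  expect_equal(grid_mass(g1), grid_mass(g2), tolerance = 1e-9)
  # each coarse box's mass equals the sum of its four children
  parent <- tibble::tibble(section_index = g2$section_index,
                           row = g2$row %/% 2, col = g2$col %/% 2,
                           length = g2$length)
  agg <- stats::aggregate(length ~ section_index + row + col, parent, sum)
  m <- merge(as.data.frame(g1)[, c("section_index", "row", "col", "length")],
             agg, by = c("section_index", "row", "col"), all = TRUE)
  expect_false(anyNA(m$length.x))
  expect_false(anyNA(m$length.y))
  expect_equal(m$length.x, m$length.y, tolerance = 1e-9)
})

test_that("translating traces by one box size shifts indices only", {
  s <- 0.04
  mask <- square_mask(1.2, c(-0.4, -3.3))
  sec <- tibble::tibble(index = 1L, ml_center = 1.9, thickness = 0.02,
                        mask = list(mask))
  set.seed(8)
  pts <- lapply(1:10, function(i) {
    p <- cbind(rc = -0.4 + cumsum(runif(8, -0.02, 0.02)),
               dv = -3.3 + cumsum(runif(8, -0.02, 0.02)))
    p
  })
  tr <- tibble::tibble(
    trace_id = sprintf("t%02d", 1:10), channel = "GFP", section_index = 1L,
    varicose = TRUE, points = pts,
    varicosity_positions = rep(list(numeric(0)), 10))
  ds <- fiber_dataset("m", sec, tr)
  tr2 <- tr
  tr2$points <- lapply(pts, function(p) p + rep(c(s, 0), each = nrow(p)))
  ds2 <- fiber_dataset("m", sec, tr2)
  g <- build_grid(ds, "GFP")
  g2 <- build_grid(ds2, "GFP")
  expect_equal(nrow(g), nrow(g2))
  o <- order(g$row, g$col); o2 <- order(g2$row, g2$col)
  expect_equal(g2$col[o2], g$col[o] + 1L)
  expect_equal(g2$row[o2], g$row[o])
  expect_equal(g2$length[o2], g$length[o], tolerance = 1e-12)
})

test_that("weighted points preserve mass and hit the mixture mean", {
  ds <- tiny_dataset()
  tr <- ds$traces
  tr$points[[1]] <- cbind(rc = c(-0.431, -0.411), dv = c(-3.31, -3.31))
  ds2 <- fiber_dataset("m", ds$sections, tr, ds$somata)
  wp1 <- grid_to_weighted_points(build_grid(ds2, "GFP"))
  expect_equal(nrow(wp1), 1)
  expect_equal(wp1$weight, 0.02, tolerance = 1e-12)
  expect_equal(wp1$ml, 1.9)

  # 500 fibers: the fiber-level sampling SE of the mean (~sigma/sqrt(n),
  # about 0.006 mm here) must sit well inside the 0.02 mm bound
  cfg <- small_config(n_fibers = c(GFP = 40, RFP = 500),
                      fiber_len_mean = 2.0)
  dss <- generate_dataset(cfg, 4)
  gt <- attr(dss, "ground_truth")
  wp <- grid_to_weighted_points(build_grid(dss, "RFP"))
  expect_equal(sum(wp$weight), grid_mass(build_grid(dss, "RFP")))
  truth <- colMeans(as.matrix(gt$centers[, c("rc", "dv", "ml")]))
  for (ax in c("rc", "dv", "ml")) {
    got <- sum(wp[[ax]] * wp$weight) / sum(wp$weight)
    expect_lt(abs(got - truth[[ax]]), 0.02)
  }
})

test_that("heatmap CSV export round-trips the grid entries", {
  ds <- generate_dataset(small_config(), 3)
  g <- build_grid(ds, "RFP")
  pref <- file.path(withr::local_tempdir(), "hm")
  files <- pallidotrace::export_heatmap(g, pref, write_png = FALSE)
  expect_gt(nrow(files), 0)
  for (sx in unique(g$section_index)[1:3]) {
    m <- as.matrix(utils::read.csv(
      paste0(pref, sprintf("_section%03d.csv", sx)), row.names = 1,
      check.names = FALSE))
    sub <- g[g$section_index == sx, ]
    expect_equal(sum(m), sum(sub$length), tolerance = 1e-9)
    for (j in seq_len(nrow(sub))) {
      expect_equal(m[paste0("dv_row", sub$row[j]),
                     paste0("rc_col", sub$col[j])],
                   sub$length[j], tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # empty grid still leaves a CSV behind
  ds0 <- fiber_dataset("e", ds$sections)
  g0 <- build_grid(ds0, "GFP")
  pref0 <- file.path(withr::local_tempdir(), "empty")
  f0 <- pallidotrace::export_heatmap(g0, pref0, write_png = FALSE)
  expect_true(file.exists(f0$file[1]))
})

test_that("single-entry heatmaps have exactly one positive cell", {
  ds <- tiny_dataset()
  tr <- ds$traces
  tr$points[[1]] <- cbind(rc = c(-0.431, -0.411), dv = c(-3.31, -3.31))
  ds2 <- fiber_dataset("m", ds$sections, tr, ds$somata)
  g <- build_grid(ds2, "GFP")
  pref <- file.path(withr::local_tempdir(), "one")
  export_heatmap(g, pref, write_png = FALSE)
  m <- as.matrix(utils::read.csv(
    paste0(pref, sprintf("_section%03d.csv", g$section_index[1])),
    row.names = 1, check.names = FALSE))
  expect_equal(sum(m > 0), 1)
})
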