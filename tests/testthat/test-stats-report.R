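test_that("center distances pair labeled components across channels", {
  f <- make_fit(c(-0.35, -3.2, 1.9), c(-0.55, -3.4, 1.9))
  d0 <- center_distances(f, f, "m1")
  expect_equal(d0$g1_r1, 0)
  expect_equal(d0$g2_r2, 0)
  expect_equal(d0$g1_g2, d0$r1_r2)
  # 3-4-12 Pythagorean offset
  g <- make_fit(c(-0.35, -3.2, 1.9), c(-0.55, -3.4, 1.9))
  r <- make_fit(c(-0.35, -3.2, 1.9) + c(0.003, 0.004, 0.012),
                c(-0.55, -3.4, 1.9), channel = "RFP")
  expect_equal(center_distances(g, r)$g1_r1, 0.013)
  expect_error(center_distances(g, list(a = 1)), "labeled")
})

test_that("a synthetic cohort shows convergent cross-channel centers", {
  cfg <- synth_config()
  co <- generate_cohort(cfg, 2, seed = 5)
  for (ds in co) {
    fits <- lapply(c(GFP = "GFP", RFP = "RFP"), function(ch) {
      fit_two_gaussians(grid_to_weighted_points(build_grid(ds, ch)),
                        channel = ch)
    })
    d <- center_distances(fits$GFP, fits$RFP, ds$mouse_id)
    expect_lt(d$g1_r1, 0.08)
    expect_lt(d$g2_r2, 0.08)
    expect_gt(d$g1_g2, 0.2)
    expect_gt(d$r1_r2, 0.2)
  }
})

test_that("KS comparison matches exhaustive enumeration on small samples", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- ks_compare(c(0, 0, 0), c(1, 1, 1))
  expect_equal(sep$statistic, 1)
  expect_equal(sep$p_value, oracle_ks_exact(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(sep$p_value, 0.1)  # 2 / choose(6, 3)
  set.seed(14)
  x <- rnorm(5); y <- rnorm(4, 0.5)
  got <- ks_compare(x, y, method = "exact")
  expect_equal(got$p_value, oracle_ks_exact(x, y), tolerance = 1e-12)
  expect_equal(got$method, "exact")
  asym <- ks_compare(x, y, method = "asymptotic")
  expect_equal(asym$method, "asymptotic")
  expect_error(ks_compare(numeric(0), y), "nonempty")
})

test_that("box classification agrees with explicit set operations", {
  ds <- generate_dataset(small_config(), 12)
  gg <- build_grid(ds, "GFP"); gr <- build_grid(ds, "RFP")
  ov <- classify_boxes(gg, gr, mouse_id = "m")
  want <- oracle_box_classes(gg, gr)
  got <- stats::setNames(ov$totals$n_boxes, ov$totals$class)
  expect_equal(got[names(want)], want)
  expect_equal(sum(ov$totals$percentage), 100, tolerance = 1e-9)
  expect_equal(ov$totals$area_mm2, ov$totals$n_boxes * 0.04^2)
  # per-section counts add up to the totals
  expect_equal(sum(ov$per_section$both), got[["both"]])

  # identical grids: everything is "both"
  ov2 <- classify_boxes(gg, gg)
  expect_equal(ov2$totals$percentage[ov2$totals$class == "both"], 100)
  expect_equal(sum(ov2$totals$n_boxes[ov2$totals$class != "both"]), 0)

  # channel swap relabels the classes symmetrically
  ov3 <- classify_boxes(gr, gg)
  t1 <- stats::setNames(ov$totals$n_boxes, ov$totals$class)
  t3 <- stats::setNames(ov3$totals$n_boxes, ov3$totals$class)
  expect_equal(t3[["gfp_only"]], t1[["rfp_only"]])
  expect_equal(t3[["rfp_only"]], t1[["gfp_only"]])
  expect_equal(t3[["both"]], t1[["both"]])
})

test_that("disjoint grids have no shared boxes", {
  mask <- square_mask(2, c(-0.4, -3.3))
  sec <- tibble::tibble(index = 1L, ml_center = 1.9, thickness = 0.02,
                        mask = list(mask))
  tr <- tibble::tibble(
    trace_id = c("g", "r"), channel = c("GFP", "RFP"), section_index = 1L,
    varicose = TRUE,
    points = list(cbind(c(-0.9, -0.7), c(-3.3, -3.3)),
                  cbind(c(0.1, 0.3), c(-3.3, -3.3))),
    varicosity_positions = list(numeric(0), numeric(0)))
  ds <- fiber_dataset("m", sec, tr)
  ov <- classify_boxes(build_grid(ds, "GFP"), build_grid(ds, "RFP"))
  t <- stats::setNames(ov$totals$percentage, ov$totals$class)
  expect_equal(t[["both"]], 0)
  expect_equal(t[["gfp_only"]] + t[["rfp_only"]], 100)
})

test_that("presence thresholds and lattice mismatches are handled", {
  ds <- generate_dataset(small_config(), 13)
  gg <- build_grid(ds, "GFP"); gr <- build_grid(ds, "RFP")
  thr <- stats::median(gg$length)
  ov <- classify_boxes(gg, gr, presence_threshold = thr)
  want <- oracle_box_classes(gg, gr, thr = thr)
  expect_equal(stats::setNames(ov$totals$n_boxes,
                               ov$totals$class)[names(want)], want)
  g2 <- build_grid(ds, "RFP", box_size = 0.02)
  expect_error(classify_boxes(gg, g2), "box size")
})

test_that("cohort overlap percentages aggregate as mean and n-1 SD", {
  mk <- function(pcts, id) {
    structure(list(totals = tibble::tibble(
      class = c("gfp_only", "rfp_only", "both"),
      n_boxes = c(10L, 10L, 10L), area_mm2 = rep(0.016, 3),
      percentage = pcts), per_section = NULL, box_size = 0.04,
      mouse_id = id, presence_threshold = 0), class = "overlap_summary")
  }
  one <- overlap_percentages(list(mk(c(20, 40, 40), "a")))
  expect_true(all(one$single_mouse))
  expect_equal(one$sd_pct, rep(0, 3))
  two <- overlap_percentages(list(mk(c(30, 30, 40), "a"),
                                  mk(c(10, 30, 60), "b")))
  both_row <- two[two$class == "both", ]
  expect_equal(both_row$mean_pct, 50)
  expect_equal(both_row$sd_pct, sqrt((40 - 50)^2 + (60 - 50)^2),
               tolerance = 1e-12)  # n-1 denominator with n = 2
  expect_equal(both_row$sd_pct, 14.142136, tolerance = 1e-6)
})

test_that("projection extents match a brute-force vertex scan", {
  # two vertices 0.5 mm apart in rc
  mask <- square_mask(2, c(-0.4, -3.3))
  sec <- tibble::tibble(index = 1L, ml_center = 1.9, thickness = 0.02,
                        mask = list(mask))
  tr <- tibble::tibble(
    trace_id = "t", channel = "GFP", section_index = 1L, varicose = TRUE,
    points = list(cbind(c(-0.65, -0.15), c(-3.3, -3.3))),
    varicosity_positions = list(numeric(0)))
  ds <- fiber_dataset("m", sec, tr)
  ext <- projection_extent(ds, "GFP")
  expect_equal(ext$extent[ext$axis == "rc"], 0.5)
  expect_equal(ext$extent[ext$axis == "dv"], 0)
  expect_equal(ext$extent[ext$axis == "ml"], 0)

  # near-point-like trace
  tr2 <- tr
  tr2$points[[1]] <- cbind(c(-0.4, -0.4 + 1e-6), c(-3.3, -3.3))
  ds2 <- fiber_dataset("m", sec, tr2)
  expect_lt(max(projection_extent(ds2, "GFP")$extent), 1e-5)

  # no varicose fiber: flagged empty, not an error
  ext_r <- projection_extent(ds, "RFP")
  expect_true(all(ext_r$empty))
  expect_equal(ext_r$extent, rep(0, 3))

  # synthetic mouse with real mask clipping vs brute force
  cfg <- small_config(mask_semiaxes = c(0.30, 0.38))
  dss <- generate_dataset(cfg, 21)
  for (ch in c("GFP", "RFP")) {
    ext_s <- projection_extent(dss, ch)
    trv <- dss$traces[dss$traces$channel == ch & dss$traces$varicose, ]
    mask_s <- dss$sections$mask[[1]]
    xs <- c(); ys <- c(); mls <- c()
    for (i in seq_len(nrow(trv))) {
      p <- trv$points[[i]]
      for (j in seq_len(nrow(p) - 1)) {
        ts <- seq(0, 1, length.out = 50)
        px <- p[j, 1] + ts * (p[j + 1, 1] - p[j, 1])
        py <- p[j, 2] + ts * (p[j + 1, 2] - p[j, 2])
        keep <- oracle_pip(px, py, mask_s)
        if (any(keep)) {
          xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
          mls <- c(mls, dss$sections$ml_center[
            dss$sections$index == trv$section_index[i]])
        }
      }
    }
    # dense sampling slightly underestimates the exact clipped range
    expect_lt(abs(ext_s$extent[1] - diff(range(xs))), 2e-3)
    expect_lt(abs(ext_s$extent[2] - diff(range(ys))), 2e-3)
    expect_equal(ext_s$extent[3], diff(range(mls)))
  }
})

test_that("co-labeling percentages reproduce printed contingency values", {
  expect_equal(contingency_percentage(255, 258), 98.8)
  expect_equal(contingency_percentage(255, 267), 95.5)
  expect_equal(contingency_percentage(99, 104), 95.2)
  expect_equal(contingency_percentage(100, 103), 97.1)
  expect_equal(contingency_percentage(10, 277), 3.6)
  expect_equal(contingency_percentage(0, 10), 0)
  expect_equal(contingency_percentage(1, 16), 6.3)  # half-up rounding
  expect_error(contingency_percentage(5, 0), "total")
  expect_error(contingency_percentage(11, 10), "positive")
})

test_that("pooled distances split within- and cross-channel values", {
  d <- dplyr::bind_rows(
    tibble::tibble(mouse_id = "a", g1_g2 = 0.2, r1_r2 = 0.21,
                   g1_r1 = 0.01, g2_r2 = 0.02),
    tibble::tibble(mouse_id = "b", g1_g2 = 0.19, r1_r2 = 0.22,
                   g1_r1 = 0.03, g2_r2 = 0.01))
  p <- pool_distances(d)
  expect_equal(sort(p$within), sort(c(0.2, 0.21, 0.19, 0.22)))
  expect_equal(sort(p$between), sort(c(0.01, 0.02, 0.03, 0.01)))
})
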