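test_that("a hand-built dataset validates and measures its trace length", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "fiber_dataset")
  expect_equal(nrow(ds$traces), 1)
  expect_equal(total_trace_length(ds), 0.02, tolerance = 1e-12)
})

test_that("container invariants are enforced", {
  ds <- tiny_dataset()
  bad <- ds$traces
  bad$section_index <- 99L
  expect_error(fiber_dataset("x", ds$sections, bad, ds$somata), "t0001")
  bad <- ds$traces
  bad$points[[1]] <- bad$points[[1]][1, , drop = FALSE]
  expect_error(fiber_dataset("x", ds$sections, bad, ds$somata), "< 2 points")
  bad <- ds$traces
  bad$varicose <- FALSE
  expect_error(fiber_dataset("x", ds$sections, bad, ds$somata),
               "varicosity positions")
  bad_soma <- ds$somata
  bad_soma$ml <- -1
  expect_error(fiber_dataset("x", ds$sections, ds$traces, bad_soma),
               "sanity bounds")
  sec <- ds$sections
  sec$thickness <- 0
  expect_error(fiber_dataset("x", sec, ds$traces, ds$somata), "thickness")
})

test_that("to_atlas_point lifts planar points to the section plane", {
  sec <- tibble::tibble(index = 1L, ml_center = 1.9, thickness = 0.02,
                        mask = list(square_mask()))
  p <- to_atlas_point(c(-0.4, -3.0), sec)
  expect_equal(unlist(p), c(rc = -0.4, dv = -3.0, ml = 1.9))
  sec2 <- sec; sec2$ml_center <- 2.1
  p2 <- to_atlas_point(c(-0.4, -3.0), sec2)
  expect_equal(p2$ml, 2.1)
  expect_equal(p[c("rc", "dv")], p2[c("rc", "dv")])
})

test_that("every vertex of a synthetic dataset lifts to a section ml", {
  ds <- generate_dataset(small_config(), 3)
  mls <- ds$sections$ml_center
  for (i in sample(nrow(ds$traces), 20)) {
    sec <- ds$sections[ds$sections$index == ds$traces$section_index[i], ]
    p <- to_atlas_point(ds$traces$points[[i]][1, ], sec)
    expect_true(p$ml %in% mls)
  }
})

test_that("write then read round-trips a dataset losslessly", {
  for (ds in list(tiny_dataset(), generate_dataset(small_config(), 1))) {
    root <- withr::local_tempdir()
    write_dataset(ds, root)
    back <- read_dataset(root)
    expect_equal(back$mouse_id, ds$mouse_id)
    expect_equal(nrow(back$traces), nrow(ds$traces))
    expect_equal(back$somata$rc, ds$somata$rc, tolerance = 1e-11)
    expect_equal(total_trace_length(back), total_trace_length(ds),
                 tolerance = 1e-9)
    expect_equal(back$sections$ml_center, ds$sections$ml_center,
                 tolerance = 1e-11)
    # per-trace geometry and varicosities (align by trace_id)
    ord <- match(ds$traces$trace_id, back$traces$trace_id)
    expect_false(anyNA(ord))
    # absolute 1e-9 mm tolerance (waldo tolerances are relative, which is
    # the wrong scale for sub-micron arc offsets)
    pt_err <- vapply(seq_len(nrow(ds$traces)), function(i) {
      max(abs(back$traces$points[[ord[i]]] - ds$traces$points[[i]]))
    }, numeric(1))
    expect_lt(max(pt_err), 1e-9)
    vp_err <- vapply(seq_len(nrow(ds$traces)), function(i) {
      a <- back$traces$varicosity_positions[[ord[i]]]
      b <- ds$traces$varicosity_positions[[i]]
      if (length(a) != length(b)) return(Inf)
      if (!length(a)) return(0)
      max(abs(a - b))
    }, numeric(1))
    expect_lt(max(vp_err), 1e-9)
  }
})

test_that("an empty-trace dataset writes manifest and soma table only", {
  ds <- tiny_dataset()
  ds2 <- fiber_dataset("empty", ds$sections, NULL, ds$somata)
  root <- withr::local_tempdir()
  write_dataset(ds2, root)
  expect_true(file.exists(file.path(root, "sections.csv")))
  expect_true(file.exists(file.path(root, "somata.csv")))
  expect_false(dir.exists(file.path(root, "traces")))
  back <- read_dataset(root)
  expect_equal(nrow(back$traces), 0)
})

test_that("a one-trace dataset writes exactly one SWC file", {
  root <- withr::local_tempdir()
  write_dataset(tiny_dataset(), root)
  expect_length(list.files(file.path(root, "traces"), pattern = "\\.swc$"), 1)
})

test_that("read errors identify the offending file or line", {
  expect_error(read_dataset(withr::local_tempdir()), "sections.csv")
  root <- withr::local_tempdir()
  write_dataset(tiny_dataset(), root)
  swc <- list.files(file.path(root, "traces"), full.names = TRUE)[1]
  lines <- readLines(swc)
  body <- which(!grepl("^#", lines))
  lines[body[1]] <- sub("^1 2 [^ ]+", "1 2 Inf", lines[body[1]])
  writeLines(lines, swc)
  expect_error(read_dataset(root), paste0("line ", body[1]))
})

test_that("superimposing adjacent sections takes ml midpoints", {
  mask <- square_mask(1, c(-0.4, -3.3))
  sec <- tibble::tibble(index = 1:2, ml_center = c(1.30, 1.32),
                        thickness = 0.02, mask = list(mask, mask))
  tr <- tibble::tibble(
    trace_id = c("a", "b"), channel = c("GFP", "RFP"),
    section_index = 1:2, varicose = TRUE,
    points = list(cbind(c(-0.45, -0.40), c(-3.3, -3.3)),
                  cbind(c(-0.42, -0.38), c(-3.2, -3.2))),
    varicosity_positions = list(numeric(0), numeric(0)))
  ds <- fiber_dataset("m", sec, tr)
  merged <- superimpose_adjacent(ds, list(c(1, 2)))
  expect_equal(nrow(merged$sections), 1)
  expect_equal(merged$sections$ml_center, 1.31)
  expect_equal(merged$sections$thickness, 0.04)
  expect_true(all(merged$traces$section_index == merged$sections$index))
})

test_that("empty pairing leaves the dataset unchanged", {
  ds <- generate_dataset(small_config(), 2)
  attr(ds, "ground_truth") <- NULL
  expect_identical(superimpose_adjacent(ds, list()), ds)
})

test_that("superposition conserves traces and length over many pairs", {
  ds <- generate_dataset(small_config(), 4)
  idx <- ds$sections$index
  pairs <- lapply(seq(1, 12, by = 2), function(i) c(idx[i], idx[i + 1]))
  merged <- superimpose_adjacent(ds, pairs)
  expect_equal(nrow(merged$sections), nrow(ds$sections) - 6)
  expect_equal(nrow(merged$traces), nrow(ds$traces))
  expect_equal(total_trace_length(merged), total_trace_length(ds))
  o <- order(merged$sections$index)
  expect_true(all(diff(merged$sections$ml_center[o]) > 0))
})

test_that("invalid pairings are rejected", {
  ds <- generate_dataset(small_config(), 2)
  expect_error(superimpose_adjacent(ds, list(c(1, 1))), "itself")
  expect_error(superimpose_adjacent(ds, list(c(1, 3))), "adjacent")
  expect_error(superimpose_adjacent(ds, list(c(1, 2), c(2, 3))),
               "at most one pair")
})

test_that("polygon union matches a rasterized membership oracle", {
  set.seed(11)
  sqA <- square_mask(1, c(0, 0))
  sqB <- square_mask(1, c(0.6, 0.4))
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ellA <- cbind(0.5 * cos(th), 0.8 * sin(th))
  ellB <- cbind(0.25 + 0.55 * cos(th), 0.1 + 0.7 * sin(th))
  cases <- list(list(sqA, sqB), list(ellA, ellB), list(sqA, sqA),
                list(square_mask(2), sqA))
  for (cs in cases) {
    u <- pallidotrace:::poly_union(cs[[1]], cs[[2]])
    px <- runif(4000, -1.6, 1.6); py <- runif(4000, -1.6, 1.6)
    want <- oracle_pip(px, py, cs[[1]]) | oracle_pip(px, py, cs[[2]])
    got <- oracle_pip(px, py, u)
    expect_gt(mean(got == want), 0.995)
  }
  expect_error(pallidotrace:::poly_union(sqA, square_mask(1, c(5, 5))),
               "disjoint")
})
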