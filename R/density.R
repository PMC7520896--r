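# Varicose-fiber length density on a 40 um x 40 um lattice per section.
# Mask clipping precedes boxing: a segment partially outside the GPe
# contributes only its inside part. Boxes are half-open [x, x+s) x [y, y+s)
# so shared edges never double-count, and the lattice origin is the mask
# bounding box floored to box_size multiples (a global-grid alignment, so
# the two channels of one section always share a lattice).

#' Build a per-box varicose-fiber-length grid
#'
#' Divides each section's GPe mask into `box_size` x `box_size` boxes and
#' sums the Euclidean length of (by default varicose) fiber polylines of
#' one channel inside each box, after clipping every segment to the
#' section's region mask.
#'
#' @param dataset A [fiber_dataset()].
#' @param channel `"GFP"` or `"RFP"`.
#' @param box_size Box side length in mm (default 0.04 = 40 um).
#' @param varicose_only Restrict to varicose traces (the default, matching
#'   the analysis the grids feed).
#' @return A `density_grid`: a tibble with one row per nonempty box
#'   (columns `section_index`, `row`, `col`, `rc`, `dv`, `ml`, `length`)
#'   and attributes `channel`, `box_size`, `origins` (per-section lattice
#'   origins), and `varicose_only`. `rc`/`dv` are box centers, `ml` the
#'   section's mediolateral center.
#' @export
build_grid <- function(dataset, channel, box_size = 0.04,
                       varicose_only = TRUE) {
  assert_channel(channel)
  assert_scalar_num(box_size, "box_size", 0, strict_min = TRUE)
  if (!inherits(dataset, "fiber_dataset")) validate_dataset(dataset)
  sec <- dataset$sections
  seg <- dataset_segments(dataset, channel, varicose_only)

  origins <- tibble(
    section_index = sec$index,
    ox = vapply(sec$mask, function(m) floor(min(m[, 1]) / box_size) * box_size,
                numeric(1)),
    oy = vapply(sec$mask, function(m) floor(min(m[, 2]) / box_size) * box_size,
                numeric(1)),
    ml_center = sec$ml_center)

  # sections frequently share one mask (hence one lattice origin): clip and
  # lattice-split per unique mask, then aggregate by section
  mask_ids <- vapply(sec$mask, rlang::hash, character(1))
  parts <- list()
  for (mid in unique(mask_ids)) {
    grp <- which(mask_ids == mid)
    s_i <- seg[seg$section_index %in% sec$index[grp], , drop = FALSE]
    if (!nrow(s_i)) next
    clipped <- clip_segments_to_polygon(s_i, sec$mask[[grp[1]]])
    if (!nrow(clipped)) next
    pieces <- split_segments_by_lattice(
      clipped, c(origins$ox[grp[1]], origins$oy[grp[1]]), box_size)
    if (!nrow(pieces)) next
    sect <- s_i$section_index[clipped$seg_id[pieces$seg_id]]
    # aggregate by (section, row, col) through one integer key (rowsum is
    # considerably faster here than a grouped summarise)
    rmin <- min(pieces$row); cmin <- min(pieces$col)
    key <- (sect * 65536 + (pieces$row - rmin)) * 65536 +
      (pieces$col - cmin)
    mass <- rowsum(pieces$len, key)
    k <- as.numeric(rownames(mass))
    agg <- tibble(col = as.integer(k %% 65536 + cmin),
                  row = as.integer((k %/% 65536) %% 65536 + rmin),
                  section_index = as.integer(k %/% (65536^2)),
                  length = as.numeric(mass))
    agg$rc <- origins$ox[grp[1]] + (agg$col + 0.5) * box_size
    agg$dv <- origins$oy[grp[1]] + (agg$row + 0.5) * box_size
    agg$ml <- origins$ml_center[match(agg$section_index,
                                      origins$section_index)]
    parts[[length(parts) + 1]] <- agg
  }
  grid <- if (length(parts)) {
    out <- dplyr::bind_rows(parts)[, c("section_index", "row", "col",
                                       "rc", "dv", "ml", "length")]
    dplyr::arrange(out, .data$section_index, .data$row, .data$col)
  } else {
    tibble(section_index = integer(0), row = integer(0), col = integer(0),
           rc = numeric(0), dv = numeric(0), ml = numeric(0),
           length = numeric(0))
  }
  structure(grid, class = c("density_grid", class(tibble())),
            channel = channel, box_size = box_size, origins = origins,
            varicose_only = varicose_only)
}

#' Convert a density grid to weighted 3D points
#'
#' Places one point at each nonempty box center (`rc`, `dv` box center,
#' `ml` section center) weighted by the box's fiber length; this weighted
#' point set is what the Gaussian-mixture arborization fit consumes. Total
#' weight equals the grid's total length exactly.
#'
#' @param grid A `density_grid` from [build_grid()].
#' @return Tibble with columns `rc`, `dv`, `ml`, `weight`.
#' @export
grid_to_weighted_points <- function(grid) {
  tibble(rc = grid$rc, dv = grid$dv, ml = grid$ml, weight = grid$length)
}

#' Total fiber length held by a grid
#' @param grid A `density_grid`.
#' @return Sum of box lengths (mm).
#' @export
grid_mass <- function(grid) sum(grid$length)

#' Export per-section heatmaps of a density grid
#'
#' Writes, for every section with entries, a CSV matrix of box lengths
#' (rows = dorsoventral box rows, descending; columns = rostrocaudal box
#' columns) and, unless suppressed, a PNG heatmap with a fixed viridis
#' color scale shared across sections (so pseudocolor is comparable).
#'
#' @param grid A `density_grid`.
#' @param path_prefix Path prefix; files are written as
#'   `<prefix>_section<idx>.csv` / `.png`.
#' @param write_png Also write PNG rasters (requires a PNG device).
#' @return Tibble of written file paths, invisibly.
#' @export
export_heatmap <- function(grid, path_prefix, write_png = TRUE) {
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE)
    if (!ok) abort(paste0("cannot write to ", dir))
  }
  secs <- sort(unique(grid$section_index))
  files <- list()
  max_len <- if (nrow(grid)) max(grid$length) else 1
  for (sx in secs) {
    g <- grid[grid$section_index == sx, ]
    rows <- seq(min(g$row), max(g$row))
    cols <- seq(min(g$col), max(g$col))
    m <- matrix(0, length(rows), length(cols),
                dimnames = list(paste0("dv_row", rev(rows)),
                                paste0("rc_col", cols)))
    m[cbind(match(g$row, rev(rows)), match(g$col, cols))] <- g$length
    csv <- paste0(path_prefix, sprintf("_section%03d.csv", sx))
    utils::write.csv(m, csv, row.names = TRUE)
    files[[length(files) + 1]] <- tibble(section_index = sx, file = csv)
    if (write_png) {
      png_path <- paste0(path_prefix, sprintf("_section%03d.png", sx))
      p <- ggplot2::ggplot(g, ggplot2::aes(.data$rc, .data$dv,
                                           fill = .data$length)) +
        ggplot2::geom_tile(width = attr(grid, "box_size"),
                           height = attr(grid, "box_size")) +
        ggplot2::scale_fill_viridis_c(limits = c(0, max_len),
                                      name = "length (mm)") +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "rostrocaudal (mm)", y = "dorsoventral (mm)",
                      title = sprintf("%s varicose-fiber density, section %d",
                                      attr(grid, "channel"), sx))
      ok <- tryCatch({
        ggplot2::ggsave(png_path, p, width = 5, height = 4, dpi = 150,
                        device = grDevices::png)
        TRUE
      }, error = function(e) {
        warn(paste0("PNG export failed (", conditionMessage(e),
                    "); CSV written"))
        FALSE
      })
      if (ok) {
        files[[length(files) + 1]] <- tibble(section_index = sx,
                                             file = png_path)
      }
    }
  }
  if (!length(files) && !length(secs)) {
    # empty grid: still leave an (empty) CSV so downstream tooling finds one
    csv <- paste0(path_prefix, "_empty.csv")
    utils::write.csv(matrix(numeric(0), 0, 0), csv)
    files[[1]] <- tibble(section_index = NA_integer_, file = csv)
  }
  invisible(dplyr::bind_rows(files))
}

#' Heatmap panels of a density grid
#'
#' @param object A `density_grid`.
#' @param sections Optional subset of section indices to plot.
#' @param ... Unused.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, sections = NULL, ...) {
  g <- object
  if (!is.null(sections)) g <- g[g$section_index %in% sections, ]
  ggplot2::ggplot(as_tibble(g),
                  ggplot2::aes(.data$rc, .data$dv, fill = .data$length)) +
    ggplot2::geom_tile(width = attr(object, "box_size"),
                       height = attr(object, "box_size")) +
    ggplot2::scale_fill_viridis_c(name = "length (mm)") +
    ggplot2::facet_wrap(~section_index) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "rostrocaudal (mm)", y = "dorsoventral (mm)")
}
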