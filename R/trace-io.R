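# On-disk layout of a fiber-trace dataset:
#   root/
#     sections.csv   index, ml_center_mm, thickness_mm, mask_file
#     masks/         one CSV polygon (rc_mm, dv_mm) per section
#     somata.csv     soma_id, channel, rc_mm, dv_mm, ml_mm
#     traces/        one SWC file per trace
#     dataset.json   mouse_id + provenance
# SWC files use the standard 7-column format (id type x y z radius parent)
# with x = rc, y = dv, z = section ml_center, all mm. Geometry nodes are
# type 2 (axon) chained through `parent`; varicosities are encoded as
# type-7 leaf nodes (SWC custom-type range) attached to the geometry node
# that starts the segment they lie on, at their interpolated position.

fmt_num <- function(x) sprintf("%.12g", x)

#' Write a fiber-trace dataset to a directory tree
#'
#' Writes the section manifest, mask polygons, soma table and one SWC file
#' per trace. Numbers are written with 12 significant digits so a
#' read-back round trip is lossless to well below 1e-9 mm.
#'
#' @param dataset A [fiber_dataset()].
#' @param root_path Directory to create/fill.
#' @return `root_path`, invisibly.
#' @export
write_dataset <- function(dataset, root_path) {
  validate_dataset(dataset)
  ok <- dir.exists(root_path) || dir.create(root_path, recursive = TRUE)
  if (!ok || file.access(root_path, 2) != 0) {
    abort(paste0("cannot write to ", root_path))
  }
  sec <- dataset$sections
  if (nrow(sec)) dir.create(file.path(root_path, "masks"), showWarnings = FALSE)
  mask_files <- character(nrow(sec))
  for (i in seq_len(nrow(sec))) {
    mask_files[i] <- file.path("masks", sprintf("mask_%03d.csv", sec$index[i]))
    m <- sec$mask[[i]]
    readr::write_csv(tibble(rc_mm = fmt_num(m[, 1]), dv_mm = fmt_num(m[, 2])),
                     file.path(root_path, mask_files[i]))
  }
  readr::write_csv(
    tibble(index = sec$index, ml_center_mm = fmt_num(sec$ml_center),
           thickness_mm = fmt_num(sec$thickness), mask_file = mask_files),
    file.path(root_path, "sections.csv"))
  so <- dataset$somata
  readr::write_csv(
    tibble(soma_id = so$soma_id, channel = so$channel,
           rc_mm = fmt_num(so$rc), dv_mm = fmt_num(so$dv),
           ml_mm = fmt_num(so$ml)),
    file.path(root_path, "somata.csv"))
  jsonlite::write_json(
    list(mouse_id = dataset$mouse_id, provenance = dataset$provenance),
    file.path(root_path, "dataset.json"), auto_unbox = TRUE)

  tr <- dataset$traces
  if (nrow(tr)) {
    tdir <- file.path(root_path, "traces")
    dir.create(tdir, showWarnings = FALSE)
    ml_of <- stats::setNames(sec$ml_center, as.character(sec$index))
    for (i in seq_len(nrow(tr))) {
      write_swc_trace(tr[i, ], ml_of[[as.character(tr$section_index[i])]],
                      file.path(tdir, paste0(tr$trace_id[i], ".swc")))
    }
  }
  invisible(root_path)
}

write_swc_trace <- function(trace_row, ml, path) {
  p <- trace_row$points[[1]]
  v <- trace_row$varicosity_positions[[1]]
  n <- nrow(p)
  hdr <- c(paste0("# trace_id: ", trace_row$trace_id),
           paste0("# channel: ", trace_row$channel),
           paste0("# section_index: ", trace_row$section_index),
           paste0("# varicose: ", trace_row$varicose))
  id <- seq_len(n)
  lines <- sprintf("%d 2 %s %s %s 0.0005 %d", id,
                   fmt_num(p[, 1]), fmt_num(p[, 2]), fmt_num(rep(ml, n)),
                   c(-1L, id[-n]))
  if (length(v)) {
    cl <- cum_arclength(p)
    seg <- pmin(pmax(findInterval(v, cl, rightmost.closed = TRUE), 1L), n - 1L)
    d <- p[seg + 1L, , drop = FALSE] - p[seg, , drop = FALSE]
    u <- d / row_norms(d)
    pos <- p[seg, , drop = FALSE] + (v - cl[seg]) * u
    vid <- n + seq_along(v)
    lines <- c(lines, sprintf("%d 7 %s %s %s 0.0005 %d", vid,
                              fmt_num(pos[, 1]), fmt_num(pos[, 2]),
                              fmt_num(rep(ml, length(v))), seg))
  }
  writeLines(c(hdr, lines), path)
}

read_swc_trace <- function(path) {
  raw <- readLines(path)
  meta_val <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), raw, value = TRUE)
    if (!length(ln)) abort(paste0("SWC file ", path, " lacks '", key, "' header"))
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  body_idx <- which(!grepl("^\\s*(#|$)", raw))
  fields <- strsplit(trimws(raw[body_idx]), "\\s+")
  bad_ncol <- which(lengths(fields) != 7)
  if (length(bad_ncol)) {
    abort(paste0("malformed SWC line ", body_idx[bad_ncol[1]], " in ", path))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  bad <- which(!is.finite(m[, 3]) | !is.finite(m[, 4]) | !is.finite(m[, 5]))
  if (length(bad)) {
    abort(paste0("non-finite coordinate at line ", body_idx[bad[1]],
                 " of ", path))
  }
  geom <- m[m[, 2] != 7, , drop = FALSE]
  vari <- m[m[, 2] == 7, , drop = FALSE]
  p <- geom[, 3:4, drop = FALSE]
  colnames(p) <- c("rc", "dv")
  vpos <- numeric(0)
  if (nrow(vari)) {
    cl <- cum_arclength(p)
    id2row <- match(vari[, 7], geom[, 1])
    if (anyNA(id2row)) abort(paste0("varicosity with unknown parent in ", path))
    vpos <- sort(cl[id2row] +
                   row_norms(vari[, 3:4, drop = FALSE] -
                               p[id2row, , drop = FALSE]))
  }
  tibble(trace_id = meta_val("trace_id"),
         channel = meta_val("channel"),
         section_index = as.integer(meta_val("section_index")),
         varicose = as.logical(meta_val("varicose")),
         points = list(p),
         varicosity_positions = list(vpos))
}

#' Read a fiber-trace dataset from a directory tree
#'
#' Inverse of [write_dataset()]. Validates all container invariants
#' (coordinate sanity bounds, mask simplicity, sorted varicosity positions,
#' section references) on read.
#'
#' @param root_path Directory written by [write_dataset()] or following the
#'   same layout.
#' @return A [fiber_dataset()].
#' @export
read_dataset <- function(root_path) {
  manifest <- file.path(root_path, "sections.csv")
  if (!file.exists(manifest)) {
    abort(paste0("missing section manifest: ", manifest))
  }
  sec_raw <- readr::read_csv(manifest, show_col_types = FALSE,
                             col_types = "indc")
  masks <- lapply(sec_raw$mask_file, function(f) {
    mf <- file.path(root_path, f)
    if (!file.exists(mf)) abort(paste0("missing mask file: ", mf))
    m <- as.matrix(readr::read_csv(mf, show_col_types = FALSE,
                                   col_types = "dd"))
    colnames(m) <- c("rc", "dv")
    m
  })
  sections <- tibble(index = as.integer(sec_raw$index),
                     ml_center = sec_raw$ml_center_mm,
                     thickness = sec_raw$thickness_mm,
                     mask = masks)

  soma_path <- file.path(root_path, "somata.csv")
  if (!file.exists(soma_path)) abort(paste0("missing soma table: ", soma_path))
  so_raw <- readr::read_csv(soma_path, show_col_types = FALSE,
                            col_types = "ccddd")
  somata <- tibble(soma_id = so_raw$soma_id, channel = so_raw$channel,
                   rc = so_raw$rc_mm, dv = so_raw$dv_mm, ml = so_raw$ml_mm)

  meta <- list(mouse_id = basename(root_path), provenance = "")
  jpath <- file.path(root_path, "dataset.json")
  if (file.exists(jpath)) meta <- jsonlite::read_json(jpath)

  tdir <- file.path(root_path, "traces")
  traces <- NULL
  if (dir.exists(tdir)) {
    files <- sort(list.files(tdir, pattern = "\\.swc$", full.names = TRUE))
    if (length(files)) traces <- dplyr::bind_rows(lapply(files, read_swc_trace))
  }
  fiber_dataset(meta$mouse_id, sections, traces, somata,
                provenance = meta$provenance %||% "")
}

#' Superimpose adjacent parasagittal sections
#'
#' Merges explicitly given pairs of physically adjacent sections into single
#' sections, emulating the overlay of a GFP-traced and an RFP-traced
#' neighboring section. Each merged section takes the midpoint of the
#' pair's `ml_center`s, the sum of their thicknesses, and the union of
#' their mask polygons; traces from both members are reassigned to the
#' merged section. Unpaired sections pass through unchanged.
#'
#' @param dataset A [fiber_dataset()].
#' @param pairing A two-column matrix/data frame (or list of length-2
#'   vectors) of section index pairs with `|difference| == 1`.
#' @return A [fiber_dataset()] with merged sections.
#' @export
superimpose_adjacent <- function(dataset, pairing) {
  validate_dataset(dataset)
  if (is.list(pairing) && !is.data.frame(pairing)) {
    pairing <- do.call(rbind, pairing)
  }
  if (is.null(pairing) || length(pairing) == 0) return(dataset)
  pairing <- as.matrix(pairing)
  if (ncol(pairing) != 2) abort("pairing must have two columns")
  if (any(pairing[, 1] == pairing[, 2])) {
    abort("cannot pair a section with itself")
  }
  if (any(abs(pairing[, 1] - pairing[, 2]) != 1)) {
    abort("paired sections must be physically adjacent (|index diff| == 1)")
  }
  if (anyDuplicated(as.vector(pairing))) {
    abort("each section may appear in at most one pair")
  }
  sec <- dataset$sections
  if (!all(as.vector(pairing) %in% sec$index)) {
    abort("pairing references unknown section indices")
  }
  remap <- stats::setNames(sec$index, as.character(sec$index))
  keep <- rep(TRUE, nrow(sec))
  for (k in seq_len(nrow(pairing))) {
    ia <- which(sec$index == pairing[k, 1])
    ib <- which(sec$index == pairing[k, 2])
    tgt <- min(ia, ib)
    oth <- max(ia, ib)
    sec$ml_center[tgt] <- (sec$ml_center[ia] + sec$ml_center[ib]) / 2
    sec$thickness[tgt] <- sec$thickness[ia] + sec$thickness[ib]
    sec$mask[[tgt]] <- poly_union(sec$mask[[ia]], sec$mask[[ib]])
    keep[oth] <- FALSE
    remap[as.character(sec$index[c(ia, ib)])] <- sec$index[tgt]
  }
  sec <- sec[keep, ]
  tr <- dataset$traces
  if (nrow(tr)) {
    tr$section_index <- unname(remap[as.character(tr$section_index)])
  }
  fiber_dataset(dataset$mouse_id, sec, tr, dataset$somata,
                provenance = dataset$provenance)
}

#' Lift a planar section point to atlas coordinates
#'
#' A traced vertex lives in its section's parasagittal plane; its atlas
#' position is the in-plane `(rc, dv)` pair with `ml` given by the
#' section's mediolateral center.
#'
#' @param planar_point Length-2 numeric `(rc, dv)` in mm.
#' @param section A one-row slice of a dataset's `sections` table (or any
#'   list with an `ml_center` element).
#' @return A one-row tibble with columns `rc`, `dv`, `ml`.
#' @export
to_atlas_point <- function(planar_point, section) {
  stopifnot(length(planar_point) == 2)
  ml <- if (is.data.frame(section)) section$ml_center[[1]] else section$ml_center
  tibble(rc = planar_point[1], dv = planar_point[2], ml = ml)
}
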