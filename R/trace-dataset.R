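# The fiber_dataset container: parasagittal sections with GPe region masks,
# traced fiber polylines with varicosity annotations, and labeled somata.

#' Construct a fiber-trace dataset
#'
#' Bundles the three tables that describe one mouse's tracing data:
#' `sections` (parasagittal section geometry with a GPe mask polygon per
#' section), `traces` (2D fiber polylines with per-trace channel, varicosity
#' flag and bouton arc-length positions), and `somata` (3D positions of
#' labeled cell bodies). All coordinates are mm from bregma; `rc` is
#' positive rostrally, `dv` positive dorsally, `ml` is distance from the
#' midline.
#'
#' @param mouse_id Character scalar identifying the animal.
#' @param sections Tibble with columns `index` (integer), `ml_center` (mm),
#'   `thickness` (mm), and `mask` (list column of 2-column `rc`,`dv`
#'   matrices, each a simple polygon with nonzero area).
#' @param traces Tibble with columns `trace_id`, `channel` (`"GFP"` or
#'   `"RFP"`), `section_index`, `varicose` (logical), `points` (list column
#'   of 2-column `rc`,`dv` matrices with at least 2 rows), and
#'   `varicosity_positions` (list column of sorted arc-length offsets in
#'   `[0, trace length]`; empty when `varicose` is `FALSE`).
#' @param somata Tibble with columns `soma_id`, `channel`, `rc`, `dv`, `ml`.
#' @param provenance Free-text metadata (e.g. generator config hash).
#' @return An object of class `fiber_dataset`.
#' @export
fiber_dataset <- function(mouse_id, sections, traces = NULL, somata = NULL,
                          provenance = "") {
  if (is.null(traces)) {
    traces <- tibble(trace_id = character(0), channel = character(0),
                     section_index = integer(0), varicose = logical(0),
                     points = list(), varicosity_positions = list())
  }
  if (is.null(somata)) {
    somata <- tibble(soma_id = character(0), channel = character(0),
                     rc = numeric(0), dv = numeric(0), ml = numeric(0))
  }
  ds <- structure(
    list(mouse_id = as.character(mouse_id),
         sections = as_tibble(sections),
         traces = as_tibble(traces),
         somata = as_tibble(somata),
         provenance = as.character(provenance)),
    class = "fiber_dataset")
  validate_dataset(ds)
  ds
}

validate_point3 <- function(rc, dv, ml, what = "position") {
  bad <- !is.finite(rc) | !is.finite(dv) | !is.finite(ml)
  if (any(bad)) abort(paste0("non-finite coordinate in ", what))
  if (any(abs(rc) > 10) || any(abs(dv) > 10) || any(ml < 0) || any(ml > 10)) {
    abort(paste0(what, " outside mouse-brain sanity bounds ",
                 "(|rc| <= 10, |dv| <= 10, 0 <= ml <= 10 mm)"))
  }
  invisible(TRUE)
}

validate_dataset <- function(ds) {
  sec <- ds$sections
  if (nrow(sec)) {
    if (any(sec$thickness <= 0)) abort("section thickness must be > 0")
    if (anyDuplicated(sec$index)) abort("duplicate section index")
    o <- order(sec$index)
    if (any(diff(sec$ml_center[o]) <= 0)) {
      abort("section ml_centers must strictly increase with index")
    }
    # sections often share one mask object; validate each distinct mask once
    mask_ids <- vapply(sec$mask, rlang::hash, character(1))
    for (i in which(!duplicated(mask_ids))) {
      m <- sec$mask[[i]]
      if (is.null(m) || nrow(m) < 3) {
        abort(paste0("mask of section ", sec$index[i], " needs >= 3 vertices"))
      }
      if (abs(polygon_area(m)) < 1e-12) {
        abort(paste0("mask of section ", sec$index[i], " has zero area"))
      }
      if (!is_simple_polygon(m)) {
        abort(paste0("mask of section ", sec$index[i], " is self-intersecting"))
      }
    }
  }
  tr <- ds$traces
  if (nrow(tr)) {
    if (!all(tr$channel %in% CHANNELS)) {
      abort("trace channels must be GFP or RFP")
    }
    missing_sec <- !tr$section_index %in% sec$index
    if (any(missing_sec)) {
      abort(paste0("traces reference unknown sections: ",
                   paste(tr$trace_id[missing_sec], collapse = ", ")))
    }
    # vectorized over all traces: flatten points once, compute all segment
    # lengths in one pass, then index back per trace
    nr <- vapply(tr$points, nrow, integer(1))
    if (any(nr < 2)) {
      abort(paste0("trace ", tr$trace_id[which(nr < 2)[1]], " has < 2 points"))
    }
    allpts <- do.call(rbind, tr$points)
    if (!all(is.finite(allpts))) {
      bad <- which(vapply(tr$points, function(p) !all(is.finite(p)),
                          logical(1)))[1]
      abort(paste0("non-finite coordinate in trace ", tr$trace_id[bad]))
    }
    idx <- rep.int(seq_len(nrow(tr)), nr)
    first <- c(TRUE, idx[-1] != idx[-length(idx)])
    last <- c(idx[-1] != idx[-length(idx)], TRUE)
    d <- allpts[!first, , drop = FALSE] - allpts[!last, , drop = FALSE]
    slen <- sqrt(rowSums(d^2))
    if (any(slen == 0)) {
      bad <- rep.int(seq_len(nrow(tr)), nr - 1L)[which(slen == 0)[1]]
      abort(paste0("trace ", tr$trace_id[bad],
                   " has repeated consecutive points"))
    }
    totlen <- as.numeric(rowsum(slen, rep.int(seq_len(nrow(tr)), nr - 1L)))
    nvp <- lengths(tr$varicosity_positions)
    if (any(!tr$varicose & nvp > 0)) {
      bad <- which(!tr$varicose & nvp > 0)[1]
      abort(paste0("non-varicose trace ", tr$trace_id[bad],
                   " carries varicosity positions"))
    }
    for (i in which(nvp > 0)) {
      v <- tr$varicosity_positions[[i]]
      if (is.unsorted(v)) abort(paste0("unsorted varicosity positions in ",
                                       tr$trace_id[i]))
      if (v[1] < 0 || v[length(v)] > totlen[i] + 1e-9) {
        abort(paste0("varicosity position outside [0, length] in ",
                     tr$trace_id[i]))
      }
    }
  }
  so <- ds$somata
  if (nrow(so)) {
    if (!all(so$channel %in% CHANNELS)) abort("soma channels must be GFP or RFP")
    validate_point3(so$rc, so$dv, so$ml, "soma position")
  }
  invisible(ds)
}

#' @export
print.fiber_dataset <- function(x, ...) {
  cat("<fiber_dataset> mouse", x$mouse_id, "\n")
  cat("  sections:", nrow(x$sections), " traces:", nrow(x$traces),
      " somata:", nrow(x$somata), "\n")
  if (nrow(x$traces)) {
    tl <- vapply(x$traces$points, polyline_length, numeric(1))
    by_ch <- tapply(tl, x$traces$channel, sum)
    cat("  total trace length (mm):",
        paste(names(by_ch), round(by_ch, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total polyline length of a dataset's traces
#'
#' @param dataset A [fiber_dataset()].
#' @param channel Optional channel filter (`"GFP"` or `"RFP"`).
#' @param varicose_only Restrict to varicose traces.
#' @return Total length in mm.
#' @export
total_trace_length <- function(dataset, channel = NULL, varicose_only = FALSE) {
  tr <- dataset$traces
  if (!is.null(channel)) tr <- tr[tr$channel == assert_channel(channel), ]
  if (varicose_only) tr <- tr[tr$varicose, ]
  if (!nrow(tr)) return(0)
  sum(vapply(tr$points, polyline_length, numeric(1)))
}

# Flatten a dataset's traces into one segment table (one row per polyline
# segment) for gridding and extent computations.
dataset_segments <- function(dataset, channel = NULL, varicose_only = FALSE) {
  tr <- dataset$traces
  if (!is.null(channel)) tr <- tr[tr$channel == assert_channel(channel), ]
  if (varicose_only) tr <- tr[tr$varicose, ]
  if (!nrow(tr)) {
    return(tibble(trace_id = character(0), section_index = integer(0),
                  x0 = numeric(0), y0 = numeric(0),
                  x1 = numeric(0), y1 = numeric(0)))
  }
  nseg <- vapply(tr$points, function(p) nrow(p) - 1L, integer(1))
  pts <- do.call(rbind, tr$points)
  idx <- rep(seq_len(nrow(tr)), nseg + 1L)
  first <- c(TRUE, idx[-1] != idx[-length(idx)])
  last <- c(idx[-1] != idx[-length(idx)], TRUE)
  tibble(trace_id = rep(tr$trace_id, nseg),
         section_index = rep(tr$section_index, nseg),
         x0 = pts[!last, 1], y0 = pts[!last, 2],
         x1 = pts[!first, 1], y1 = pts[!first, 2])
}

#' Interpolated 3D positions of all varicosities
#'
#' Walks each varicose trace and converts bouton arc-length offsets to
#' atlas positions (in-plane interpolation; `ml` is the section center).
#'
#' @param dataset A [fiber_dataset()].
#' @param channel Optional channel filter.
#' @return Tibble with columns `trace_id`, `channel`, `rc`, `dv`, `ml`.
#' @export
varicosity_points <- function(dataset, channel = NULL) {
  tr <- dataset$traces
  if (!is.null(channel)) tr <- tr[tr$channel == assert_channel(channel), ]
  ml_of <- stats::setNames(dataset$sections$ml_center,
                           as.character(dataset$sections$index))
  nvp <- lengths(tr$varicosity_positions)
  tr <- tr[nvp > 0, , drop = FALSE]
  if (!nrow(tr)) {
    return(tibble(trace_id = character(0), channel = character(0),
                  rc = numeric(0), dv = numeric(0), ml = numeric(0)))
  }
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    p <- tr$points[[i]]
    v <- tr$varicosity_positions[[i]]
    cl <- cum_arclength(p)
    seg <- pmin(pmax(findInterval(v, cl, rightmost.closed = TRUE), 1L),
                nrow(p) - 1L)
    d <- p[seg + 1L, , drop = FALSE] - p[seg, , drop = FALSE]
    u <- d / row_norms(d)
    pos <- p[seg, , drop = FALSE] + (v - cl[seg]) * u
    out[[i]] <- tibble(trace_id = tr$trace_id[i], channel = tr$channel[i],
                       rc = pos[, 1], dv = pos[, 2],
                       ml = ml_of[[as.character(tr$section_index[i])]])
  }
  dplyr::bind_rows(out)
}
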