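# Convergence statistics: Euclidean distances between labeled arborization
# centers, exact two-sample Kolmogorov-Smirnov comparison, projection-area
# overlap classification, projection extents, and co-labeling percentages.

#' Euclidean distances between labeled arborization centers
#'
#' Given the GFP (direct-pathway) and RFP (indirect-pathway) fits of one
#' mouse, computes the within-channel distances G1-G2 and R1-R2 and the
#' cross-channel distances G1-R1 and G2-R2, pairing arborization #1 with #1
#' and #2 with #2.
#'
#' @param fit_gfp,fit_rfp `arborization_fit` objects.
#' @param mouse_id Optional identifier for the output row.
#' @return One-row tibble with columns `mouse_id`, `g1_g2`, `r1_r2`,
#'   `g1_r1`, `g2_r2` (mm).
#' @export
center_distances <- function(fit_gfp, fit_rfp, mouse_id = NA_character_) {
  for (f in list(fit_gfp, fit_rfp)) {
    if (!inherits(f, "arborization_fit") ||
        !identical(names(f$components), c("#1", "#2"))) {
      abort("center_distances needs labeled arborization_fit objects")
    }
  }
  m <- function(f, lb) f$components[[lb]]$mean
  d <- function(a, b) sqrt(sum((a - b)^2))
  tibble(mouse_id = mouse_id,
         g1_g2 = d(m(fit_gfp, "#1"), m(fit_gfp, "#2")),
         r1_r2 = d(m(fit_rfp, "#1"), m(fit_rfp, "#2")),
         g1_r1 = d(m(fit_gfp, "#1"), m(fit_rfp, "#1")),
         g2_r2 = d(m(fit_gfp, "#2"), m(fit_rfp, "#2")))
}

#' Pool a cohort's distances into within- and cross-channel samples
#'
#' The two within-channel distances per mouse (G1-G2, R1-R2) form one
#' sample and the two cross-channel distances (G1-R1, G2-R2) the other,
#' pooled across mice (2n values each for n mice).
#'
#' @param distances Tibble of [center_distances()] rows.
#' @return List with elements `within` and `between`.
#' @export
pool_distances <- function(distances) {
  list(within = c(distances$g1_g2, distances$r1_r2),
       between = c(distances$g1_r1, distances$g2_r2))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the within-channel and cross-channel distance samples. The
#' exact p-value (via the Smirnov distribution over orderings, ties
#' handled) is used whenever `n * m <= 10^4` -- at the study's scale (12 vs
#' 12 values for 6 mice) the asymptotic approximation is unreliable.
#'
#' @param within_sample,between_sample Nonempty numeric vectors.
#' @param method `"auto"` (exact when `n*m <= 1e4`), `"exact"`, or
#'   `"asymptotic"`.
#' @return One-row tibble: `statistic` (D), `p_value`, `method`,
#'   `n_within`, `n_between`.
#' @export
ks_compare <- function(within_sample, between_sample,
                       method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (!length(within_sample) || !length(between_sample)) {
    abort("both samples must be nonempty")
  }
  n <- length(within_sample); m <- length(between_sample)
  exact <- switch(method, auto = n * m <= 1e4, exact = TRUE,
                  asymptotic = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(within_sample, between_sample, exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = if (exact) "exact" else "asymptotic",
         n_within = n, n_between = m)
}

#' Classify lattice boxes by channel presence
#'
#' Binarizes the two channels' density grids box by box: a box whose fiber
#' length exceeds `presence_threshold` in exactly one channel is GFP-only
#' or RFP-only, in both channels "both"; boxes below threshold in both are
#' excluded. Grids must share box size and lattice origins (guaranteed when
#' both were built from the same dataset).
#'
#' @param grid_gfp,grid_rfp `density_grid`s of the two channels.
#' @param presence_threshold Minimum length (mm) for presence (default 0,
#'   i.e. strictly positive length counts).
#' @param mouse_id Optional identifier.
#' @return An `overlap_summary`: list with `per_section` counts/areas,
#'   `totals` (counts, areas in mm^2, percentages of occupied boxes),
#'   `box_size`, and `mouse_id`.
#' @export
classify_boxes <- function(grid_gfp, grid_rfp, presence_threshold = 0,
                           mouse_id = NA_character_) {
  bs <- attr(grid_gfp, "box_size")
  if (!isTRUE(all.equal(bs, attr(grid_rfp, "box_size")))) {
    abort("grids have different box sizes")
  }
  og <- attr(grid_gfp, "origins"); orf <- attr(grid_rfp, "origins")
  shared <- dplyr::inner_join(og, orf, by = "section_index",
                              suffix = c("_g", "_r"))
  if (!isTRUE(all.equal(shared$ox_g, shared$ox_r)) ||
      !isTRUE(all.equal(shared$oy_g, shared$oy_r))) {
    abort("grids are on mismatched lattices")
  }
  if (!setequal(og$section_index, orf$section_index)) {
    abort("grids cover different section sets")
  }
  g <- as_tibble(grid_gfp)[, c("section_index", "row", "col", "length")]
  r <- as_tibble(grid_rfp)[, c("section_index", "row", "col", "length")]
  j <- dplyr::full_join(g, r, by = c("section_index", "row", "col"),
                        suffix = c("_gfp", "_rfp"))
  pg <- !is.na(j$length_gfp) & j$length_gfp > presence_threshold
  pr <- !is.na(j$length_rfp) & j$length_rfp > presence_threshold
  j$class <- dplyr::case_when(pg & pr ~ "both",
                              pg ~ "gfp_only",
                              pr ~ "rfp_only",
                              TRUE ~ NA_character_)
  j <- j[!is.na(j$class), ]
  per_section <- j |>
    dplyr::count(.data$section_index, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("gfp_only", "rfp_only", "both")) {
    if (!cl %in% names(per_section)) per_section[[cl]] <- 0L
  }
  per_section <- per_section[, c("section_index", "gfp_only", "rfp_only", "both")]
  per_section <- dplyr::mutate(
    per_section,
    area_gfp_only = .data$gfp_only * bs^2,
    area_rfp_only = .data$rfp_only * bs^2,
    area_both = .data$both * bs^2)
  counts <- c(gfp_only = sum(per_section$gfp_only),
              rfp_only = sum(per_section$rfp_only),
              both = sum(per_section$both))
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts * NA_real_
  structure(list(per_section = per_section,
                 totals = tibble(class = names(counts),
                                 n_boxes = as.integer(counts),
                                 area_mm2 = unname(counts) * bs^2,
                                 percentage = unname(pct)),
                 box_size = bs, mouse_id = mouse_id,
                 presence_threshold = presence_threshold),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>", if (!is.na(x$mouse_id)) x$mouse_id else "", "\n")
  print(x$totals)
  invisible(x)
}

#' Cohort-level projection-area percentages
#'
#' Aggregates per-mouse box-class percentages as an unweighted mean and SD
#' (n-1 denominator) across mice, the convention used for cohort summaries
#' of the three-class (RFP-only / GFP-only / both) area breakdown.
#'
#' @param cohort_summaries List of `overlap_summary` objects (>= 1 mouse).
#' @return Tibble with columns `class`, `mean_pct`, `sd_pct`, `n_mice`,
#'   `single_mouse` (flag: SD reported as 0 for a single mouse).
#' @export
overlap_percentages <- function(cohort_summaries) {
  if (inherits(cohort_summaries, "overlap_summary")) {
    cohort_summaries <- list(cohort_summaries)
  }
  stopifnot(length(cohort_summaries) >= 1)
  per <- dplyr::bind_rows(lapply(cohort_summaries, function(s) {
    out <- s$totals[, c("class", "percentage")]
    out$mouse_id <- s$mouse_id
    out
  }))
  single <- length(cohort_summaries) == 1
  per |>
    dplyr::summarise(
      mean_pct = mean(.data$percentage),
      sd_pct = if (single) 0 else stats::sd(.data$percentage),
      n_mice = dplyr::n(),
      .by = "class") |>
    dplyr::mutate(single_mouse = single)
}

#' Per-axis extent of a channel's varicose projection field
#'
#' Max minus min over mask-clipped varicose-trace vertices for the
#' in-plane axes; the mediolateral extent spans the section centers that
#' carry clipped varicose fiber.
#'
#' @param dataset A [fiber_dataset()].
#' @param channel `"GFP"` or `"RFP"`.
#' @return Tibble with columns `channel`, `axis`, `extent` (mm), `empty`
#'   (TRUE with zero extents when the channel has no varicose fiber inside
#'   the masks).
#' @export
projection_extent <- function(dataset, channel) {
  assert_channel(channel)
  sec <- dataset$sections
  seg <- dataset_segments(dataset, channel, varicose_only = TRUE)
  rng_rc <- c(Inf, -Inf); rng_dv <- c(Inf, -Inf); mls <- numeric(0)
  for (i in seq_len(nrow(sec))) {
    s_i <- seg[seg$section_index == sec$index[i], , drop = FALSE]
    if (!nrow(s_i)) next
    cl <- clip_segments_to_polygon(s_i, sec$mask[[i]])
    if (!nrow(cl)) next
    xs <- c(cl$x0, cl$x1); ys <- c(cl$y0, cl$y1)
    rng_rc <- c(min(rng_rc[1], min(xs)), max(rng_rc[2], max(xs)))
    rng_dv <- c(min(rng_dv[1], min(ys)), max(rng_dv[2], max(ys)))
    mls <- c(mls, sec$ml_center[i])
  }
  empty <- !length(mls)
  tibble(channel = channel, axis = AXES,
         extent = if (empty) c(0, 0, 0) else
           c(diff(rng_rc), diff(rng_dv), diff(range(mls))),
         empty = empty)
}

#' Co-labeling percentage
#'
#' `100 * positive / total`, rounded half-up to one decimal -- the format
#' used for marker co-expression statistics (e.g. 255 of 258 cells ->
#' 98.8).
#'
#' @param positive,total Non-negative counts with `positive <= total`,
#'   `total > 0`.
#' @return Percentage rounded to one decimal.
#' @examples
#' contingency_percentage(255, 258)
#' @export
contingency_percentage <- function(positive, total) {
  if (any(total <= 0)) abort("total must be > 0")
  if (any(positive < 0) || any(positive > total)) {
    abort("need 0 <= positive <= total")
  }
  round_half_up(100 * positive / total, 1)
}
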