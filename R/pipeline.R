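# End-to-end orchestration: synthesis (or file input) -> per-channel
# density gridding -> two-Gaussian arborization fits -> distance / KS /
# overlap / extent statistics -> cohort topography, with a reproducible
# JSON report.

#' Configure an analysis pipeline run
#'
#' @param synth A [synth_config()] (synthetic mode).
#' @param data_roots Character vector of dataset directories (file mode;
#'   overrides `synth`).
#' @param n_mice Cohort size in synthetic mode.
#' @param injection_jitter Per-axis SD (mm) of injection-site displacement
#'   across synthetic mice.
#' @param box_size Density lattice box side (mm).
#' @param presence_threshold Box presence threshold (mm of fiber).
#' @param em EM options: `tol`, `max_iter`, `ridge`, `restarts`.
#' @param ks_method `"auto"`, `"exact"`, or `"asymptotic"`.
#' @param pairing Optional adjacent-section pairing applied to every mouse
#'   before gridding (see [superimpose_adjacent()]).
#' @param seed Integer seed for all randomness.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param write_plots Also write PNG heatmap/topography plots.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), data_roots = NULL,
                            n_mice = 6,
                            injection_jitter = c(0.15, 0.15, 0.15),
                            box_size = 0.04, presence_threshold = 0,
                            em = list(tol = 1e-8, max_iter = 500,
                                      ridge = 1e-6, restarts = 1),
                            ks_method = "auto", pairing = NULL, seed = 1,
                            out_dir = NULL, write_plots = FALSE) {
  assert_scalar_num(box_size, "box_size", 0, strict_min = TRUE)
  assert_scalar_num(presence_threshold, "presence_threshold", 0)
  stopifnot(n_mice >= 1)
  em <- utils::modifyList(list(tol = 1e-8, max_iter = 500, ridge = 1e-6,
                               restarts = 1), em)
  cfg <- list(synth = synth, data_roots = data_roots, n_mice = n_mice,
              injection_jitter = injection_jitter, box_size = box_size,
              presence_threshold = presence_threshold, em = em,
              ks_method = ks_method, pairing = pairing, seed = seed,
              out_dir = out_dir, write_plots = write_plots)
  class(cfg) <- "pipeline_config"
  cfg
}

analyze_mouse <- function(ds, config) {
  grids <- fits <- list()
  for (ch in CHANNELS) {
    grids[[ch]] <- build_grid(ds, ch, box_size = config$box_size)
    wp <- grid_to_weighted_points(grids[[ch]])
    fits[[ch]] <- fit_two_gaussians(
      wp, tol = config$em$tol, max_iter = config$em$max_iter,
      ridge = config$em$ridge, restarts = config$em$restarts,
      seed = config$seed, channel = ch)
  }
  list(grids = grids, fits = fits,
       distances = center_distances(fits$GFP, fits$RFP, ds$mouse_id),
       overlap = classify_boxes(grids$GFP, grids$RFP,
                                config$presence_threshold, ds$mouse_id),
       extents = dplyr::bind_rows(projection_extent(ds, "GFP"),
                                  projection_extent(ds, "RFP")) |>
         dplyr::mutate(mouse_id = ds$mouse_id),
       soma = dplyr::bind_rows(soma_summary(ds, "GFP"),
                               soma_summary(ds, "RFP")) |>
         dplyr::mutate(mouse_id = ds$mouse_id))
}

#' Run the full convergence-analysis pipeline
#'
#' Generates (or reads) a cohort, optionally superimposes adjacent
#' sections, grids each channel's varicose-fiber length, fits the
#' two-component arborization model per channel, and assembles the
#' convergence statistics: per-mouse center distances, the pooled
#' within- vs cross-channel KS comparison, box-overlap classification
#' with cohort percentages, projection extents, soma summaries, and the
#' axis-wise topography regressions. Identical config + seed yields an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return A `pallido_report` list with elements `mice` (per-mouse grids,
#'   fits and tables), `distances`, `ks`, `overlap_pct`, `extents`,
#'   `somata`, `topography`, and `provenance`. If `config$out_dir` is set,
#'   CSV tables, per-mouse fit JSONs and `report.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  cohort <- if (!is.null(config$data_roots)) {
    ds_list <- lapply(config$data_roots, read_dataset)
    stats::setNames(ds_list,
                    vapply(ds_list, function(d) d$mouse_id, character(1)))
  } else {
    generate_cohort(config$synth, config$n_mice, config$injection_jitter,
                    seed = config$seed)
  }
  if (!is.null(config$pairing)) {
    cohort <- lapply(cohort, superimpose_adjacent, pairing = config$pairing)
  }
  mice <- vector("list", length(cohort))
  names(mice) <- names(cohort)
  for (i in seq_along(cohort)) {
    mice[[i]] <- tryCatch(
      analyze_mouse(cohort[[i]], config),
      error = function(e) {
        abort(paste0("pipeline stage failed for ", names(cohort)[i], ": ",
                     conditionMessage(e)))
      })
  }
  distances <- dplyr::bind_rows(lapply(mice, `[[`, "distances"))
  pooled <- pool_distances(distances)
  ks <- ks_compare(pooled$within, pooled$between, method = config$ks_method)
  overlap_pct <- overlap_percentages(lapply(mice, `[[`, "overlap"))
  extents <- dplyr::bind_rows(lapply(mice, `[[`, "extents"))
  somata <- dplyr::bind_rows(lapply(mice, `[[`, "soma"))

  fits_tbl <- dplyr::bind_rows(lapply(names(mice), function(mid) {
    tibble(mouse_id = mid, channel = CHANNELS,
           fit = list(mice[[mid]]$fits$GFP, mice[[mid]]$fits$RFP))
  }))
  topo <- topography_report(fits_tbl, somata, per_channel = TRUE)

  cfg_hashable <- config
  cfg_hashable$out_dir <- NULL       # output location must not change the
  cfg_hashable$write_plots <- NULL   # scientific provenance hash
  provenance <- list(config_hash = rlang::hash(cfg_hashable),
                     seed = config$seed,
                     n_mice = length(cohort),
                     package_version = as.character(utils::packageVersion("pallidotrace")))
  report <- structure(
    list(mice = mice, distances = distances, ks = ks,
         overlap_pct = overlap_pct, extents = extents, somata = somata,
         topography = topo, fits_tbl = fits_tbl, provenance = provenance),
    class = "pallido_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir, write_plots = config$write_plots)
  }
  message(sprintf("pipeline finished in %.1f s (%d mice)",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  length(cohort)))
  report
}

#' Write a pipeline report's artifacts
#'
#' Writes `distances.csv`, `overlap.csv` (per-section class areas in units
#' of 10^4 um^2), `extents.csv`, `somata.csv`, `topography.csv`, per-mouse
#' arborization-fit JSONs, and a consolidated `report.json` embedding the
#' provenance block.
#'
#' @param report A `pallido_report`.
#' @param out_dir Output directory.
#' @param write_plots Also write PNG heatmaps and topography scatter plots.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, write_plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$distances, file.path(out_dir, "distances.csv"))
  overlap_sections <- dplyr::bind_rows(lapply(report$mice, function(m) {
    ps <- m$overlap$per_section
    tibble(mouse_id = m$overlap$mouse_id, section_index = ps$section_index,
           gfp_only_1e4um2 = ps$area_gfp_only * 1e2,
           rfp_only_1e4um2 = ps$area_rfp_only * 1e2,
           both_1e4um2 = ps$area_both * 1e2)
  }))
  readr::write_csv(overlap_sections, file.path(out_dir, "overlap.csv"))
  readr::write_csv(report$extents, file.path(out_dir, "extents.csv"))
  readr::write_csv(report$somata, file.path(out_dir, "somata.csv"))
  readr::write_csv(report$topography, file.path(out_dir, "topography.csv"))
  for (mid in names(report$mice)) {
    for (ch in CHANNELS) {
      write_fit_json(report$mice[[mid]]$fits[[ch]],
                     file.path(out_dir, sprintf("fit_%s_%s.json", mid, ch)))
    }
  }
  json <- list(
    provenance = report$provenance,
    ks = as.list(report$ks),
    distances = report$distances,
    overlap_percentages = report$overlap_pct,
    extents = report$extents,
    topography = report$topography)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (write_plots) {
    for (mid in names(report$mice)) {
      for (ch in CHANNELS) {
        export_heatmap(report$mice[[mid]]$grids[[ch]],
                       file.path(out_dir, sprintf("heatmap_%s_%s", mid, ch)))
      }
    }
    for (ax in AXES) {
      p <- plot_topography(report$fits_tbl, report$somata, axis = ax)
      tryCatch(ggplot2::ggsave(
        file.path(out_dir, sprintf("topography_%s.png", ax)), p,
        width = 7, height = 4, dpi = 150, device = grDevices::png),
        error = function(e) warn(paste0("PNG export failed: ",
                                        conditionMessage(e))))
    }
  }
  invisible(out_dir)
}

#' @export
print.pallido_report <- function(x, ...) {
  cat("<pallido_report>", x$provenance$n_mice, "mice, seed",
      x$provenance$seed, "\n")
  cat("  KS within- vs cross-channel distances: D =",
      signif(x$ks$statistic, 3), ", p =", signif(x$ks$p_value, 3), "\n")
  cat("  projection-area percentages (mean +/- SD):\n")
  op <- x$overlap_pct
  for (i in seq_len(nrow(op))) {
    cat(sprintf("    %-9s %5.1f +/- %.1f %%\n", op$class[i],
                op$mean_pct[i], op$sd_pct[i]))
  }
  invisible(x)
}
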