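# Soma-distribution summaries and axis-wise regression of arborization
# centers on injection (soma) centers across a cohort.

#' Summarize a channel's labeled soma distribution
#'
#' Unweighted per-axis mean and range of the channel's soma positions.
#'
#' @param dataset A [fiber_dataset()].
#' @param channel `"GFP"` or `"RFP"`.
#' @return One-row tibble: `channel`, `n_cells`, `center_rc/dv/ml`,
#'   `range_rc/dv/ml` (mm), `empty` flag when there are no somata.
#' @export
soma_summary <- function(dataset, channel) {
  assert_channel(channel)
  so <- dataset$somata[dataset$somata$channel == channel, ]
  if (!nrow(so)) {
    return(tibble(channel = channel, n_cells = 0L,
                  center_rc = NA_real_, center_dv = NA_real_,
                  center_ml = NA_real_, range_rc = NA_real_,
                  range_dv = NA_real_, range_ml = NA_real_, empty = TRUE))
  }
  tibble(channel = channel, n_cells = nrow(so),
         center_rc = mean(so$rc), center_dv = mean(so$dv),
         center_ml = mean(so$ml),
         range_rc = diff(range(so$rc)), range_dv = diff(range(so$dv)),
         range_ml = diff(range(so$ml)), empty = FALSE)
}

#' Ordinary least-squares regression for one topography axis
#'
#' OLS slope and intercept with the Pearson correlation and its two-sided
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x_values,y_values Equal-length numeric vectors (n >= 2); `x` must
#'   not be constant.
#' @return One-row tibble: `slope`, `intercept`, `pearson_r`, `p_value`
#'   (NA when n < 3), `n_points`.
#' @export
axis_regression <- function(x_values, y_values) {
  if (length(x_values) != length(y_values) || length(x_values) < 2) {
    abort("x and y must have equal length >= 2")
  }
  if (diff(range(x_values)) == 0) {
    abort("x is constant; regression slope undefined")
  }
  fit <- lm(y_values ~ x_values)
  r <- if (stats::sd(y_values) == 0) 0 else
    stats::cor(x_values, y_values)
  p <- NA_real_
  if (length(x_values) >= 3 && stats::sd(y_values) > 0) {
    p <- stats::cor.test(x_values, y_values)$p.value
  }
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         pearson_r = r, p_value = p, n_points = length(x_values))
}

#' Cohort topography: arborization centers vs soma centers
#'
#' For each axis (rc, dv, ml) and each arborization label (#1 rostral, #2
#' caudal), regresses the soma-distribution center (y) on the fitted
#' arborization center (x) across the cohort, pooling the two channels as
#' separate points (2 points per mouse), the plotting convention with soma
#' centers on the vertical axis. Optionally also per channel.
#'
#' @param cohort_fits Tibble with columns `mouse_id`, `channel`, `fit`
#'   (list column of `arborization_fit`s).
#' @param cohort_soma_summaries Tibble with columns `mouse_id`, `channel`,
#'   `center_rc`, `center_dv`, `center_ml` (e.g. bound [soma_summary()]
#'   rows).
#' @param per_channel Also compute per-channel regressions.
#' @return Tibble with one row per axis x label (x channel): `axis`,
#'   `label`, `channel` (`"pooled"` or the channel), regression fields from
#'   [axis_regression()], and `underpowered` (TRUE when n_points < 3).
#' @export
topography_report <- function(cohort_fits, cohort_soma_summaries,
                              per_channel = FALSE) {
  fits <- cohort_fits
  soma <- cohort_soma_summaries
  missing <- dplyr::anti_join(soma[, c("mouse_id", "channel")],
                              fits[, c("mouse_id", "channel")],
                              by = c("mouse_id", "channel"))
  missing2 <- dplyr::anti_join(fits[, c("mouse_id", "channel")],
                               soma[, c("mouse_id", "channel")],
                               by = c("mouse_id", "channel"))
  if (nrow(missing) || nrow(missing2)) {
    bad <- dplyr::bind_rows(missing, missing2)
    warn(paste0("skipping mouse/channel pairs without both fit and somata: ",
                paste(paste(bad$mouse_id, bad$channel), collapse = "; ")))
  }
  centers <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    td <- tidy(fits$fit[[i]])[, c("label", "rc", "dv", "ml")]
    td$mouse_id <- fits$mouse_id[i]
    td$channel <- fits$channel[i]
    td
  }))
  pts <- dplyr::inner_join(centers, soma, by = c("mouse_id", "channel"))
  groups <- if (per_channel) c("pooled", CHANNELS) else "pooled"
  out <- list()
  for (grp in groups) {
    sub_all <- if (grp == "pooled") pts else pts[pts$channel == grp, ]
    for (lb in c("#1", "#2")) {
      sub <- sub_all[sub_all$label == lb, ]
      for (ax in AXES) {
        x <- sub[[ax]]
        y <- sub[[paste0("center_", ax)]]
        reg <- tryCatch(axis_regression(x, y), error = function(e) {
          tibble(slope = NA_real_, intercept = NA_real_,
                 pearson_r = NA_real_, p_value = NA_real_,
                 n_points = length(x))
        })
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble(axis = ax, label = lb, channel = grp), reg)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$underpowered <- res$n_points < 3
  res
}

#' Scatter plot of cohort topography for one axis
#'
#' Arborization centers (x) against soma centers (y) with dotted
#' regression lines, one panel per arborization label, channels colored.
#'
#' @param cohort_fits,cohort_soma_summaries As in [topography_report()].
#' @param axis One of `"rc"`, `"dv"`, `"ml"`.
#' @return A ggplot object.
#' @export
plot_topography <- function(cohort_fits, cohort_soma_summaries,
                            axis = c("ml", "dv", "rc")) {
  axis <- match.arg(axis)
  centers <- dplyr::bind_rows(lapply(seq_len(nrow(cohort_fits)), function(i) {
    td <- tidy(cohort_fits$fit[[i]])[, c("label", "rc", "dv", "ml")]
    td$mouse_id <- cohort_fits$mouse_id[i]
    td$channel <- cohort_fits$channel[i]
    td
  }))
  pts <- dplyr::inner_join(centers, cohort_soma_summaries,
                           by = c("mouse_id", "channel"))
  pts$x <- pts[[axis]]
  pts$y <- pts[[paste0("center_", axis)]]
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$channel), size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", color = "black",
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_color_manual(values = c(GFP = "forestgreen",
                                           RFP = "magenta3")) +
    ggplot2::labs(x = paste0("arborization center ", axis, " (mm)"),
                  y = paste0("soma center ", axis, " (mm)"))
}
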