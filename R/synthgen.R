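# Synthetic mouse generator. Each channel's varicose fiber field is built
# so its length-weighted spatial density follows a known two-component 3D
# Gaussian mixture: fibers are stationary AR(1) (discrete
# Ornstein-Uhlenbeck) random walks whose per-axis stationary law equals the
# sampled mixture component, so every vertex is marginally distributed as
# the component Gaussian while consecutive vertices stay ~one step apart.
# This realizes the target density as genuine polylines (exercising
# length-based gridding) rather than i.i.d. points.

#' Configuration of a synthetic mouse
#'
#' Defaults emulate the study conditions: ~20-30 labeled somata per channel
#' in a ~0.5 x 0.8 x 0.5 mm injection volume of the caudate-putamen, dual
#' channel varicose fiber fields in a GPe-like region each shaped as a
#' two-component 3D Gaussian mixture with nearly coincident cross-channel
#' centers and 0.2 mm rostrocaudal within-channel separation, the
#' indirect-pathway (RFP) field wider and denser than the direct-pathway
#' (GFP) field (covariance scale 1.5), and a linear dorsoventral +
#' mediolateral topographic map from soma centroid to arborization
#' mid-center with no rostrocaudal dependence.
#'
#' @param soma_center Length-3 `(rc, dv, ml)` center of the infected soma
#'   cloud (mm from bregma).
#' @param soma_spread Per-axis SD of the soma cloud (mm).
#' @param n_somata Named count per channel.
#' @param topo_map 3x2 matrix (rows rc, dv, ml; cols slope, intercept)
#'   mapping the soma-cloud center to the arborization mid-center.
#' @param arborization_offsets 2x3 matrix: displacement of components #1
#'   (rostral, row 1) and #2 (caudal, row 2) from the mid-center (mm).
#' @param mixture_sd Per-axis SD of one GFP arborization component (mm);
#'   component covariances are `diag(mixture_sd^2) * channel_scales`.
#' @param channel_scales Per-channel covariance scale; RFP >= GFP emulates
#'   the wider indirect-pathway field (warned, not enforced).
#' @param mixture_weights Per-channel length-2 mixing proportions (sum 1).
#' @param n_fibers Fibers per channel.
#' @param p_varicose Probability that a fiber is varicose, per channel.
#' @param fiber_step Mean 3D step length of the fiber walk (mm).
#' @param fiber_step_ml Step SD along ml (mm); smaller than the in-plane
#'   step because axons run mostly within a parasagittal plane.
#' @param fiber_len_mean Mean fiber length (mm); lengths are Gamma(shape 4).
#' @param varicosity_spacing Mean arc length between boutons (mm);
#'   spacings are exponential (Poisson along arc length).
#' @param section_span Length-2 ml interval covered by sections (mm).
#' @param section_thickness Section thickness (mm).
#' @param mask_semiaxes Length-2 `(rc, dv)` semi-axes of the elliptical
#'   GPe mask, centered on the arborization mid-center.
#' @param seed Default seed used when the generator is called without one.
#' @return A `synth_config` list.
#' @export
synth_config <- function(soma_center = c(rc = 0.5, dv = -3.0, ml = 2.2),
                         soma_spread = c(rc = 0.13, dv = 0.20, ml = 0.135),
                         n_somata = c(GFP = 29, RFP = 23),
                         topo_map = cbind(slope = c(0, 1, 1),
                                          intercept = c(-0.45, -0.3, -0.3)),
                         arborization_offsets = rbind(`#1` = c(0.10, 0.10, 0),
                                                      `#2` = c(-0.10, -0.10, 0)),
                         mixture_sd = c(rc = 0.07, dv = 0.10, ml = 0.10),
                         channel_scales = c(GFP = 1, RFP = 1.5),
                         mixture_weights = list(GFP = c(0.5, 0.5),
                                                RFP = c(0.5, 0.5)),
                         n_fibers = c(GFP = 80, RFP = 120),
                         p_varicose = c(GFP = 0.8, RFP = 1.0),
                         fiber_step = 0.01,
                         fiber_step_ml = 0.004,
                         fiber_len_mean = 2.0,
                         varicosity_spacing = 0.006,
                         section_span = c(1.3, 2.7),
                         section_thickness = 0.02,
                         mask_semiaxes = c(0.55, 0.70),
                         seed = 1) {
  cfg <- list(soma_center = soma_center, soma_spread = soma_spread,
              n_somata = n_somata, topo_map = topo_map,
              arborization_offsets = arborization_offsets,
              mixture_sd = mixture_sd, channel_scales = channel_scales,
              mixture_weights = mixture_weights, n_fibers = n_fibers,
              p_varicose = p_varicose, fiber_step = fiber_step,
              fiber_step_ml = fiber_step_ml, fiber_len_mean = fiber_len_mean,
              varicosity_spacing = varicosity_spacing,
              section_span = section_span,
              section_thickness = section_thickness,
              mask_semiaxes = mask_semiaxes, seed = seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  pos <- c(cfg$soma_spread, cfg$mixture_sd, cfg$channel_scales,
           cfg$fiber_step, cfg$fiber_step_ml, cfg$fiber_len_mean,
           cfg$varicosity_spacing, cfg$section_thickness, cfg$mask_semiaxes)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    abort("all spreads, scales, lengths and spacings must be > 0")
  }
  if (cfg$fiber_step_ml >= cfg$fiber_step) {
    abort("fiber_step_ml must be smaller than fiber_step")
  }
  for (ch in CHANNELS) {
    w <- cfg$mixture_weights[[ch]]
    if (length(w) != 2 || any(w <= 0) || abs(sum(w) - 1) > 1e-9) {
      abort(paste0("mixture_weights$", ch, " must be two positive values summing to 1"))
    }
  }
  if (any(cfg$p_varicose < 0) || any(cfg$p_varicose > 1)) {
    abort("p_varicose must lie in [0, 1]")
  }
  if (cfg$channel_scales[["RFP"]] < cfg$channel_scales[["GFP"]]) {
    warn("channel_scales[RFP] < channel_scales[GFP]: the indirect-pathway field will not contain the direct-pathway field")
  }
  if (diff(cfg$section_span) <= 0) abort("section_span must be increasing")
  invisible(cfg)
}

#' Ground-truth arborization centers implied by a configuration
#'
#' Applies the topographic map to the configured soma center and adds the
#' component offsets; these are the true means of the generated mixtures.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `label`, `rc`, `dv`, `ml`.
#' @export
true_arbor_centers <- function(config) {
  mid <- config$topo_map[, "slope"] * config$soma_center +
    config$topo_map[, "intercept"]
  tibble(label = c("#1", "#2"),
         rc = mid[1] + config$arborization_offsets[, 1],
         dv = mid[2] + config$arborization_offsets[, 2],
         ml = mid[3] + config$arborization_offsets[, 3])
}

# Elliptical GPe-like mask centered on the arborization mid-center.
make_mask <- function(config, n_vertices = 28) {
  mid <- config$topo_map[, "slope"] * config$soma_center +
    config$topo_map[, "intercept"]
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  m <- cbind(rc = mid[1] + config$mask_semiaxes[1] * cos(th),
             dv = mid[2] + config$mask_semiaxes[2] * sin(th))
  m
}

# Stationary AR(1) (discrete Ornstein-Uhlenbeck) walks for a whole block
# of fibers at once: one row per fiber, columns are successive vertices.
# Per axis, x_t = a x_{t-1} + eps with eps ~ N(0, (1-a^2) sd^2) and
# x_1 ~ N(0, sd^2), so every vertex is marginally N(0, sd^2) exactly while
# consecutive vertices stay ~one step apart; `a` is set from the requested
# per-axis step SD via step^2 = 2 (1 - a) sd^2.
walk_fiber_block <- function(nf, maxn, sdv, step_sd) {
  a <- 1 - pmin(step_sd^2 / (2 * sdv^2), 0.5)
  out <- vector("list", 3)
  for (k in 1:3) {
    m <- matrix(0, nf, maxn)
    m[, 1] <- rnorm(nf, 0, sdv[k])
    if (maxn > 1) {
      eps <- matrix(rnorm(nf * (maxn - 1), 0, sqrt(1 - a[k]^2) * sdv[k]),
                    nf, maxn - 1)
      for (t in 2:maxn) m[, t] <- a[k] * m[, t - 1] + eps[, t - 1]
    }
    out[[k]] <- m
  }
  out
}

#' Generate a synthetic mouse dataset
#'
#' Draws somata from the configured injection-site Gaussian and realizes
#' each channel's varicose fiber field as polyline fibers whose
#' length-weighted density follows the configured two-component 3D Gaussian
#' mixture. Fibers are cut into per-section planar traces wherever they
#' cross section boundaries; varicosities are placed at exponential
#' arc-length spacings along varicose traces. The same `(config, seed)`
#' always yields an identical dataset.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [fiber_dataset()] with a `ground_truth` attribute holding the
#'   true component centers, covariances and soma parameters.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_synth_config(config)
  mouse_id <- sprintf("synth_seed%d", as.integer(seed))

  span <- config$section_span
  thick <- config$section_thickness
  n_sec <- ceiling((span[2] - span[1]) / thick - 1e-9)
  mask <- make_mask(config)
  sections <- tibble(index = seq_len(n_sec),
                     ml_center = span[1] + (seq_len(n_sec) - 0.5) * thick,
                     thickness = thick,
                     mask = rep(list(mask), n_sec))

  centers <- true_arbor_centers(config)
  gt <- list(centers = centers,
             covariances = lapply(CHANNELS, function(ch) {
               diag(config$mixture_sd^2) * config$channel_scales[[ch]]
             }) |> stats::setNames(CHANNELS),
             soma_center = config$soma_center,
             soma_spread = config$soma_spread)

  # somata
  somata <- withr::with_seed(derive_seed(seed, "somata"), {
    dplyr::bind_rows(lapply(CHANNELS, function(ch) {
      n <- config$n_somata[[ch]]
      if (n == 0) return(NULL)
      tibble(soma_id = sprintf("%s_s%03d", ch, seq_len(n)), channel = ch,
             rc = rnorm(n, config$soma_center[1], config$soma_spread[1]),
             dv = rnorm(n, config$soma_center[2], config$soma_spread[2]),
             ml = rnorm(n, config$soma_center[3], config$soma_spread[3]))
    }))
  })

  # fibers: accumulate columns in flat lists (a tibble per fragment would
  # dominate the runtime)
  trace_rows <- withr::with_seed(derive_seed(seed, "fibers"), {
    acc_id <- character(0); acc_ch <- character(0)
    acc_sec <- integer(0); acc_var <- logical(0)
    acc_pts <- list(); acc_vp <- list()
    for (ch in CHANNELS) {
      nf <- config$n_fibers[[ch]]
      if (nf == 0) next
      sdv <- config$mixture_sd * sqrt(config$channel_scales[[ch]])
      if (any(sdv^2 < 1e-10)) abort("degenerate covariance after scaling")
      step_ip <- sqrt(pmax(config$fiber_step^2 - config$fiber_step_ml^2, 1e-8) / 2)
      step_sd <- c(step_ip, step_ip, config$fiber_step_ml)
      comp <- sample.int(2, nf, replace = TRUE,
                         prob = config$mixture_weights[[ch]])
      lens <- rgamma(nf, shape = 4, scale = config$fiber_len_mean / 4)
      nv <- pmax(5L, as.integer(round(lens / config$fiber_step)))
      varic <- runif(nf) < config$p_varicose[[ch]]
      blk <- walk_fiber_block(nf, max(nv), sdv, step_sd)
      muM <- as.matrix(centers[comp, c("rc", "dv", "ml")])
      for (f in seq_len(nf)) {
        pts <- cbind(blk[[1]][f, seq_len(nv[f])] + muM[f, 1],
                     blk[[2]][f, seq_len(nv[f])] + muM[f, 2],
                     blk[[3]][f, seq_len(nv[f])] + muM[f, 3])
        ipd <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
        sec_idx <- floor((pts[, 3] - span[1]) / thick) + 1
        inside <- sec_idx >= 1 & sec_idx <= n_sec
        r <- rle(ifelse(inside, sec_idx, NA_integer_))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        piece <- 0L
        for (g in seq_along(r$lengths)) {
          if (is.na(r$values[g]) || r$lengths[g] < 2) next
          sl <- ipd[starts[g]:(ends[g] - 1L)]
          dup <- c(FALSE, sl == 0)
          p2 <- pts[starts[g]:ends[g], 1:2, drop = FALSE][!dup, , drop = FALSE]
          if (nrow(p2) < 2) next
          piece <- piece + 1L
          colnames(p2) <- c("rc", "dv")
          L <- sum(sl)
          vp <- numeric(0)
          if (varic[f]) {
            vp <- cumsum(rexp(ceiling(L / config$varicosity_spacing) + 25,
                              rate = 1 / config$varicosity_spacing))
            vp <- vp[vp <= L]
          }
          k <- length(acc_pts) + 1L
          acc_id[k] <- sprintf("%s_f%03d_p%02d", ch, f, piece)
          acc_ch[k] <- ch
          acc_sec[k] <- as.integer(r$values[g])
          acc_var[k] <- varic[f]
          acc_pts[[k]] <- p2
          acc_vp[[k]] <- vp
        }
      }
    }
    if (!length(acc_pts)) NULL else {
      tibble(trace_id = acc_id, channel = acc_ch, section_index = acc_sec,
             varicose = acc_var, points = acc_pts,
             varicosity_positions = acc_vp)
    }
  })

  prov <- paste0("synthgen config ", rlang::hash(config), " seed ", seed)
  ds <- fiber_dataset(mouse_id, sections,
                      if (is.null(trace_rows) || !nrow(trace_rows)) NULL else trace_rows,
                      somata, provenance = prov)
  attr(ds, "ground_truth") <- gt
  ds
}

#' Generate a cohort of synthetic mice
#'
#' Each mouse's injection site (soma-cloud center) is displaced by a seeded
#' per-axis Gaussian draw; arborization centers follow the configured
#' topographic map applied to the displaced center, so the cohort embeds a
#' known linear soma-to-arborization topography.
#'
#' @param config A [synth_config()].
#' @param n_mice Number of mice (>= 1).
#' @param injection_jitter Per-axis SD (mm) of the soma-center displacement
#'   across mice; a scalar is recycled.
#' @param seed Integer seed.
#' @return A list of [fiber_dataset()]s (named by mouse).
#' @export
generate_cohort <- function(config, n_mice = 6,
                            injection_jitter = c(0.15, 0.15, 0.15),
                            seed = config$seed) {
  stopifnot(n_mice >= 1)
  injection_jitter <- rep_len(injection_jitter, 3)
  shifts <- withr::with_seed(derive_seed(seed, "cohort"), {
    matrix(rnorm(3 * n_mice, 0, rep(injection_jitter, each = n_mice)),
           nrow = n_mice)
  })
  if (all(injection_jitter == 0)) shifts[] <- 0
  out <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    cfg_i <- config
    cfg_i$soma_center <- config$soma_center + shifts[i, ]
    ds <- generate_dataset(cfg_i, seed = derive_seed(seed, paste0("mouse", i)))
    ds$mouse_id <- sprintf("mouse%02d", i)
    out[[i]] <- ds
  }
  stats::setNames(out, vapply(out, function(d) d$mouse_id, character(1)))
}

#' Simulate a co-labeling contingency count
#'
#' Draws the number of double-positive cells binomially, emulating
#' marker-colocalization counts such as Cre/preprodynorphin co-labeling.
#'
#' @param p_true True co-labeling probability in `[0, 1]`.
#' @param n_cells Number of scored cells (>= 1).
#' @param seed Integer seed.
#' @param marker_pair Text label for the marker pair.
#' @return Tibble with columns `marker_pair`, `positive`, `total`.
#' @export
generate_colabel_counts <- function(p_true, n_cells, seed = 1,
                                    marker_pair = "markerA/markerB") {
  if (!is.numeric(p_true) || p_true < 0 || p_true > 1) {
    abort("p_true must lie in [0, 1]")
  }
  stopifnot(n_cells >= 1)
  pos <- withr::with_seed(derive_seed(seed, "colabel"),
                          rbinom(1, n_cells, p_true))
  tibble(marker_pair = marker_pair, positive = pos, total = as.integer(n_cells))
}

#' Serialize / deserialize a synthetic configuration
#'
#' @param config A [synth_config()].
#' @param path YAML file path.
#' @return `read_synth_config` returns a [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  obj <- lapply(unclass(config), function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, data = as.numeric(x), nrow = nrow(x),
           dimnames = dimnames(x))
    } else if (is.numeric(x) && !is.null(names(x))) {
      as.list(x)  # maps keep names; bare YAML sequences do not
    } else x
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj <- lapply(obj, function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      matrix(x$data, nrow = x$nrow, dimnames = x$dimnames)
    } else if (is.list(x) && !is.null(names(x)) &&
                 all(vapply(x, is.numeric, logical(1))) &&
                 all(lengths(x) == 1)) {
      unlist(x)
    } else x
  })
  do.call(synth_config, obj)
}
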