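# Two-component 3D Gaussian mixture fit to length-weighted density points,
# by weighted expectation-maximization. This is the arborization model: the
# rostral component is labeled "#1", the caudal "#2", following the
# rostrocaudal arrangement of the two striatopallidal terminal fields.

weighted_moments <- function(x, w) {
  W <- sum(w)
  mu <- colSums(x * w) / W
  xc <- sweep(x, 2, mu)
  cov <- crossprod(xc * w, xc) / W
  list(mean = mu, cov = cov, weight = W)
}

# Deterministic initialization: split at the weighted median rc (ties
# broken by dv, ml, weight so the split never depends on row order).
init_median_split <- function(x, w) {
  ord <- order(x[, 1], x[, 2], x[, 3], w)
  cum <- cumsum(w[ord])
  half <- which(cum >= sum(w) / 2)[1]
  half <- min(max(half, 1L), length(w) - 1L)
  idx1 <- ord[seq_len(half)]
  idx2 <- ord[(half + 1):length(w)]
  list(weighted_moments(x[idx1, , drop = FALSE], w[idx1]),
       weighted_moments(x[idx2, , drop = FALSE], w[idx2]))
}

init_random <- function(x, w) {
  ctrs <- sample.int(nrow(x), 2, prob = w / sum(w))
  glob <- weighted_moments(x, w)
  lapply(1:2, function(k) {
    list(mean = x[ctrs[k], ], cov = glob$cov / 4, weight = sum(w) / 2)
  })
}

# Weighted log-density of one mixture component at all points (xT is the
# transposed 3 x n point matrix). Failure of the Cholesky factorization
# means a numerically non-PD covariance, reported with the iteration.
em_log_dens <- function(xT, mu, sg, pi_k, iter) {
  ch <- chol(sg)
  if (!all(is.finite(ch))) {
    abort(paste0("non-positive-definite covariance in EM iteration ", iter))
  }
  z <- forwardsolve(t(ch), xT - mu)
  log(pi_k) - 0.5 * colSums(z^2) - sum(log(diag(ch))) - 1.5 * log(2 * pi)
}

run_em <- function(x, w, comps, tol, max_iter, ridge) {
  xT <- t(x)
  W <- sum(w)
  pi_k <- vapply(comps, function(c) c$weight, numeric(1))
  pi_k <- pi_k / sum(pi_k)
  mu <- lapply(comps, function(c) c$mean)
  sg <- lapply(comps, function(c) c$cov + diag(ridge, 3))
  ll_old <- -Inf
  ll_trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    lp1 <- em_log_dens(xT, mu[[1]], sg[[1]], pi_k[1], iter)
    lp2 <- em_log_dens(xT, mu[[2]], sg[[2]], pi_k[2], iter)
    m <- pmax(lp1, lp2)
    lse <- m + log1p(exp(pmin(lp1, lp2) - m))
    ll <- sum(w * lse)
    if (!is.finite(ll)) {
      abort(paste0("non-finite weighted log-likelihood at EM iteration ", iter))
    }
    ll_trace[iter] <- ll
    if (iter > 1 && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- exp(lp1 - lse)          # responsibility of component 1
    wk <- list(w * r1, w * (1 - r1))
    for (k in 1:2) {
      Nk <- sum(wk[[k]])
      pi_k[k] <- Nk / W
      mu[[k]] <- as.numeric(xT %*% wk[[k]]) / Nk
      xc <- xT - mu[[k]]
      sg[[k]] <- tcrossprod(xc * rep(wk[[k]], each = 3L), xc) / Nk +
        diag(ridge, 3)
    }
  }
  list(pi = pi_k, mu = mu, sigma = sg, log_likelihood = ll_trace[iter],
       ll_trace = ll_trace[seq_len(iter)], n_iterations = iter,
       converged = converged)
}

#' Fit two 3D Gaussian arborization components to weighted density points
#'
#' Maximizes the weighted log-likelihood
#' `sum_i w_i log sum_k pi_k N(x_i; mu_k, Sigma_k)` over a two-component
#' trivariate Gaussian mixture by EM, with responsibilities weighted by
#' `w_i` in the M-step and a ridge added to covariance diagonals (the few
#' distinct mediolateral values set by section spacing otherwise make the
#' covariance near-singular in ml). The default initialization splits the
#' points at the weighted median rostrocaudal coordinate, which is
#' deterministic and suits the rostrocaudally arranged arborizations.
#'
#' @param weighted_points Tibble with columns `rc`, `dv`, `ml`, `weight`
#'   (e.g. from [grid_to_weighted_points()]), or a 3-column matrix plus
#'   `weights`.
#' @param weights Optional weight vector when `weighted_points` is a bare
#'   matrix.
#' @param init `"median_split"` (deterministic, default) or `"random"`.
#' @param tol Stop when the weighted log-likelihood improves by less than
#'   this (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param ridge Diagonal regularization added to covariances (mm^2).
#' @param restarts Number of EM runs; runs beyond the first use random
#'   initialization and the best final likelihood wins.
#' @param seed Seed for random restarts.
#' @param channel Optional channel tag stored on the fit.
#' @return An `arborization_fit` with components labeled `"#1"` (rostral:
#'   larger rc mean) and `"#2"` (caudal), the converged weighted
#'   log-likelihood, the per-iteration likelihood trace, iteration count
#'   and convergence flag.
#' @export
fit_two_gaussians <- function(weighted_points, weights = NULL,
                              init = c("median_split", "random"),
                              tol = 1e-8, max_iter = 500, ridge = 1e-6,
                              restarts = 1, seed = 1, channel = NA_character_) {
  init <- match.arg(init)
  if (is.data.frame(weighted_points)) {
    x <- as.matrix(weighted_points[, c("rc", "dv", "ml")])
    w <- weighted_points$weight
  } else {
    x <- as.matrix(weighted_points)
    w <- weights %||% rep(1, nrow(x))
  }
  stopifnot(ncol(x) == 3, length(w) == nrow(x))
  keep <- w > 0
  x <- x[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(unique(x)) < 4 || sum(w) <= 0) {
    abort("need >= 4 distinct points with positive total weight")
  }
  colnames(x) <- AXES

  runs <- list()
  first_init <- if (init == "median_split") init_median_split(x, w) else NULL
  if (restarts <= 1 && !is.null(first_init)) {
    # fully deterministic: no RNG involved
    runs[[1]] <- run_em(x, w, first_init, tol, max_iter, ridge)
  } else {
    withr::with_seed(derive_seed(seed, "emrestarts"), {
      for (r in seq_len(max(1, restarts))) {
        comps <- if (r == 1 && !is.null(first_init)) first_init else
          init_random(x, w)
        runs[[r]] <- run_em(x, w, comps, tol, max_iter, ridge)
      }
    })
  }
  best <- runs[[which.max(vapply(runs, function(z) z$log_likelihood, numeric(1)))]]

  # label: "#1" is rostral (larger rc mean); ties by dv, then ml, then weight
  key <- vapply(1:2, function(k) best$mu[[k]][1], numeric(1))
  tie <- abs(diff(key)) < 1e-9
  ord <- if (!tie) order(-key) else {
    o <- order(-vapply(1:2, function(k) best$mu[[k]][2], numeric(1)),
               -vapply(1:2, function(k) best$mu[[k]][3], numeric(1)),
               -best$pi)
    o
  }
  comps <- lapply(ord, function(k) {
    list(mean = stats::setNames(best$mu[[k]], AXES),
         cov = best$sigma[[k]], weight = best$pi[k])
  })
  names(comps) <- c("#1", "#2")
  structure(list(channel = channel, components = comps,
                 labels = c("#1", "#2"),
                 log_likelihood = best$log_likelihood,
                 ll_trace = best$ll_trace,
                 n_iterations = best$n_iterations,
                 converged = best$converged, n_points = nrow(x),
                 total_weight = sum(w)),
            class = "arborization_fit")
}

#' @export
print.arborization_fit <- function(x, ...) {
  cat("<arborization_fit>", if (!is.na(x$channel)) x$channel else "", "\n")
  for (lb in names(x$components)) {
    c_ <- x$components[[lb]]
    cat(sprintf("  %s: center (%.3f, %.3f, %.3f) mm, weight %.3f\n",
                lb, c_$mean[1], c_$mean[2], c_$mean[3], c_$weight))
  }
  cat(sprintf("  logLik %.4f after %d iterations (%sconverged)\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @describeIn fit_two_gaussians One row per component: label, mixing
#'   weight, center coordinates and per-axis SDs.
#' @param x,object An `arborization_fit`.
#' @param ... Unused.
#' @method tidy arborization_fit
#' @export
tidy.arborization_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$components), function(lb) {
    c_ <- x$components[[lb]]
    tibble(label = lb, weight = c_$weight,
           rc = c_$mean[["rc"]], dv = c_$mean[["dv"]], ml = c_$mean[["ml"]],
           sd_rc = sqrt(c_$cov[1, 1]), sd_dv = sqrt(c_$cov[2, 2]),
           sd_ml = sqrt(c_$cov[3, 3]))
  }))
}

#' @describeIn fit_two_gaussians One-row fit diagnostics.
#' @method glance arborization_fit
#' @export
glance.arborization_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, n_iterations = x$n_iterations,
         converged = x$converged, n_points = x$n_points,
         total_weight = x$total_weight)
}

#' Mahalanobis-distance ellipsoid of a fitted component
#'
#' The region where the Mahalanobis distance from the component center is
#' at most `radius`: `{x : (x - mu)' Sigma^-1 (x - mu) <= radius^2}`. Its
#' principal axes are the covariance eigenvectors with semi-axis lengths
#' `radius * sqrt(eigenvalue)`.
#'
#' @param component One element of an `arborization_fit`'s `components`
#'   (any list with `mean` and `cov`).
#' @param radius Mahalanobis radius (>= 0; the standard contour is 1).
#' @return A `mahalanobis_region`: list with `center`, `axes` (unit
#'   eigenvector columns), `semi_axes`, and `radius`.
#' @export
mahalanobis_region <- function(component, radius = 1) {
  assert_scalar_num(radius, "radius", 0)
  ev <- eigen(component$cov, symmetric = TRUE)
  if (any(ev$values <= 0)) abort("singular covariance in mahalanobis_region")
  structure(list(center = component$mean, axes = ev$vectors,
                 semi_axes = radius * sqrt(ev$values), radius = radius,
                 cov = component$cov),
            class = "mahalanobis_region")
}

#' Intersection of a Mahalanobis ellipsoid with a section plane
#'
#' Returns the in-plane ellipse where the ellipsoid of
#' [mahalanobis_region()] meets the parasagittal plane `ml = ml_plane`
#' (for overlaying fit contours on section heatmaps), or `NULL` if the
#' plane misses the ellipsoid.
#'
#' @param component A component (list with `mean`, `cov`).
#' @param ml_plane Mediolateral plane position (mm).
#' @param radius Mahalanobis radius.
#' @param n Number of polygon points returned.
#' @return Tibble with columns `rc`, `dv` tracing the ellipse, or `NULL`.
#' @export
section_ellipse <- function(component, ml_plane, radius = 1, n = 90) {
  P <- solve(component$cov)
  mu <- component$mean
  Puu <- P[1:2, 1:2]; Puw <- P[1:2, 3]; Pww <- P[3, 3]
  dw <- ml_plane - mu[3]
  u0 <- mu[1:2] - solve(Puu, Puw) * dw
  r0sq <- dw^2 * (Pww - sum(Puw * solve(Puu, Puw)))
  rem <- radius^2 - r0sq
  if (rem < 0) return(NULL)
  ev <- eigen(Puu, symmetric = TRUE)
  semi <- sqrt(rem / ev$values)
  th <- seq(0, 2 * pi, length.out = n)
  pts <- ev$vectors %*% rbind(semi[1] * cos(th), semi[2] * sin(th))
  tibble(rc = u0[1] + pts[1, ], dv = u0[2] + pts[2, ])
}

#' Probability mass inside a Mahalanobis radius
#'
#' For a `dim`-variate Gaussian, the squared Mahalanobis distance is
#' chi-square distributed with `dim` degrees of freedom, so the mass inside
#' radius `r` is `pchisq(r^2, dim)`. At the standard radius 1 in 3D this
#' is 0.1987 -- the "approximately 20%" contour.
#'
#' @param radius Mahalanobis radius (>= 0).
#' @param dim Dimension (>= 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' mass_within(1, 3)  # ~0.199
#' @export
mass_within <- function(radius, dim = 3) {
  assert_scalar_num(radius, "radius", 0)
  stopifnot(dim >= 1)
  pchisq(radius^2, df = dim)
}

#' Serialize an arborization fit to JSON
#'
#' Writes means, covariances (row-major), mixing weights, labels and
#' convergence diagnostics.
#'
#' @param fit An `arborization_fit`.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    channel = fit$channel,
    components = lapply(names(fit$components), function(lb) {
      c_ <- fit$components[[lb]]
      list(label = lb, mean = as.numeric(c_$mean),
           covariance_row_major = as.numeric(t(c_$cov)),
           weight = c_$weight)
    }),
    log_likelihood = fit$log_likelihood,
    n_iterations = fit$n_iterations,
    converged = fit$converged,
    n_points = fit$n_points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Overlay fitted Mahalanobis-1 ellipses on a section's density heatmap
#'
#' @param object An `arborization_fit`.
#' @param grid Optional `density_grid` to show underneath.
#' @param ml_plane Section plane to cut the ellipsoids at (defaults to the
#'   weight-averaged component ml).
#' @param ... Unused.
#' @method autoplot arborization_fit
#' @export
autoplot.arborization_fit <- function(object, grid = NULL, ml_plane = NULL,
                                      ...) {
  td <- tidy(object)
  ml_plane <- ml_plane %||% stats::weighted.mean(td$ml, td$weight)
  ell <- dplyr::bind_rows(lapply(names(object$components), function(lb) {
    e <- section_ellipse(object$components[[lb]], ml_plane)
    if (is.null(e)) return(NULL)
    e$label <- lb
    e
  }))
  p <- ggplot2::ggplot()
  if (!is.null(grid)) {
    g <- grid[abs(grid$ml - ml_plane) == min(abs(grid$ml - ml_plane)), ]
    p <- p + ggplot2::geom_tile(
      data = as_tibble(g),
      ggplot2::aes(.data$rc, .data$dv, fill = .data$length),
      width = attr(grid, "box_size"), height = attr(grid, "box_size")) +
      ggplot2::scale_fill_viridis_c(name = "length (mm)")
  }
  p +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(.data$rc, .data$dv, group = .data$label),
                       color = "white", linewidth = 0.7) +
    ggplot2::geom_point(data = td, ggplot2::aes(.data$rc, .data$dv),
                        shape = 4, size = 3, color = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "rostrocaudal (mm)", y = "dorsoventral (mm)")
}
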