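# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named random substream. Keeps the
# result strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1e6
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

# Round half away from zero to `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

assert_channel <- function(channel) {
  if (!is.character(channel) || length(channel) != 1 || !channel %in% CHANNELS) {
    abort(paste0("`channel` must be one of ", paste(CHANNELS, collapse = ", ")))
  }
  channel
}

assert_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  if (strict_min && x <= min) abort(paste0("`", name, "` must be > ", min))
  if (!strict_min && x < min) abort(paste0("`", name, "` must be >= ", min))
  invisible(x)
}

# Euclidean norm of rows of a 2- or 3-column matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Cumulative arc length along a polyline given as a 2-column matrix.
cum_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(row_norms(diff(pts))))
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(row_norms(diff(pts)))
}
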