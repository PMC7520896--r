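# Fixtures built in code: a tiny hand-constructed dataset and a scaled-down
# generator configuration for fast unit tests (the acceptance tests use the
# full default configuration).

square_mask <- function(side = 1, center = c(0, 0)) {
  m <- cbind(rc = center[1] + side / 2 * c(-1, 1, 1, -1),
             dv = center[2] + side / 2 * c(-1, -1, 1, 1))
  m
}

tiny_dataset <- function() {
  sections <- tibble::tibble(
    index = 1L, ml_center = 1.9, thickness = 0.02,
    mask = list(square_mask(1, c(-0.4, -3.3))))
  traces <- tibble::tibble(
    trace_id = "t0001", channel = "GFP", section_index = 1L,
    varicose = TRUE,
    points = list(cbind(rc = c(-0.41, -0.39), dv = c(-3.30, -3.30))),
    varicosity_positions = list(c(0.005, 0.015)))
  somata <- tibble::tibble(soma_id = "s1", channel = "GFP",
                           rc = 0.5, dv = -3.0, ml = 2.2)
  fiber_dataset("tiny", sections, traces, somata, provenance = "hand-built")
}

# Reduced fiber counts and section span: fast, but same generative model.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_fibers = c(GFP = 15, RFP = 22), fiber_len_mean = 0.8,
         section_span = c(1.5, 2.3)),
    list(...))
  do.call(synth_config, args)
}

# Minimal labeled fit object for distance tests.
make_fit <- function(mean1, mean2, channel = "GFP",
                     cov = diag(0.01, 3)) {
  comp <- function(m) list(mean = stats::setNames(m, c("rc", "dv", "ml")),
                           cov = cov, weight = 0.5)
  structure(list(channel = channel,
                 components = list(`#1` = comp(mean1), `#2` = comp(mean2)),
                 labels = c("#1", "#2"), log_likelihood = 0,
                 ll_trace = 0, n_iterations = 1, converged = TRUE,
                 n_points = 4, total_weight = 1),
            class = "arborization_fit")
}
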