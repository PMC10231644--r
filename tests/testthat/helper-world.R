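# Shared fixtures, built in code. Small worlds keep unit tests fast; the
# acceptance tests build the full-size worlds themselves.

tiny_truth <- function(...) default_ground_truth(grid_shape = c(16L, 16L, 16L), ...)

# one small normative world, preprocessed once per test session
tiny_runs_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- tiny_truth()
      runs <- generate_normative_timeseries(3L, 2L, 48L, truth = tr, seed = 42L)
      cache <<- list(truth = tr,
                     cleaned = suppressMessages(
                       lapply(runs, preprocess_run, config = analysis_config())))
    }
    cache
  }
})

block_mask <- function(dims, from, to, affine = diag(4), id = "p1") {
  g <- array(0L, dims)
  g[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  lesion_mask(g, affine, id)
}

expect_silent_log <- function(expr) suppressMessages(expr)
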