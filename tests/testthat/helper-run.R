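# Shared, lazily-computed pipeline runs so expensive cohorts are generated
# once per test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# A small, fast configuration exercising every stage.
small_config <- function(seed = 303L) {
  run_config(
    n_subjects = 24L, seed = seed, folds = 4L,
    grid_shape = c(48L, 48L, 48L),
    lesion_radius_mm = list(early = c(7, 1), advanced = c(10.5, 1.5))
  )
}

small_run <- function() {
  cached("small_run", suppressWarnings(suppressMessages(
    run_pipeline(small_config())
  )))
}

# The full study-scale conditions: n = 100, 70/30 split, default class effects.
full_run <- function() {
  cached("full_run", suppressWarnings(suppressMessages(
    run_pipeline(run_config(n_subjects = 100L, seed = 20260901L))
  )))
}
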