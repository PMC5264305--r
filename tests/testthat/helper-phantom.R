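# Shared phantom fixtures, built once per test run (several files reuse the
# same bundles; building them repeatedly would dominate the suite's time).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Short default-geometry phantom (full radii, few slabs) - noiseless.
small_noiseless <- function() fixture("small_noiseless", function()
  build_phantom(phantom_params(grid_shape = c(64L, 64L, 16L),
                               long_axis_extent_mm = 6, snr = Inf)))

# Same geometry at the study SNR of 120.
small_noisy <- function() fixture("small_noisy", function()
  build_phantom(phantom_params(grid_shape = c(64L, 64L, 16L),
                               long_axis_extent_mm = 6, snr = 120)))

# Scar-free control version.
small_control <- function() fixture("small_control", function()
  build_phantom(control_params(grid_shape = c(64L, 64L, 16L),
                               long_axis_extent_mm = 6, snr = Inf)))

small_analysis <- function() fixture("small_analysis", function()
  analyze_heart(small_noiseless(), heart_id = "fix", heart_type = "infarcted"))

# The 8-vs-4 study-condition cohort at SNR 120 (the expensive fixture; built
# once and shared between the group-statistics and acceptance tests).
cohort_metrics <- function() fixture("cohort_metrics", function()
  run_cohort(cohort_params(n_infarcted = 8L, n_control = 4L, seed = 20L)))
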