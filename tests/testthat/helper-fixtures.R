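# Shared fixtures, built lazily and cached for the whole test run (several
# tests reuse the same expensive phantom fits).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

test_input <- function() fx("input", simulate_input())
test_schedule <- function() fx("schedule", default_frame_schedule())

# Small phantom for unit tests that only need geometry, not fit accuracy.
small_phantom_spec <- function(noise_scale = 0, ...) {
  phantom_spec(
    shape = c(20, 20, 10), tissue_semiaxes_mm = c(14, 14, 8),
    vessel_center_mm = c(-20, -20), active_center_mm = c(6, 0, 0),
    bkg_center_mm = c(18, 18, 0), noise_scale = noise_scale, ...
  )
}
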