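# Shared fixtures built in code. The standard navigation arena (8-cm plate,
# droplet 15 mm left of centre, 30 min) is solved once per test run on the
# coarse grid and reused by the field, navigator and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

arena_field_coarse <- function() {
  if (is.null(.fixture_cache$field)) {
    .fixture_cache$field <- solve_bilayer_diffusion(
      plate_geometry(radius = 40, dx = 2, dz = 1),
      transport_params(),
      source_spec(center_xy = c(-15, 0)),
      duration = 1800, output_times = seq(0, 1800, by = 60))
  }
  .fixture_cache$field
}

arena_slice_coarse <- function() {
  if (is.null(.fixture_cache$slice))
    .fixture_cache$slice <- slice_field(arena_field_coarse(), -0.5)
  .fixture_cache$slice
}
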