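# Shared fixtures, built once per test run. Small geometries keep the suite
# fast; the full 30-fibre reference geometry is only built where a test needs
# the exact published counts.

.fixtures <- new.env()

small_geometry <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generate_cross_section(4, 400, 120, seed = 7)
  .fixtures$small
}

mid_geometry <- function() {
  if (is.null(.fixtures$mid))
    .fixtures$mid <- generate_cross_section(6, 1200, 320, seed = 2)
  .fixtures$mid
}

default_geometry_cached <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- default_geometry(seed = 1)
  .fixtures$default
}

mid_baseline <- function() {
  if (is.null(.fixtures$mid_base))
    .fixtures$mid_base <- steady_state_field(mid_geometry(), sim_config())
  .fixtures$mid_base
}

# a tiny hand-built geometry: one 3x3 fibre fully wrapped in ECM on a 7x7 grid
ring_geometry <- function() {
  lab <- matrix(0L, 7, 7)
  lab[2:6, 2:6] <- -1L
  lab[3:5, 3:5] <- 1L
  tissue_geometry(lab)
}
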