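## shared fixtures and a per-session cache for the expensive Monte Carlo
## runs used by several acceptance checks (built once per test run)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## a small water tank with the beam entering at y = 0
small_water_grid <- function(lateral = 120, depth = 200, spacing = 4) {
  water_box_grid(lateral_mm = lateral, depth_mm = depth, spacing = spacing)
}

## a coarse homogeneous-slab grid of one material for transmission checks
slab_grid <- function(material = "water", density = NULL, depth = 200,
                      spacing = c(8, 2, 8)) {
  g <- water_box_grid(lateral_mm = 240, depth_mm = depth, spacing = spacing)
  g$materials <- material
  if (!is.null(density)) g$density$data[] <- density
  else g$density$data[] <- tte_material(material)$density
  g
}
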