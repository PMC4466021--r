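# Shared fixtures, all generated in code.

# A small regional grid used throughout.
toy_grid <- function(res = 2, lon = c(-20, 20), lat = c(-10, 10)) {
  grid_spec(res, lon, lat)
}

constant_field <- function(grid, value, variable = "tas", units = "degC",
                           scenario = "modern", model_id = "toy") {
  monthly_field(matrix(value, grid$n_cells, 12), grid, variable, units,
                scenario, model_id)
}

# Scattered observations from a seeded uniform draw over a box.
scatter_points <- function(n, seed, lon = c(0, 20), lat = c(0, 20)) {
  set.seed(seed)
  list(lon = runif(n, lon[1], lon[2]), lat = runif(n, lat[1], lat[2]))
}

# Fabricate an ensemble cube from per-model n x 19 matrices.
toy_cube <- function(mats, grid) {
  mats <- lapply(mats, function(m) {
    colnames(m) <- bio_names()
    m
  })
  ensemble_cube(mats, grid = grid)
}
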