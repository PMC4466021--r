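test_that("temperature trends are simple differences", {
  g <- toy_grid()
  tr <- compute_climate_change_trend(constant_field(g, 10, scenario = "lgm"),
                                     constant_field(g, 15))
  expect_equal(tr$kind, "difference")
  expect_true(all(tr$values == -5))
})

test_that("precipitation trends are ratios with the zero-modern rules", {
  g <- grid_spec(10, c(0, 20), c(0, 10))  # 2 cells
  lgm <- monthly_field(rbind(rep(50, 12), rep(0, 12)), g, "pr", "mm/month",
                       "lgm")
  modern <- monthly_field(rbind(rep(100, 12), rep(0, 12)), g, "pr",
                          "mm/month")
  tr <- compute_climate_change_trend(lgm, modern)
  expect_equal(tr$kind, "ratio")
  expect_true(all(tr$values[1, ] == -0.5))
  expect_true(all(tr$values[2, ] == 0))     # both scenarios dry: ratio 0
  expect_length(tr$flagged, 0)
  # modern 0 but LGM wet: floored at eps = 0.1 and flagged
  lgm2 <- monthly_field(rbind(rep(50, 12), rep(1, 12)), g, "pr",
                        "mm/month", "lgm")
  tr2 <- compute_climate_change_trend(lgm2, modern)
  expect_equal(tr2$values[2, 1], (1 - 0.1) / 0.1)
  expect_length(tr2$flagged, 12)
})

test_that("trend computation rejects mismatched grids", {
  expect_error(
    compute_climate_change_trend(constant_field(toy_grid(), 1),
                                 constant_field(toy_grid(res = 4), 1)),
    "different grids")
})

test_that("applying trends follows the difference and ratio formulas", {
  g <- toy_grid()
  rec <- apply_trend(constant_field(g, 10),
                     glacialclim:::new_anomaly_field(
                       matrix(-5, g$n_cells, 12), g, "difference", "tas"))
  expect_true(all(rec$values == 5))
  rec2 <- apply_trend(constant_field(g, 200, variable = "pr",
                                     units = "mm/month"),
                      glacialclim:::new_anomaly_field(
                        matrix(-0.5, g$n_cells, 12), g, "ratio", "pr"))
  expect_true(all(rec2$values == 100))
})

test_that("interpolation overshoot below zero rain is clipped and counted", {
  g <- toy_grid()
  rec <- apply_trend(constant_field(g, 10, variable = "pr",
                                    units = "mm/month"),
                     glacialclim:::new_anomaly_field(
                       matrix(-1.3, g$n_cells, 12), g, "ratio", "pr"))
  expect_true(all(rec$values == 0))
  expect_equal(attr(rec, "n_clipped"), g$n_cells * 12L)
})

test_that("change-factor round trip: identical scenarios reconstruct the modern layer", {
  # LGM == modern => zero trend => reconstructed LGM == interpolated
  # modern, bit-equal for differences
  g_native <- grid_spec(4, c(-40, 40), c(-20, 20))
  g_target <- grid_spec(1, c(-40, 40), c(-20, 20))
  f <- generate_gaussian_field(g_native, field_params(mean = 12, sill = 9,
                                                      range = 15, seed = 77))
  lgm <- monthly_field(f$values, g_native, "tas", "degC", "lgm")
  res <- downscale_field(f, lgm, g_target)
  expect_identical(res$lgm$values, res$modern$values)
  # ratio trends: same property within 1e-10
  fp <- generate_gaussian_field(g_native, field_params(mean = 120, sill = 400,
                                                       range = 15, seed = 78),
                                variable = "pr", units = "mm/month",
                                clip_zero = TRUE)
  lgm_p <- monthly_field(fp$values, g_native, "pr", "mm/month", "lgm")
  res_p <- downscale_field(fp, lgm_p, g_target)
  expect_lt(max(abs(res_p$lgm$values - res_p$modern$values)), 1e-10)
})

test_that("spatially constant temperature trends shift the interpolated field", {
  g_native <- grid_spec(4, c(-40, 40), c(-20, 20))
  g_target <- grid_spec(2, c(-40, 40), c(-20, 20))
  f <- generate_gaussian_field(g_native, field_params(mean = 10, sill = 4,
                                                      range = 12, seed = 79))
  lgm <- monthly_field(f$values - 6, g_native, "tas", "degC", "lgm")
  res <- downscale_field(f, lgm, g_target)
  expect_equal(res$lgm$values, res$modern$values - 6, tolerance = 1e-8)
})

test_that("MSE benchmark reproduces closed-form cases", {
  set.seed(90)
  z <- rnorm(2000)
  r <- mse_benchmark(z, list(same = z, shifted = z + 3), n_points = 500,
                     n_reps = 50, seed = 7)
  expect_true(all(r$mse[, "same"] == 0))
  expect_true(all(abs(r$mse[, "shifted"] - 9) < 1e-12))
  # deterministic given seed
  r2 <- mse_benchmark(z, list(same = z, shifted = z + 3), n_points = 500,
                      n_reps = 50, seed = 7)
  expect_identical(r$mse, r2$mse)
  expect_warning(mse_benchmark(z, list(a = z), n_points = 5000, n_reps = 2),
                 "available cells")
})

test_that("kriging beats IDW in median MSE on its own model's fields", {
  g_fine <- grid_spec(0.5, c(0, 30), c(0, 30))
  f <- generate_gaussian_field(g_fine, field_params(nugget = 0.3, sill = 2.3,
                                                    range = 8, seed = 55))
  ctr <- grid_centers(g_fine)
  z <- f$values[, 1]
  keep <- which(ctr$lon %% 2 == 0.25 & ctr$lat %% 2 == 0.25)  # 2 deg subgrid
  sv <- empirical_variogram(ctr$lon[keep], ctr$lat[keep], z[keep])
  vm <- suppressWarnings(fit_spherical_variogram(sv))
  kr <- krige_to_grid(ctr$lon[keep], ctr$lat[keep], z[keep], vm, g_fine)
  iw <- interpolate_idw(ctr$lon[keep], ctr$lat[keep], z[keep], g_fine)
  res <- mse_benchmark(z, list(kriging = as.numeric(kr), idw = iw),
                       n_points = 500, n_reps = 100, seed = 3)
  med <- apply(res$mse, 2, stats::median)
  expect_lte(med["kriging"], med["idw"])
})
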