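# A tiny grid and fabricated per-model stacks drive the agreement
# statistics; bigger integration runs live in the synthetic-ensemble
# tests.

tiny_grid <- grid_spec(10, c(0, 30), c(0, 20))  # 6 cells

cube_from_values <- function(per_model, grid = tiny_grid) {
  # per_model: named list of single values or length-n_cells vectors;
  # every variable gets the same per-model map
  mats <- lapply(per_model, function(v) {
    matrix(rep_len(v, grid$n_cells), grid$n_cells, 19)
  })
  toy_cube(mats, grid)
}

test_that("ensemble SD is the sample SD across models", {
  cube <- cube_from_values(setNames(as.list(1:9), paste0("m", 1:9)))
  s <- ensemble_sd(cube, "BIO1")
  expect_equal(as.numeric(s), rep(sqrt(7.5), 6))
  # identical models: zero spread
  cube0 <- cube_from_values(list(a = 4, b = 4, c = 4))
  expect_true(all(ensemble_sd(cube0, "BIO5") == 0))
})

test_that("SD skips masked models and masks below two models", {
  g <- tiny_grid
  mats <- lapply(setNames(as.list(1:9), paste0("m", 1:9)), function(v) {
    matrix(v, g$n_cells, 19)
  })
  mats[["m9"]][1, ] <- NA  # model 9 masked at cell 1
  cube <- toy_cube(mats, g)
  s <- ensemble_sd(cube, "BIO1")
  expect_equal(s[1], sd(1:8))
  expect_equal(s[2], sd(1:9))
  expect_equal(attr(s, "n_models")[1], 8)
})

test_that("QCD follows (q3 - q1)/(q3 + q1) with type-7 quartiles", {
  # five models 0..4: type-7 quartiles are exactly 1 and 3 -> QCD 0.5
  cube <- cube_from_values(list(a = 0, b = 1, c = 2, d = 3, e = 4))
  q <- ensemble_qcd(cube, "BIO12")
  expect_equal(as.numeric(q), rep(0.5, 6))
  # identical models: QCD 0
  cube0 <- cube_from_values(list(a = 7, b = 7, c = 7, d = 7))
  expect_true(all(ensemble_qcd(cube0, "BIO12") == 0))
})

test_that("QCD matches an order-statistics oracle on random ensembles", {
  g <- grid_spec(10, c(0, 10), c(0, 10))
  set.seed(41)
  for (rep in 1:200) {
    vals <- rnorm(9, 50, 20)
    cube <- toy_cube(lapply(setNames(as.list(vals), paste0("m", 1:9)),
                            function(v) matrix(v, 1, 19)), g)
    q <- ensemble_qcd(cube, "BIO13")
    q1 <- quantile7_oracle(vals, 0.25)
    q3 <- quantile7_oracle(vals, 0.75)
    expect_equal(as.numeric(q), (q3 - q1) / (q3 + q1), tolerance = 1e-12)
  }
})

test_that("Celsius-scale variables are shifted to Kelvin before quartiles", {
  # around 0 degC the unshifted ratio would blow up / change sign
  cube <- cube_from_values(list(a = -2, b = -1, c = 1, d = 2))
  q <- ensemble_qcd(cube, "BIO1")
  expect_equal(attr(q, "shift"), 273.15)
  k <- c(-2, -1, 1, 2) + 273.15
  q1 <- quantile7_oracle(k, 0.25); q3 <- quantile7_oracle(k, 0.75)
  expect_equal(as.numeric(q), rep((q3 - q1) / (q3 + q1), 6))
  # precipitation variables are not shifted
  expect_equal(attr(ensemble_qcd(cube, "BIO12"), "shift"), 0)
})

test_that("QCD is scale-invariant and SD scales linearly", {
  vals <- c(10, 20, 35, 50, 80)
  cube1 <- cube_from_values(setNames(as.list(vals), paste0("m", 1:5)))
  cube3 <- cube_from_values(setNames(as.list(3 * vals), paste0("m", 1:5)))
  expect_equal(as.numeric(ensemble_qcd(cube3, "BIO12")),
               as.numeric(ensemble_qcd(cube1, "BIO12")), tolerance = 1e-12)
  expect_equal(as.numeric(ensemble_sd(cube3, "BIO12")),
               3 * as.numeric(ensemble_sd(cube1, "BIO12")))
})

test_that("statistics are invariant under model reordering", {
  g <- tiny_grid
  set.seed(43)
  mats <- lapply(setNames(1:9, paste0("m", 1:9)), function(i) {
    matrix(rnorm(g$n_cells * 19, 50, 10), g$n_cells, 19)
  })
  cube_a <- toy_cube(mats, g)
  cube_b <- toy_cube(rev(mats), g)
  expect_equal(as.numeric(ensemble_sd(cube_a, "BIO2")),
               as.numeric(ensemble_sd(cube_b, "BIO2")))
  expect_equal(as.numeric(ensemble_qcd(cube_a, "BIO16")),
               as.numeric(ensemble_qcd(cube_b, "BIO16")))
})

test_that("agreement mask applies the all-variables rule", {
  n <- tiny_grid$n_cells
  maps <- setNames(lapply(1:19, function(i) rep(0, n)), bio_names())
  expect_true(all(agreement_mask(maps) == 1))
  maps$BIO7 <- rep(0.6, n)   # one variable above threshold everywhere
  expect_true(all(agreement_mask(maps) == 0))
  # threshold monotonicity: raising it never removes an agreeing cell
  maps2 <- setNames(lapply(1:19, function(i) runif(n, 0, 1)), bio_names())
  m_lo <- agreement_mask(maps2, threshold = 0.4)
  m_hi <- agreement_mask(maps2, threshold = 0.7)
  expect_true(all(m_hi[m_lo == 1] == 1))
  # masked variable -> undefined cell; absent variable -> error
  maps3 <- maps
  maps3$BIO7 <- rep(0, n)
  maps3$BIO1[2] <- NA
  expect_true(is.na(agreement_mask(maps3)[2]))
  expect_error(agreement_mask(maps3[-1]), "missing QCD")
})

test_that("zonal profiles aggregate by latitude band, south to north", {
  g <- grid_spec(1, c(0, 10), c(-30, 30))
  ctr <- grid_centers(g)
  prof <- zonal_profile(rep(4, g$n_cells), g, band_width_deg = 10)
  expect_true(all(prof$mean == 4))
  expect_equal(nrow(prof), 6)
  expect_true(!is.unsorted(prof$lat))
  prof2 <- zonal_profile(abs(ctr$lat), g, band_width_deg = 10)
  expect_true(all(abs(prof2$mean - abs(prof2$lat)) <= 5))
})

test_that("region summaries match a per-label loop oracle", {
  g <- grid_spec(1, c(0, 10), c(0, 10))
  ctr <- grid_centers(g)
  # two constant regions
  mask <- ifelse(ctr$lon < 5, "west", "east")
  map <- ifelse(ctr$lon < 5, 2, 5)
  tab <- region_summary(map, mask)
  expect_equal(tab$mean[tab$region == "west"], 2)
  expect_equal(tab$mean[tab$region == "east"], 5)
  # checkerboard vs explicit loop
  set.seed(47)
  map2 <- rnorm(g$n_cells)
  mask2 <- rep_len(c(1, 2), g$n_cells)
  tab2 <- region_summary(map2, mask2)
  for (lb in c(1, 2)) {
    v <- c()
    for (i in seq_len(g$n_cells)) if (mask2[i] == lb) v <- c(v, map2[i])
    expect_equal(tab2$mean[tab2$region == lb], mean(v))
    expect_equal(tab2$sd[tab2$region == lb], sd(v))
    expect_equal(tab2$n_cells[tab2$region == lb], length(v))
  }
  # single region covering everything equals the global mean
  tab3 <- region_summary(map2, rep(1, g$n_cells))
  expect_equal(tab3$mean, mean(map2))
})
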