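grid6 <- grid_spec(10, c(0, 30), c(0, 20))

test_that("pairwise correlations reproduce hand-computed Pearson r", {
  g <- grid_spec(10, c(0, 20), c(0, 20))  # 4 cells
  A <- c(1, 2, 3, 4)
  B <- c(1, 2, 3, 5)
  cube <- toy_cube(list(A = matrix(A, 4, 19), B = matrix(B, 4, 19),
                        C = matrix(2 * A + 1, 4, 19),
                        D = matrix(-A, 4, 19)), g)
  r <- pairwise_model_correlation(cube, "BIO1")
  # direct-formula oracle
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r["A", "B"], pearson(A, B))
  expect_equal(r["A", "C"], 1)    # affine image
  expect_equal(r["A", "D"], -1)   # sign flip
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("zero-variance models are masked and flagged", {
  g <- grid_spec(10, c(0, 20), c(0, 20))
  cube <- toy_cube(list(A = matrix(1:4, 4, 19),
                        B = matrix(7, 4, 19),
                        C = matrix(4:1, 4, 19)), g)
  r <- pairwise_model_correlation(cube, "BIO2")
  expect_true(is.na(r["A", "B"]))
  expect_equal(attr(r, "flagged"), "B")
  expect_equal(r["A", "C"], -1)
})

test_that("clustering recovers a planted partition and renumbers groups", {
  set.seed(51)
  n <- 200
  base <- lapply(1:4, function(i) rnorm(n))
  mats <- list()
  part <- c(1, 2, 2, 3, 3, 3, 4, 4, 4)
  for (i in seq_along(part)) {
    mats[[paste0("m", i)]] <- matrix(base[[part[i]]] + 0.05 * rnorm(n),
                                     n, 19)
  }
  g <- grid_spec(1, c(0, 20), c(0, 10))
  cube <- toy_cube(mats, g)
  r <- pairwise_model_correlation(cube, "BIO1")
  cl <- cluster_models(r, k = 4)
  expect_equal(unname(cl$labels), part)  # first-appearance numbering
  expect_false(cl$degenerate)
})

test_that("clustering is invariant under model reordering", {
  set.seed(53)
  n <- 150
  base <- lapply(1:3, function(i) rnorm(n))
  part <- c(1, 1, 2, 2, 3, 3)
  mats <- setNames(lapply(seq_along(part), function(i) {
    matrix(base[[part[i]]] + 0.05 * rnorm(n), n, 19)
  }), paste0("m", seq_along(part)))
  g <- grid_spec(1, c(0, 15), c(0, 10))
  cl1 <- cluster_models(pairwise_model_correlation(toy_cube(mats, g),
                                                   "BIO4"), k = 3)
  perm <- c(5, 3, 1, 6, 2, 4)
  cl2 <- cluster_models(pairwise_model_correlation(toy_cube(mats[perm], g),
                                                   "BIO4"), k = 3)
  # same partition up to label permutation
  lab1 <- cl1$labels[paste0("m", seq_along(part))]
  lab2 <- cl2$labels[paste0("m", seq_along(part))]
  expect_equal(outer(lab1, lab1, "=="), outer(lab2, lab2, "=="),
               ignore_attr = TRUE)
})

test_that("dendrogram cuts at k and k+1 nest, and k is validated", {
  set.seed(57)
  n <- 100
  mats <- setNames(lapply(1:6, function(i) matrix(rnorm(n), n, 19)),
                   paste0("m", 1:6))
  g <- grid_spec(1, c(0, 10), c(0, 10))
  r <- pairwise_model_correlation(toy_cube(mats, g), "BIO9")
  cl3 <- cluster_models(r, k = 3)
  cl4 <- cluster_models(r, k = 4)
  # k+1 refines k: each k=4 group sits inside one k=3 group
  split_count <- tapply(cl3$labels, cl4$labels,
                        function(v) length(unique(v)))
  expect_true(all(split_count == 1))
  expect_error(cluster_models(r, k = 7), "exceeds")
})

test_that("identical models cluster degenerately but deterministically", {
  g <- grid_spec(10, c(0, 20), c(0, 20))
  m <- matrix(1:4, 4, 19)
  cube <- toy_cube(list(a = m, b = m, c = m, d = m, e = m), g)
  cl <- cluster_models(pairwise_model_correlation(cube, "BIO1"), k = 4)
  expect_true(cl$degenerate)
  expect_equal(length(unique(cl$labels)), 4)
})

test_that("consensus clustering averages per-variable distances", {
  set.seed(59)
  n <- 120
  base <- lapply(1:2, function(i) rnorm(n))
  part <- c(1, 1, 2, 2)
  mats <- setNames(lapply(seq_along(part), function(i) {
    matrix(base[[part[i]]] + 0.1 * rnorm(n * 19), n, 19)
  }), paste0("m", seq_along(part)))
  g <- grid_spec(1, c(0, 12), c(0, 10))
  cube <- toy_cube(mats, g)
  mlist <- setNames(lapply(bio_names(), function(v) {
    pairwise_model_correlation(cube, v)
  }), bio_names())
  cl <- cluster_models(mlist, k = 2)
  expect_equal(unname(cl$labels), part)
})

test_that("correlation summaries carry families, values and outliers", {
  g <- grid_spec(10, c(0, 20), c(0, 20))
  m <- matrix(1:4, 4, 19)
  set.seed(61)
  cube <- toy_cube(list(A = m, B = m + matrix(rnorm(76, 0, 0.5), 4, 19)),
                   g)
  mlist <- setNames(lapply(bio_names(), function(v) {
    pairwise_model_correlation(cube, v)
  }), bio_names())
  cs <- correlation_summary(mlist)
  expect_equal(nrow(cs$pairs), 19)    # one pair per variable
  expect_equal(bio_family("BIO11"), "temperature")
  expect_equal(bio_family("BIO12"), "precipitation")
  expect_true(all(cs$pairs$family[cs$pairs$variable == "BIO11"] ==
                    "temperature"))
  # two models, identical r on every variable: summary rows all equal it
  m2 <- matrix(c(1, 2, 3, 5), 4, 19)
  cube2 <- toy_cube(list(A = m, B = m2), g)
  mlist2 <- setNames(lapply(bio_names(), function(v) {
    pairwise_model_correlation(cube2, v)
  }), bio_names())
  cs2 <- correlation_summary(mlist2)
  r_ab <- cor(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_true(all(abs(cs2$pairs$r - r_ab) < 1e-12))
  expect_true(all(cs2$by_model$n_outliers == 0))
})

test_that("a precipitation-aberrant model has the lowest precipitation r", {
  set.seed(63)
  n <- 300
  shared_t <- rnorm(n)
  shared_p <- rnorm(n)
  mats <- list()
  for (i in 1:5) {
    temp <- matrix(shared_t + 0.1 * rnorm(n), n, 11)
    prec <- if (i == 3) {
      matrix(rnorm(n * 8), n, 8)          # aberrant precipitation only
    } else {
      matrix(shared_p + 0.1 * rnorm(n), n, 8)
    }
    mats[[paste0("m", i)]] <- cbind(temp, prec)
  }
  g <- grid_spec(1, c(0, 30), c(0, 10))
  cube <- toy_cube(mats, g)
  mlist <- setNames(lapply(bio_names(), function(v) {
    pairwise_model_correlation(cube, v)
  }), bio_names())
  cs <- correlation_summary(mlist)
  med_p <- cs$by_model[cs$by_model$family == "precipitation", ]
  expect_equal(med_p$model[which.min(med_p$median)], "m3")
  med_t <- cs$by_model[cs$by_model$family == "temperature", ]
  expect_gt(min(med_t$median), 0.9)
})

test_that("cluster tables and Newick export have the published shapes", {
  g <- grid_spec(4)
  ens <- generate_pseudo_gcm_ensemble(ensemble_config(seed = 19), g)
  stacks <- lapply(ens$models, function(m) {
    compute_bioclim(m$lgm$tas, m$lgm$tasmax, m$lgm$tasmin, m$lgm$pr)
  })
  cube <- ensemble_cube(stacks)
  tab <- cluster_table(cube, k = 4)
  expect_equal(dim(tab), c(9, 19))
  expect_true(all(unlist(tab) %in% 1:4))
  expect_equal(colnames(tab), bio_names())
  # every variable's grouping recovers the planted partition
  for (v in bio_names()) {
    expect_equal(unname(tab[[v]]), unname(ens$groups))
  }
  cl <- cluster_models(pairwise_model_correlation(cube, "BIO1"), k = 4)
  nwk <- dendrogram_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(names(ens$models), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})
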