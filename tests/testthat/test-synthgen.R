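test_that("config invariants are enforced", {
  expect_error(sim_config(grid_rows = 0), "dimensions")
  expect_error(sim_config(covariate_smoothness = 0), "smoothness")
  expect_error(sim_config(true_p_det = 1), "true_p_det")
  expect_error(sim_config(grid_rows = 5, grid_cols = 5, n_cameras = 26),
               "more cameras than cells")
  expect_error(sim_config(design = "clustered", n_cameras = 100,
                          n_clusters = 10, cameras_per_cluster = 4),
               "n_clusters")
})

test_that("landscapes are standardized, seeded and spatially structured", {
  cfg <- sim_config(grid_rows = 50, grid_cols = 40, rng_seed = 3)
  g <- gen_landscape(cfg)
  expect_s3_class(g, "cell_grid")
  expect_false(any(g$mask))
  # continuous covariates: mean 0 / sd 1 to numerical precision
  for (j in which(g$cov_type == "continuous")) {
    expect_lt(abs(mean(g$covariates[, j])), 1e-9)
    expect_lt(abs(sd(g$covariates[, j]) - 1), 1e-9)
  }
  expect_lt(abs(mean(g$bias)), 1e-9)
  # binary covariates are 0/1
  for (j in which(g$cov_type == "binary"))
    expect_true(all(g$covariates[, j] %in% c(0, 1)))
  # determinism: same seed gives bit-identical grids
  expect_identical(g, gen_landscape(cfg))
  expect_false(identical(g$covariates,
                         gen_landscape(sim_config(grid_rows = 50,
                                                  grid_cols = 40,
                                                  rng_seed = 4))$covariates))
  # smoothing induces positive autocorrelation between row neighbours
  f <- matrix(g$covariates[, 1], cfg$grid_rows, cfg$grid_cols, byrow = TRUE)
  expect_gt(cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ])), 0.5)
})

test_that("a vanishing smoothing kernel leaves iid standard normal noise", {
  cfg <- sim_config(grid_rows = 100, grid_cols = 100,
                    covariate_smoothness = 1e-6, n_binary = 0,
                    true_beta = c(0, 0), rng_seed = 8)
  g <- gen_landscape(cfg)
  ks <- suppressWarnings(ks.test(g$covariates[, 1], "pnorm"))
  expect_gt(ks$p.value, 0.01)
  f <- matrix(g$covariates[, 1], 100, 100, byrow = TRUE)
  expect_lt(abs(cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ]))), 0.05)
})

test_that("latent abundance follows the Poisson intensity", {
  # beta = 0: lambda * A = 1 per 1-ha cell
  g <- cell_grid(100, 100, matrix(rnorm(10000), ncol = 1), bias = rep(0, 1e4))
  tr <- sim_latent_abundance(g, c(0, 0), seed = 2)
  expect_equal(tr$expected_total, 10000)
  se <- sqrt(10000) / sqrt(10000)  # sd of the mean of 1e4 Poisson(1) draws
  expect_lt(abs(mean(tr$latent_N) - 1), 3 * se)
  # Z/N consistency
  expect_identical(tr$latent_Z, as.integer(tr$latent_N > 0))
  # vanishing intensity
  tr0 <- sim_latent_abundance(g, c(-50, 0), seed = 2)
  expect_true(all(tr0$latent_N == 0) && all(tr0$latent_Z == 0))
  # doubling areas doubles the expected total exactly
  g2 <- g; g2$area <- g$area * 2
  expect_equal(sim_latent_abundance(g2, c(0.3, 0.1), seed = 1)$expected_total,
               2 * sim_latent_abundance(g, c(0.3, 0.1), seed = 1)$expected_total)
  expect_error(sim_latent_abundance(g, c(0, 0, 0), seed = 1), "length")
})

test_that("presence-only thinning has binomial moments and edge behaviour", {
  g <- cell_grid(10, 10, matrix(rnorm(100), ncol = 1), bias = rep(0, 100))
  tr <- sim_latent_abundance(g, c(1, 0), seed = 4)
  # b = 0 -> empty; b = 1 -> every individual retained
  expect_equal(nrow(sim_po_points(tr, g, c(-40, 0), seed = 1)), 0)
  expect_equal(nrow(sim_po_points(tr, g, c(40, 0), seed = 1)),
               tr$realized_total)
  # b = 0.5: mean ~ N/2, sd ~ sqrt(N/4) over replicates
  counts <- vapply(1:200, function(s)
    nrow(sim_po_points(tr, g, c(0, 0), seed = s)), 0L)
  n_tot <- tr$realized_total
  expect_lt(abs(mean(counts) - n_tot / 2), 3 * sqrt(n_tot / 4) / sqrt(200))
  expect_lt(abs(sd(counts) - sqrt(n_tot / 4)), 0.2 * sqrt(n_tot / 4))
  # all retained points carry valid cells
  po <- sim_po_points(tr, g, c(0, -1), seed = 9)
  expect_true(all(po$cell_id %in% which(tr$latent_N > 0)))
})

test_that("binomial-thinning conservation: mean PO count matches the thinned intensity", {
  cfg <- sim_config(grid_rows = 40, grid_cols = 40, true_beta = c(-0.5, 0.4),
                    n_binary = 0, covariate_smoothness = 3)
  g <- gen_landscape(cfg)
  delta <- c(-0.7, -0.8)
  b <- thinning_prob(g$bias, delta)
  lam <- intensity(g$covariates, cfg$true_beta)
  expected <- sum(lam * b * g$area)
  counts <- vapply(1:200, function(s) {
    tr <- sim_latent_abundance(g, cfg$true_beta, seed = 1000 + s)
    nrow(sim_po_points(tr, g, delta, seed = 2000 + s))
  }, 0L)
  # PO count is Poisson(expected); check the mean within 3 standard errors
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 200))
})

test_that("camera placement honours both designs", {
  cfg_e <- sim_config(grid_rows = 100, grid_cols = 100, n_cameras = 100)
  g <- gen_landscape(cfg_e)
  cams <- place_cameras(g, cfg_e)
  expect_equal(nrow(cams), 100)
  expect_false(anyDuplicated(cams$cell_id) > 0)
  # lattice regularity: nearest-neighbour distances nearly constant
  d <- as.matrix(dist(cams[, c("row", "col")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.2)

  cfg_c <- sim_config(grid_rows = 100, grid_cols = 100, n_cameras = 100,
                      design = "clustered", n_clusters = 25,
                      cameras_per_cluster = 4)
  cams_c <- place_cameras(g, cfg_c, seed = 5)
  expect_equal(nrow(cams_c), 100)
  expect_equal(length(unique(cams_c$cluster)), 25)
  expect_false(anyDuplicated(cams_c$cell_id) > 0)
  # cameras stay within their cluster's 3x3 box
  for (k in unique(cams_c$cluster)) {
    sub <- cams_c[cams_c$cluster == k, ]
    expect_lte(diff(range(sub$row)), 2)
    expect_lte(diff(range(sub$col)), 2)
  }
  # determinism
  expect_identical(cams_c, place_cameras(g, cfg_c, seed = 5))

  # degenerate single-camera design works under both designs
  cfg1e <- sim_config(grid_rows = 10, grid_cols = 10, n_cameras = 1)
  cfg1c <- sim_config(grid_rows = 10, grid_cols = 10, n_cameras = 1,
                      design = "clustered", n_clusters = 1,
                      cameras_per_cluster = 1)
  g10 <- gen_landscape(cfg1e)
  expect_equal(nrow(place_cameras(g10, cfg1e)), 1)
  expect_equal(nrow(place_cameras(g10, cfg1c)), 1)
})

test_that("detection histories are Bernoulli given occupancy", {
  g <- cell_grid(100, 100, matrix(0, 1e4, 1), bias = rep(0, 1e4))
  # every cell occupied (huge intercept)
  tr1 <- sim_latent_abundance(g, c(3, 0), seed = 1)
  cams <- data.frame(camera_id = 1:10000, cell_id = 1:10000)
  hist <- sim_detection_histories(tr1, cams, p_det = 0.3, n_nights = 40,
                                  seed = 2)
  tot <- tally_detections(hist)
  expect_equal(nrow(hist), 10000 * 40)
  # mean detections per camera ~ 12 within 3 standard errors
  expect_lt(abs(mean(tot$detections) - 12),
            3 * sqrt(40 * 0.3 * 0.7) / sqrt(10000))
  # certain detection
  h1 <- sim_detection_histories(tr1, cams[1:5, ], p_det = 1, n_nights = 7,
                                seed = 3)
  expect_true(all(h1$detected == 1))
  # unoccupied cells never detect
  tr0 <- sim_latent_abundance(g, c(-50, 0), seed = 1)
  h0 <- sim_detection_histories(tr0, cams[1:100, ], p_det = 0.9,
                                n_nights = 10, seed = 4)
  expect_true(all(h0$detected == 0))
})

test_that("the full generator pipeline is a pure function of config and seed", {
  cfg <- small_config()
  s1 <- simulate_survey(cfg, seed = 77)
  s2 <- simulate_survey(cfg, seed = 77)
  expect_identical(s1$grid, s2$grid)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$po, s2$po)
  expect_identical(s1$histories, s2$histories)
  s3 <- simulate_survey(cfg, seed = 78)
  expect_false(identical(s1$truth$latent_N, s3$truth$latent_N))
})
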