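mk_images <- function(times, camera = "C1", species = "MG") {
  data.frame(camera_id = camera, species = species,
             timestamp = as.POSIXct(times, tz = "UTC"))
}

test_that("the 30-minute incident rule is applied per camera and species", {
  # 20:00, 20:10, 20:45 -> two incidents (20:45 is 35 min after 20:10)
  img <- mk_images(c("2021-06-01 20:00:00", "2021-06-01 20:10:00",
                     "2021-06-01 20:45:00"))
  inc <- filter_incidents(img)
  expect_equal(nrow(inc), 2)
  expect_equal(format(inc$timestamp, "%H:%M"), c("20:00", "20:45"))

  # single image is an incident
  expect_equal(nrow(filter_incidents(mk_images("2021-06-01 03:00:00"))), 1)

  # exact 30-minute spacing: boundary inclusive, every image an incident
  img30 <- mk_images(c("2021-06-01 20:00:00", "2021-06-01 20:30:00",
                       "2021-06-01 21:00:00"))
  expect_equal(nrow(filter_incidents(img30)), 3)

  # separate species and cameras never share windows
  img2 <- rbind(mk_images(c("2021-06-01 20:00:00", "2021-06-01 20:05:00")),
                mk_images("2021-06-01 20:06:00", species = "possum"),
                mk_images("2021-06-01 20:07:00", camera = "C2"))
  expect_equal(nrow(filter_incidents(img2)), 3)

  # unparseable timestamps are counted, not fatal
  bad <- data.frame(camera_id = "C1", species = "MG",
                    timestamp = c("2021-06-01 20:00:00", "not a time"))
  out <- filter_incidents(bad)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_rejected"), 1)
})

test_that("incident filtering is idempotent", {
  set.seed(1)
  t0 <- as.POSIXct("2021-06-01 18:00:00", tz = "UTC")
  img <- data.frame(camera_id = sample(c("A", "B"), 60, replace = TRUE),
                    species = sample(c("MG", "KG"), 60, replace = TRUE),
                    timestamp = t0 + cumsum(rexp(60, 1 / 1200)))
  once <- filter_incidents(img)
  twice <- filter_incidents(once)
  attr(once, "n_rejected") <- NULL; attr(twice, "n_rejected") <- NULL
  expect_identical(once, twice)
})

test_that("effort accounting multiplies cameras by nights with per-camera variation", {
  # 20 cameras x 27 nights = 540 camera-nights
  site1 <- data.frame(camera_id = 1:20, site = "Abergowrie", nights = 27)
  expect_equal(compute_effort(site1)$camera_nights, 540)
  # mixed 41/42-night deployments summing to 832
  site2 <- data.frame(camera_id = 1:20, site = "Allendale",
                      nights = c(rep(41, 8), rep(42, 12)))
  expect_equal(compute_effort(site2)$camera_nights, 832)
  # zero cameras -> empty table
  expect_equal(nrow(compute_effort(site1[0, ])), 0)
  # multiple sites kept separate
  both <- rbind(site1, site2)
  eff <- compute_effort(both)
  expect_equal(eff$camera_nights[match(c("Abergowrie", "Allendale"),
                                       eff$site)], c(540, 832))
})

test_that("naive capture rates reproduce the survey table arithmetic", {
  expect_equal(naive_capture_rate(78, 832), 9.38)
  expect_equal(naive_capture_rate(0, 540), 0)
  expect_equal(naive_capture_rate(22, 894), 2.46)
  expect_equal(naive_capture_rate(19, 1016), 1.87)
  expect_equal(naive_capture_rate(3, 840), 0.36)
  expect_error(naive_capture_rate(1, 0), "effort")
})

test_that("presence-only cleaning drops incomplete and pre-cutoff records", {
  rec <- data.frame(cell_id = 1:5,
                    year = c(1985, 2001, 2010, NA, 1995),
                    count = c(2, 5, NA, 1, 3),
                    complete = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- clean_po(rec)
  r <- attr(out, "retention")
  expect_equal(out$cell_id, c(2, 3))        # 1985 dropped, NA/incomplete dropped
  expect_true(all(out$presence == 1))
  expect_null(out$count)                    # counts become presences
  expect_equal(r$n_input, 5)
  expect_equal(r$n_retained, 2)
  expect_equal(r$n_pre_cutoff, 1)
  expect_equal(r$n_incomplete, 2)
  # empty input
  e <- clean_po(rec[0, ])
  expect_equal(nrow(e), 0)
  expect_equal(attr(e, "retention")$n_retained, 0)
  # cutoff is configurable
  expect_equal(nrow(clean_po(rec, cutoff_year = 1980)), 3)
})

test_that("covariate standardization respects roles, masks and scalers", {
  set.seed(6)
  covs <- cbind(env1 = rnorm(100, 5, 3), hab = rep(c(0, 1), 50))
  mask <- rep(c(FALSE, FALSE, FALSE, TRUE), 25)
  g <- cell_grid(10, 10, covs, bias = rnorm(100), mask = mask,
                 cov_type = c("continuous", "binary"))
  gs <- standardize_covariates(g)
  keep <- !g$mask
  expect_lt(abs(mean(gs$covariates[keep, 1])), 1e-9)
  expect_lt(abs(sd(gs$covariates[keep, 1]) - 1), 1e-9)
  # binary column untouched
  expect_identical(gs$covariates[, 2], covs[, 2])
  # scaler statistics computed over unmasked cells only
  sc <- attr(gs, "scaler")
  expect_equal(sc$mean[1], mean(covs[keep, 1]))
  g_all <- cell_grid(10, 10, covs, bias = rnorm(100),
                     cov_type = c("continuous", "binary"))
  expect_false(isTRUE(all.equal(attr(standardize_covariates(g_all),
                                     "scaler")$mean[1], sc$mean[1])))
  # reusing a scaler reproduces the transform; name mismatch errors
  gs2 <- standardize_covariates(g, scaler = sc)
  expect_identical(gs2$covariates, gs$covariates)
  colnames(g_all$covariates) <- c("other", "hab")
  expect_error(standardize_covariates(g_all, scaler = sc), "mismatch")
  # zero-variance continuous covariate errors by name
  g0 <- cell_grid(2, 2, cbind(flat = rep(1, 4)), bias = rnorm(4))
  expect_error(standardize_covariates(g0), "flat")
})

test_that("grid aggregation averages covariates, sums areas and maps cell areas as documented", {
  # factor 1 is the identity
  g <- tiny_grid(4, 4, ncov = 2)
  expect_identical(aggregate_grid(g, aggregation_spec(1)), g)
  # 2x2 block of values {1,2,3,4} -> coarse mean 2.5
  covs <- cbind(v = c(1, 2, 3, 4))
  g2 <- cell_grid(2, 2, covs, bias = c(1, 2, 3, 4), area = 1)
  cg <- aggregate_grid(g2, aggregation_spec(2))
  expect_equal(unname(cg$covariates[1, 1]), 2.5)
  expect_equal(cg$bias[1], 2.5)
  expect_equal(cg$area[1], 4)
  # factor 3 on 1-ha pixels gives 9-ha cells; factor 5 gives 25 ha
  expect_equal(aggregation_spec(3)$cell_area, 9)
  expect_equal(aggregation_spec(5)$cell_area, 25)
  g9 <- tiny_grid(9, 9)
  expect_equal(unique(unname(aggregate_grid(g9, aggregation_spec(3))$area)), 9)
  expect_error(aggregation_spec(0), "factor")
})

test_that("aggregation handles masks and ragged edges by mask-padding", {
  covs <- cbind(v = 1:12)
  mask <- c(TRUE, TRUE, FALSE, rep(FALSE, 9))
  g <- cell_grid(3, 4, covs, bias = rep(0, 12), area = 2, mask = mask)
  cg <- aggregate_grid(g, aggregation_spec(2, base_pixel_area = 2))
  expect_equal(cg$rows, 2); expect_equal(cg$cols, 2)
  # top-left block: cells 1,2 masked; mean over cells 5,6 only
  expect_equal(unname(cg$covariates[1, 1]), mean(c(5, 6)))
  expect_equal(cg$area[1], 4)
  # fully masked block stays masked after aggregation (commutes with masking)
  g_all_masked <- cell_grid(2, 2, cbind(v = 1:4), bias = rep(0, 4),
                            mask = rep(TRUE, 4))
  cg2 <- aggregate_grid(g_all_masked, aggregation_spec(2))
  expect_true(all(cg2$mask))
  # ragged 3x3 grid at factor 2 pads to 2x2 coarse cells
  g3 <- tiny_grid(3, 3)
  cg3 <- aggregate_grid(g3, aggregation_spec(2))
  expect_equal(c(cg3$rows, cg3$cols), c(2L, 2L))
  expect_false(any(cg3$mask))  # every coarse cell has >= 1 fine constituent
})

test_that("camera subsampling implements max, mean and sum with their contracts", {
  g <- tiny_grid(6, 6)
  # three cameras, two sharing a coarse cell at factor 3
  h <- data.frame(unit_id = c(10L, 2L, 3L), cell_id = c(1L, 9L, 22L),
                  nights = c(10, 10, 10), detections = c(3, 7, 2))
  # cells 1 and 9 are in coarse cell 1; cell 22 in coarse cell 4
  sp_max <- aggregation_spec(3, "max")
  out <- assign_and_subsample(h, g, sp_max)
  expect_equal(nrow(out), 2)
  expect_equal(out$detections[out$cell_id == 1], 7)    # highest wins
  expect_equal(out$unit_id[out$cell_id == 1], 2)
  # tie broken by lowest camera id
  h_tie <- h; h_tie$detections <- c(7, 7, 2)
  out_tie <- assign_and_subsample(h_tie, g, sp_max)
  expect_equal(out_tie$unit_id[out_tie$cell_id == 1], 2)
  # sum pools detections and nights
  out_sum <- assign_and_subsample(h, g, aggregation_spec(3, "sum"))
  expect_equal(out_sum$detections[out_sum$cell_id == 1], 10)
  expect_equal(out_sum$nights[out_sum$cell_id == 1], 20)
  # mean gives fractional histories and is flagged non-Bernoulli
  out_mean <- assign_and_subsample(h, g, aggregation_spec(3, "mean"))
  expect_equal(out_mean$detections[out_mean$cell_id == 1], 5)
  expect_true(attr(out_mean, "non_bernoulli"))
  # one camera per cell: all three methods return the history unchanged
  h1 <- h[3, , drop = FALSE]
  for (m in c("max", "mean", "sum")) {
    o <- assign_and_subsample(h1, g, aggregation_spec(3, m))
    expect_equal(o$detections, 2); expect_equal(o$nights, 10)
  }
  # sum violating the survey-night ceiling errors (certain detection)
  h_v <- data.frame(unit_id = 1:2, cell_id = c(1L, 9L), nights = c(10, 10),
                    detections = c(10, 10))
  expect_error(assign_and_subsample(h_v, g, aggregation_spec(3, "sum")),
               "assumption violation")
})

test_that("subsampling conserves or reduces detections as each method dictates", {
  set.seed(3)
  g <- tiny_grid(10, 10)
  # low per-camera detection totals, as the sum method requires
  h <- data.frame(unit_id = 1:20, cell_id = sample(100, 20),
                  nights = rep(12, 20), detections = rbinom(20, 12, 0.1))
  sp <- function(m) aggregation_spec(5, m)
  o_max <- assign_and_subsample(h, g, sp("max"))
  o_sum <- assign_and_subsample(h, g, sp("sum"))
  o_mean <- assign_and_subsample(h, g, sp("mean"))
  # per cell: max <= sum; mean per-night values in [0, 1]
  expect_true(all(o_max$detections <=
                    o_sum$detections[match(o_max$cell_id, o_sum$cell_id)]))
  expect_true(all(o_mean$detections / o_mean$nights >= 0 &
                    o_mean$detections / o_mean$nights <= 1))
  # sum conserves the total; max and mean cannot increase it
  expect_equal(sum(o_sum$detections), sum(h$detections))
  expect_lte(sum(o_max$detections), sum(h$detections))
  expect_lte(sum(o_mean$detections), sum(h$detections))
})
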