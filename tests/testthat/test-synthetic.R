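test_that("spec validation rejects inverted contrast and missing seed", {
  expect_error(synthetic_spec(background_mean = 60, droplet_mean = 210,
                              seed = 1), "darker|below")
  expect_error(synthetic_spec(), "seed")
  expect_error(synthetic_spec(glare_hole_prob = 2, seed = 1),
               "glare_hole_prob")
})

test_that("zero droplets gives a pure-background image with zero truth", {
  g <- generate_wsp(synthetic_spec(n_droplets = 0, seed = 1))
  expect_equal(g$truth$n_droplets_placed, 0)
  expect_equal(g$truth$coverage_pct, 0)
  expect_equal(sum(g$truth$mask$pixels), 0)
  expect_equal(dim(g$image), c(98L, 287L))
  # noise only: pixels near the background mean
  expect_true(abs(mean(g$image$pixels) - 210) < 2)
})

test_that("identical spec and seed give bit-identical output", {
  sp <- synthetic_spec(n_droplets = 12, seed = 99)
  a <- generate_wsp(sp)
  b <- generate_wsp(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask$pixels, b$truth$mask$pixels)
  expect_identical(a$truth$per_droplet, b$truth$per_droplet)
  c <- generate_wsp(synthetic_spec(n_droplets = 12, seed = 100))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("truth accounting is exact and consistent", {
  g <- generate_wsp(noise_free_spec(seed = 8))
  tr <- g$truth
  expect_equal(tr$coverage_pct,
               100 * sum(tr$mask$pixels) / length(tr$mask$pixels))
  expect_equal(tr$total_area_px, sum(tr$mask$pixels))
  expect_equal(sum(tr$per_droplet$area_px), tr$total_area_px)
  # gap enforcement: one component per placed droplet
  expect_equal(nrow(label_droplets(tr$mask)), tr$n_droplets_placed)
})

test_that("glare holes are strictly interior and do not touch the truth", {
  sp_on <- synthetic_spec(n_droplets = 15, noise_sigma = 0,
                          glare_hole_prob = 1, seed = 13)
  sp_off <- synthetic_spec(n_droplets = 15, noise_sigma = 0,
                           glare_hole_prob = 0, seed = 13)
  on <- generate_wsp(sp_on)
  off <- generate_wsp(sp_off)
  # truth is pre-glare: identical either way
  expect_identical(on$truth$mask$pixels, off$truth$mask$pixels)
  expect_equal(on$truth$n_droplets_placed, off$truth$n_droplets_placed)
  # glare bright pixels only appear inside stain footprints
  holes <- on$image$pixels != off$image$pixels
  expect_true(any(holes))
  expect_true(all(on$truth$mask$pixels[holes]))
  # and never on the footprint boundary: every hole pixel's full 3x3
  # neighbourhood is stain (interior margin >= 1)
  tm <- on$truth$mask$pixels
  idx <- which(holes, arr.ind = TRUE)
  interior <- apply(idx, 1, function(rc) {
    all(tm[(rc[1] - 1):(rc[1] + 1), (rc[2] - 1):(rc[2] + 1)])
  })
  expect_true(all(interior))
})

test_that("otsu threshold of a clean image lies between the two modes", {
  g <- generate_wsp(noise_free_spec(seed = 21))
  k <- otsu_threshold(compute_histogram(g$image))
  expect_gt(k, 60)
  expect_lt(k, 210)
})

test_that("full pipeline recovers truth on clean well-separated discs", {
  g <- generate_wsp(noise_free_spec(seed = 5))
  rep <- analyze_image(g$image, "otsu")
  expect_equal(rep$droplet_count, g$truth$n_droplets_placed)
  expect_equal(rep$coverage_pct, g$truth$coverage_pct)
})

test_that("unsatisfiable specs fail loudly, crowded ones place fewer", {
  expect_error(
    generate_wsp(synthetic_spec(width_px = 40, height_px = 40,
                                n_droplets = 500, radius_meanlog = log(6),
                                radius_sdlog = 0.1, seed = 2)),
    "unsatisfiable|placed")
  expect_warning(
    g <- generate_wsp(synthetic_spec(width_px = 60, height_px = 60,
                                     n_droplets = 60,
                                     radius_meanlog = log(4),
                                     radius_sdlog = 0.05, seed = 2)),
    "placed")
  expect_lt(g$truth$n_droplets_placed, 60)
})

test_that("group panels land inside the printed PA intervals", {
  sparse <- generate_group_panel("sparse", n_images = 3, seed = 7)
  pa <- sapply(sparse, function(x) x$truth$total_area_px)
  expect_true(all(pa > 0 & pa <= 12000))

  dense <- generate_group_panel("dense", n_images = 2, seed = 8)
  pa_d <- sapply(dense, function(x) x$truth$total_area_px)
  expect_true(all(pa_d > 40000 & pa_d < 90000))

  medium <- generate_group_panel("medium", n_images = 2, seed = 9)
  pa_m <- sapply(medium, function(x) x$truth$total_area_px)
  expect_true(all(pa_m > 12000 & pa_m <= 40000))
})

test_that("panels are reproducible from the master seed", {
  a <- generate_group_panel("sparse", n_images = 2, seed = 5)
  b <- generate_group_panel("sparse", n_images = 2, seed = 5)
  expect_identical(lapply(a, function(x) x$image$pixels),
                   lapply(b, function(x) x$image$pixels))
  expect_identical(lapply(a, function(x) x$truth$total_area_px),
                   lapply(b, function(x) x$truth$total_area_px))
})
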