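test_that("structuring elements have the documented shapes", {
  d1 <- structuring_element("disk", 1)
  expect_true(all(d1))                      # radius-1 disk = full 3x3
  expect_identical(dim(unclass(d1)), c(3L, 3L))
  s2 <- structuring_element("square", 2)
  expect_true(all(s2))
  expect_identical(dim(unclass(s2)), c(5L, 5L))
  d2 <- structuring_element("disk", 2)
  expect_false(d2[1, 1])                    # corners outside rounded disk
  expect_true(d2[1, 3])
})

test_that("closing fills holes smaller than the element", {
  m <- matrix(TRUE, 5, 5)
  m[3, 3] <- FALSE
  closed <- morphological_close(droplet_mask(m))
  expect_true(all(closed$pixels))

  # a 5-px plus-shaped hole (strict disc radius 1) is also repaired
  m2 <- matrix(TRUE, 9, 9)
  m2[cbind(c(5, 4, 6, 5, 5), c(5, 5, 5, 4, 6))] <- FALSE
  expect_true(all(morphological_close(droplet_mask(m2))$pixels))

  empty <- droplet_mask(matrix(FALSE, 6, 6))
  expect_equal(sum(morphological_close(empty)$pixels), 0)
})

test_that("closing is extensive and idempotent on random masks", {
  withr::local_seed(9)
  for (i in 1:15) {
    m <- random_mask(p = runif(1, 0.05, 0.5))
    selem <- structuring_element(sample(c("disk", "square"), 1),
                                 sample(1:2, 1))
    c1 <- morphological_close(m, selem)
    expect_true(all(c1$pixels[m$pixels]))               # extensivity
    c2 <- morphological_close(c1, selem)
    expect_identical(c2$pixels, c1$pixels)              # idempotence
  }
})

test_that("label_droplets follows the connectivity definition", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE                      # touching only diagonally
  expect_equal(nrow(label_droplets(droplet_mask(m), 8)), 1)
  expect_equal(nrow(label_droplets(droplet_mask(m), 4)), 2)

  expect_equal(nrow(label_droplets(droplet_mask(matrix(FALSE, 3, 3)))), 0)

  m3 <- matrix(FALSE, 8, 12)
  m3[1:2, 1:2] <- TRUE
  m3[5:6, 5:6] <- TRUE
  m3[7:8, 10:11] <- TRUE
  rec <- label_droplets(droplet_mask(m3))
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$area_px == 4))
})

test_that("droplet records are consistent: areas, centroids, bboxes", {
  withr::local_seed(14)
  for (i in 1:10) {
    m <- random_mask(30, 40, p = 0.25)
    rec <- label_droplets(m)
    expect_equal(sum(rec$area_px), sum(m$pixels))       # area conservation
    expect_false(anyDuplicated(rec$label) > 0)
    # bbox (half-open on max edges) contains the centroid
    expect_true(all(rec$centroid_row >= rec$min_row &
                      rec$centroid_row < rec$max_row))
    expect_true(all(rec$centroid_col >= rec$min_col &
                      rec$centroid_col < rec$max_col))
  }
})

test_that("counts, areas and content coverage are translation invariant", {
  withr::local_seed(21)
  m <- random_mask(20, 20, p = 0.3)
  rec <- label_droplets(m)
  big <- matrix(FALSE, 40, 40)
  big[11:30, 13:32] <- m$pixels                 # shifted, padded
  rec2 <- label_droplets(droplet_mask(big))
  expect_equal(nrow(rec2), nrow(rec))
  expect_equal(sort(rec2$area_px), sort(rec$area_px))
  expect_equal(sum(big), sum(m$pixels))         # foreground preserved
})

test_that("coverage is the foreground percentage", {
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:5] <- TRUE
  expect_equal(coverage(droplet_mask(m)), 25)
  expect_equal(coverage(droplet_mask(matrix(TRUE, 3, 3))), 100)
  expect_equal(coverage(droplet_mask(matrix(FALSE, 3, 3))), 0)
})

test_that("density is droplets per cm2", {
  expect_equal(droplet_density(0, 5), 0)
  expect_equal(droplet_density(50, 10), 5)
  expect_equal(droplet_density(100, 19.68942), 5.078870, tolerance = 1e-6)
  rec <- label_droplets(droplet_mask(matrix(c(TRUE, FALSE, FALSE, TRUE),
                                            2)), 4)
  expect_equal(droplet_density(rec, 4), 0.5)
  expect_error(droplet_density(10, 0), "positive")
  expect_error(droplet_density(10, -1), "positive")
})

test_that("PA grouping reproduces the printed interval edges", {
  expect_identical(classify_pa_group(0), "sparse")
  expect_identical(classify_pa_group(12000), "sparse")
  expect_identical(classify_pa_group(12001), "medium")
  expect_identical(classify_pa_group(40000), "medium")
  expect_identical(classify_pa_group(40001), "dense")
  expect_identical(classify_pa_group(89999), "dense")
  expect_warning(g <- classify_pa_group(90000), "outside")
  expect_identical(g, "dense")
  expect_error(classify_pa_group(-1), "non-negative")
})

test_that("analyze_image recovers truth exactly on clean synthetics", {
  g <- generate_wsp(noise_free_spec(seed = 33))
  for (method in c("fixed", "otsu", "genetic_otsu")) {
    rep <- analyze_image(
      g$image, method,
      ga_config = if (method == "genetic_otsu") ga_config(seed = 2))
    expect_equal(rep$droplet_count, g$truth$n_droplets_placed,
                 info = method)
    expect_equal(rep$coverage_pct, g$truth$coverage_pct, info = method)
    expect_equal(rep$total_droplet_area_px, g$truth$total_area_px,
                 info = method)
  }
})

test_that("analyze_image on a blank background reports zeros", {
  g <- generate_wsp(noise_free_spec(seed = 3, n_droplets = 0))
  rep <- analyze_image(g$image, "fixed")
  expect_equal(rep$droplet_count, 0)
  expect_equal(rep$coverage_pct, 0)
  expect_equal(rep$density_per_cm2, 0)
  expect_identical(rep$pa_group, "sparse")
})

test_that("analyze_image is deterministic and validates ga_config use", {
  g <- generate_wsp(synthetic_spec(n_droplets = 10, seed = 44))
  a <- analyze_image(g$image, "genetic_otsu", ga_config = ga_config(seed = 9))
  b <- analyze_image(g$image, "genetic_otsu", ga_config = ga_config(seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(analyze_image(g$image, "genetic_otsu"), "requires")
  expect_error(analyze_image(g$image, "otsu", ga_config = ga_config(seed = 1)),
               "ga_config")
})

test_that("min_droplet_area_px filters small components from all outputs", {
  px <- matrix(210L, 20, 20)
  px[5, 5] <- 0L                    # single-pixel speck
  px[10:13, 10:13] <- 0L            # real droplet
  img <- gray_image(px)
  rep <- analyze_image(img, "fixed", min_droplet_area_px = 2)
  expect_equal(rep$droplet_count, 1)
  expect_equal(rep$total_droplet_area_px, 16L)
  expect_equal(rep$coverage_pct, 100 * 16 / 400)
  rep0 <- analyze_image(img, "fixed", min_droplet_area_px = 0)
  expect_equal(rep0$droplet_count, 2)
})
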