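test_that("load_image extracts the requested channel from RGB rasters", {
  cases <- list(
    list(rgb = c(1, 1, 1), channel = "luma", expect = 255L),
    list(rgb = c(0, 0, 0), channel = "red", expect = 0L),
    list(rgb = c(0, 0, 0), channel = "luma", expect = 0L),
    list(rgb = c(0, 0, 1), channel = "red", expect = 0L),   # pure blue
    list(rgb = c(0, 0, 1), channel = "blue", expect = 255L),
    list(rgb = c(0, 1, 0), channel = "green", expect = 255L)
  )
  for (cs in cases) {
    f <- write_rgb_png(cs$rgb, dpi = 96)
    img <- load_image(f, channel = cs$channel)
    expect_true(all(img$pixels == cs$expect),
                info = paste(cs$channel, paste(cs$rgb, collapse = ",")))
    expect_identical(dim(img), c(2L, 2L))
  }
})

test_that("luma conversion uses BT.601 weights", {
  f <- write_rgb_png(c(1, 0.5, 0.25), dpi = 96)
  img <- load_image(f, channel = "luma")
  # channels quantised to 8 bits on write, weights applied on read
  expected <- round(255 * (0.299 * 1 + 0.587 * (128 / 255) +
                             0.114 * (64 / 255)))
  expect_true(all(img$pixels == expected))
})

test_that("DPI comes from metadata, then override, then 96 with warning", {
  f <- write_rgb_png(c(1, 1, 1), dpi = 96)
  expect_equal(load_image(f)$dpi, 96, tolerance = 1e-3)  # 95.9866 round-trip
  f2 <- write_rgb_png(c(1, 1, 1))                        # no metadata
  expect_silent(img2 <- load_image(f2, dpi_override = 300))
  expect_equal(img2$dpi, 300)
  expect_warning(img3 <- load_image(f2), "assuming 96 DPI")
  expect_equal(img3$dpi, 96)
})

test_that("load_image is deterministic and validates its inputs", {
  f <- write_rgb_png(c(0.3, 0.7, 0.2), nr = 4, nc = 5, dpi = 96)
  a <- load_image(f)
  b <- load_image(f)
  expect_identical(a$pixels, b$pixels)
  expect_error(load_image(file.path(tempdir(), "nope.png")), "not found")
  ft <- tempfile(fileext = ".tiff")
  file.create(ft)
  expect_error(load_image(ft), "TIFF")
})

test_that("plain PNM round-trips grayscale and RGB with comments/maxval", {
  px <- matrix(sample(0:255, 24, replace = TRUE), 4, 6)
  f <- tempfile(fileext = ".pgm")
  write_pnm(px, f)
  expect_identical(read_pnm(f), px)
  img <- load_image(f, dpi_override = 96)
  expect_identical(img$pixels, px)

  # hand-written plain file with a comment and maxval 15
  f2 <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "# a comment", "2 2", "15", "0 15", "15 0"), f2)
  expect_identical(read_pnm(f2), matrix(c(0L, 255L, 255L, 0L), 2,
                                        byrow = TRUE))

  arr <- array(sample(0:255, 2 * 3 * 3, replace = TRUE), c(2, 3, 3))
  f3 <- tempfile(fileext = ".ppm")
  write_pnm(arr, f3)
  expect_identical(read_pnm(f3), array(as.integer(arr), dim(arr)))
  expect_true(all(load_image(f3, channel = "red",
                             dpi_override = 96)$pixels == arr[, , 1]))
})

test_that("gray_image enforces its invariants", {
  expect_error(gray_image(matrix(c(0, 256), 1)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(c(0, 1.5), 1)), "integers")
  expect_error(gray_image(matrix(0L, 0, 0)), "at least one pixel")
  expect_error(gray_image(matrix(0L, 2, 2), dpi = 0), "dpi")
})

test_that("physical_area_cm2 matches hand-computed areas", {
  expect_equal(physical_area_cm2(gray_image(matrix(255L, 96, 96))),
               6.4516)                                   # one square inch
  expect_equal(physical_area_cm2(gray_image(matrix(0L, 98, 287))),
               19.68942, tolerance = 1e-6)               # 76x26mm @96DPI scan
  expect_equal(
    physical_area_cm2(gray_image(matrix(0L, 1, 1), dpi = 25.4)),
    0.01)                                                # 1 mm pixel
})

test_that("physical area scales quadratically with mm per px", {
  img <- gray_image(matrix(0L, 10, 20), dpi = 96)
  a1 <- physical_area_cm2(img, physical_scale(96))
  a2 <- physical_area_cm2(img, physical_scale(48))  # doubles mm_per_px
  expect_equal(a2, 4 * a1)
  expect_equal(physical_scale(96)$mm_per_px * 96, 25.4)
})

test_that("write_mask_png serialises droplet=255, background=0", {
  m <- droplet_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  f <- tempfile(fileext = ".png")
  write_mask_png(m, f)
  back <- png::readPNG(f)
  expect_equal(back, matrix(c(1, 0, 0, 1), 2))
})
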