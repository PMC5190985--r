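test_that("rgb_to_hsb matches the standard RGB-to-HSV closed form", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)   # white
  px[1, 2, ] <- c(0, 0, 0)         # black
  px[1, 3, ] <- c(0, 0, 255)       # pure blue
  hsb <- rgb_to_hsb(canopy_image(px))
  expect_equal(hsb$hue[1, 1], 0)
  expect_equal(hsb$saturation[1, 1], 0)
  expect_equal(hsb$brightness[1, 1], 1)
  expect_equal(hsb$saturation[1, 2], 0)
  expect_equal(hsb$brightness[1, 2], 0)
  expect_equal(hsb$hue[1, 3], 240)
  expect_equal(hsb$saturation[1, 3], 1)
  expect_equal(hsb$brightness[1, 3], 1)
})

test_that("invalid images are rejected", {
  expect_error(canopy_image(matrix(1, 2, 2)), "H x W x 3")
  expect_error(canopy_image(array(300, c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(canopy_image(array(1, c(0, 2, 3))), "at least one pixel")
})

test_that("uniform sky-like and leaf-like frames classify as one class", {
  sky_only <- two_tone_image(matrix(TRUE, 20, 20))
  m <- segment_sky(rgb_to_hsb(sky_only))
  expect_equal(m$n_sky, m$n_total)

  leaf_only <- two_tone_image(matrix(FALSE, 20, 20))
  m <- segment_sky(rgb_to_hsb(leaf_only))
  expect_equal(m$n_sky, 0L)
})

test_that("two-tone images recover the constructed sky proportion exactly", {
  sky <- matrix(FALSE, 50, 40)
  sky[seq_len(2000 * 0.4)] <- TRUE          # exactly 40% sky
  gf <- gap_fraction(segment_sky(rgb_to_hsb(two_tone_image(sky))))
  expect_identical(gf$p0, 0.4)

  # property: exact for arbitrary proportions and pixel placements
  withr::with_seed(11, {
    for (p in c(0.05, 0.33, 0.5, 0.91)) {
      sky <- matrix(runif(30 * 30) < p, 30, 30)
      gf <- gap_fraction(segment_sky(rgb_to_hsb(two_tone_image(sky))))
      expect_identical(gf$p0, mean(sky))
    }
  })
})

test_that("bright saturated green pixels are kept as vegetation", {
  # sunlit leaf: brighter than the sky threshold but green and saturated
  sky <- matrix(TRUE, 10, 10)
  img <- two_tone_image(sky)$pixels
  sunlit <- grDevices::col2rgb(grDevices::hsv(120 / 360, 0.8, 0.98))
  for (ch in 1:3) img[1:5, , ch] <- sunlit[ch]
  m <- segment_sky(rgb_to_hsb(canopy_image(img)),
                   seg_params(brightness_cut = 0.6))
  expect_equal(m$n_sky, 50L)
  expect_true(all(!m$mask[1:5, ]))
})

test_that("gap fraction is a pure pixel count ratio with saturation flag", {
  all_sky <- segment_sky(rgb_to_hsb(two_tone_image(matrix(TRUE, 5, 5))))
  gf <- gap_fraction(all_sky)
  expect_identical(gf$p0, 1)
  expect_false(gf$saturated)

  none <- segment_sky(rgb_to_hsb(two_tone_image(matrix(FALSE, 5, 5))))
  gf <- gap_fraction(none)
  expect_identical(gf$p0, 0)
  expect_true(gf$saturated)

  half <- structure(list(mask = matrix(c(TRUE, FALSE), 100, 100),
                         n_sky = 5000L, n_total = 10000L),
                    class = "segmentation_mask")
  expect_identical(gap_fraction(half)$p0, 0.5)

  empty <- structure(list(mask = matrix(FALSE, 0, 0), n_sky = 0L,
                          n_total = 0L), class = "segmentation_mask")
  expect_error(gap_fraction(empty), "zero pixels")
})

test_that("p0 is permutation-invariant and segmentation idempotent", {
  withr::with_seed(5, {
    sky <- matrix(runif(400) < 0.35, 20, 20)
    perm <- matrix(sample(sky), 20, 20)
  })
  p_a <- gap_fraction(segment_sky(rgb_to_hsb(two_tone_image(sky))))$p0
  p_b <- gap_fraction(segment_sky(rgb_to_hsb(two_tone_image(perm))))$p0
  expect_identical(p_a, p_b)

  img <- render_canopy(0.8, width = 64, height = 64, seed = 9)
  m1 <- segment_sky(rgb_to_hsb(img))
  m2 <- segment_sky(rgb_to_hsb(img))
  expect_identical(m1$mask, m2$mask)
})

test_that("image and mask round trip through PNG", {
  img <- render_canopy(1, width = 32, height = 32, seed = 4)
  f <- withr::local_tempfile(fileext = ".png")
  write_canopy_png(img, f)
  back <- read_canopy_image(f, vine_id = "v1", side = "left")
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$vine_id, "v1")

  m <- segment_sky(rgb_to_hsb(img))
  fm <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, fm)
  expect_equal(png::readPNG(fm) == 1, m$mask)
})
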