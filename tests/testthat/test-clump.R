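test_that("smooth is the exact 3x3 mean with replicated borders", {
  const <- matrix(5, 6, 6)
  expect_equal(ij_smooth(const), const)

  z <- matrix(0, 7, 7); z[4, 4] <- 9
  sm <- ij_smooth(z)
  expect_equal(sm[3:5, 3:5], matrix(1, 3, 3))
  expect_equal(sum(sm), 9)  # interior mass conserved

  set.seed(1)
  img <- matrix(runif(25), 5, 5)
  # brute-force mean of clamped neighborhood
  for (pt in list(c(1, 1), c(3, 4), c(5, 5))) {
    i <- pt[1]; j <- pt[2]
    vals <- c()
    for (di in -1:1) for (dj in -1:1)
      vals <- c(vals, img[min(max(i + di, 1), 5), min(max(j + dj, 1), 5)])
    expect_equal(ij_smooth(img)[i, j], mean(vals))
  }
})

test_that("find edges is the Sobel magnitude with the expected step response", {
  expect_equal(ij_find_edges(matrix(3, 5, 5)), matrix(0, 5, 5))

  h <- 7
  step <- cbind(matrix(0, 6, 4), matrix(h, 6, 4))  # vertical step edge
  e <- ij_find_edges(step)
  expect_equal(e[3, 4], 4 * h)  # interior response along the step
  expect_equal(e[3, 5], 4 * h)
  expect_equal(e[3, 2], 0)

  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  rot <- t(img)[ncol(img):1, ]  # 90 degree rotation
  e1 <- ij_find_edges(img)
  e2 <- ij_find_edges(rot)
  expect_equal(e2, t(e1)[ncol(e1):1, ], tolerance = 1e-12)
})

test_that("despeckle equals the brute-force 3x3 median", {
  z <- matrix(1, 6, 6); z[3, 3] <- 50  # isolated speckle removed
  expect_equal(ij_despeckle(z), matrix(1, 6, 6))
  expect_equal(ij_despeckle(matrix(2, 5, 5)), matrix(2, 5, 5))

  set.seed(3)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    expect_equal(ij_despeckle(img), brute_median3(img))
  }
})

test_that("IsoData threshold separates a balanced bimodal image", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- isodata_threshold(img)
  expect_equal(t, 105)  # fixed point: (10 + 200) / 2
  mask <- ij_make_binary(img)
  expect_equal(sum(mask), 50)
  expect_true(all(img[mask] == 200))

  expect_warning(m0 <- ij_make_binary(matrix(4, 5, 5)), "constant")
  expect_false(any(m0))

  # inverted contrast selects the complementary class
  inv <- ij_make_binary(255 - img)
  expect_equal(sum(inv & mask), 0)
  expect_equal(sum(inv | mask), 100)
})

test_that("morphology obeys monotonicity, closing and hole-filling contracts", {
  m <- matrix(FALSE, 11, 11); m[4:8, 4:8] <- TRUE  # isolated 5x5 square
  expect_equal(ij_erode(ij_dilate(m)), m)  # closing restores a convex square
  expect_gte(sum(ij_dilate(m)), sum(m))
  expect_lte(sum(ij_erode(m)), sum(m))

  ring <- matrix(FALSE, 9, 9); ring[3:7, 3:7] <- TRUE; ring[5, 5] <- FALSE
  expect_true(all(ij_fill_holes(ring)[3:7, 3:7]))

  set.seed(4)
  rnd <- matrix(runif(400) < 0.4, 20, 20)
  expect_true(all(ij_dilate(rnd) | !rnd))
  expect_true(all(rnd | !ij_erode(rnd)))
})

test_that("particle analysis uses 8-connectivity and the strict 20 um^2 cutoff", {
  # two squares touching only at a corner: one particle
  m <- matrix(FALSE, 20, 20)
  m[2:8, 2:8] <- TRUE; m[9:15, 9:15] <- TRUE
  rec <- analyze_particles(m, pixel_size_um = 1, min_area_um2 = 20)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_pixels, 2 * 49)

  # 100 px at 0.5 um/px -> 25 um^2 kept; 80 px -> exactly 20 um^2 dropped
  m2 <- matrix(FALSE, 30, 30)
  m2[1:10, 1:10] <- TRUE          # 100 px
  m2[20:27, 15:24] <- TRUE        # 80 px
  rec2 <- analyze_particles(m2, pixel_size_um = 0.5)
  expect_equal(rec2$area_um2, 25)
  expect_equal(nrow(rec2), 1L)

  expect_equal(nrow(analyze_particles(matrix(FALSE, 5, 5), 1)), 0L)

  # area conservation: pixel counts sum to the mask's foreground count
  set.seed(5)
  blob <- matrix(runif(900) < 0.3, 30, 30)
  all_rec <- analyze_particles(blob, pixel_size_um = 1, min_area_um2 = 0)
  expect_equal(sum(all_rec$n_pixels), sum(blob))
})

test_that("cell equivalents scale linearly with area", {
  expect_equal(cell_equivalents(28, 28), 1)
  expect_equal(cell_equivalents(750, 10), 75)
  expect_equal(cell_equivalents(2 * 77, 11), 2 * cell_equivalents(77, 11))
  expect_error(cell_equivalents(10, 0), "> 0")
})

test_that("the full chain recovers synthetic ground truth", {
  spec <- synthetic_image_spec(clump_composition = c(2L, 6L, 12L),
                               noise_sd = 0, bacteria_density = 0,
                               image_shape = c(900L, 900L), seed = 11)
  gen <- generate_dic_image(spec)
  ref_area <- pi * spec$cell_radius_um^2
  rec <- quantify_image(gen$image, spec$pixel_size_um, ref_area)
  expect_equal(nrow(rec), 3L)
  expect_equal(sort(rec$area_um2), sort(gen$ground_truth$area_um2),
               tolerance = 0.1)
  expect_true(all(rec$area_um2 > 20))

  # adding bacteria and noise does not change the particle count
  spec2 <- synthetic_image_spec(clump_composition = c(2L, 6L, 12L),
                                image_shape = c(900L, 900L), seed = 11)
  rec2 <- quantify_image(generate_dic_image(spec2)$image,
                         spec2$pixel_size_um, ref_area)
  expect_equal(nrow(rec2), 3L)

  # a field with nothing but bacteria yields no records
  spec3 <- synthetic_image_spec(clump_composition = integer(),
                                image_shape = c(300L, 300L),
                                bacteria_density = 5e-4, seed = 12)
  gen3 <- generate_dic_image(spec3)
  expect_equal(nrow(gen3$ground_truth), 0L)
  expect_equal(nrow(quantify_image(gen3$image, spec3$pixel_size_um,
                                   ref_area)), 0L)
})

test_that("image generator ground truth is consistent", {
  spec <- synthetic_image_spec(clump_composition = c(1L, 5L, 20L),
                               noise_sd = 0, bacteria_density = 0, seed = 2)
  gen <- generate_dic_image(spec)
  gt <- gen$ground_truth
  # single disk area ~ pi r^2 within rasterization error
  expect_equal(gt$area_um2[gt$n_cells == 1], pi * spec$cell_radius_um^2,
               tolerance = 0.02)
  # areas monotone in cell count
  expect_true(all(diff(gt$area_um2[order(gt$n_cells)]) > 0))
  # ground truth area equals total foreground drawn
  expect_equal(sum(gt$n_pixels), sum(gen$image == 0.9))
  # determinism
  expect_identical(generate_dic_image(spec)$image, gen$image)
  # impossible placement errors out
  tiny <- synthetic_image_spec(image_shape = c(60L, 60L),
                               clump_composition = c(20L, 20L), seed = 1)
  expect_error(generate_dic_image(tiny), "too small")
})

test_that("two-sample KS matches the ECDF oracle and separates distinct populations", {
  same <- ks_two_sample(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(1:3, 4:6)$statistic, 1)

  set.seed(6)
  for (rep in 1:10) {
    x <- rnorm(30); y <- rnorm(40, 0.5)
    expect_equal(ks_two_sample(x, y)$statistic, brute_ks_D(x, y))
  }
  expect_error(ks_two_sample(numeric(), 1:3), "nonempty")
})

test_that("clump summaries give median, IQR and non-outlier range", {
  s <- summarize_clumps(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(c(s$q1, s$q3), c(2, 4))
  expect_equal(c(s$range_lo, s$range_hi), c(1, 5))

  one <- summarize_clumps(7)
  expect_equal(unlist(one[c("median", "q1", "q3", "range_lo", "range_hi")]),
               c(median = 7, q1 = 7, q3 = 7, range_lo = 7, range_hi = 7))

  with_outlier <- summarize_clumps(c(1, 2, 3, 4, 5, 500))
  expect_equal(with_outlier$median, 3.5)
  expect_equal(with_outlier$range_hi, 5)  # outlier excluded from the range
  expect_error(summarize_clumps(numeric()), "no clump")
})
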