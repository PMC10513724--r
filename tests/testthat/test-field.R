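test_that("uniformity profile is flat for constant images and scale invariant", {
  img <- fgs_image(matrix(20000, 256, 256), 16)
  u <- uniformity_profile(img)
  expect_equal(u$profile, rep(1, 256))
  expect_equal(u$summary$min_profile, 1)
  expect_equal(u$summary$frac_ge_090, 1)
  expect_equal(u$summary$center_to_edge_ratio, 1)
  expect_equal(range(u$x_norm), c(0, 1))

  vig <- render_uniform_field(camera = noiseless_camera(
    blur_sigma0 = 0, vignette_strength = 0.3), seed = 1)$image
  u1 <- uniformity_profile(vig)
  u2 <- uniformity_profile(fgs_image(vig$pixels / 8, 16))
  expect_equal(u1$profile, u2$profile, tolerance = 1e-4)

  expect_error(uniformity_profile(img, band_half_width_px = 200), "band")
})

test_that("band profile matches the analytic vignette cross-section", {
  v <- 0.35
  r <- render_uniform_field(size_px = c(401, 401), level_dn = 40000,
                            camera = noiseless_camera(blur_sigma0 = 0,
                                                      vignette_strength = v),
                            seed = 1)
  u <- uniformity_profile(r$image)
  d <- dim(r$image$pixels)
  cr <- (d[1] - 1) / 2; cc <- (d[2] - 1) / 2
  rmax2 <- ((d[1] - 1) / 2)^2 + ((d[2] - 1) / 2)^2
  band_m2 <- mean(((u$band_rows - 1) - cr)^2)
  analytic <- function(col0) { # mean V over the band at one column
    (1 - v * (((col0 - cc)^2 + band_m2) / rmax2))
  }
  expect_equal(u$profile[1] / u$profile[201],
               analytic(0) / analytic(200), tolerance = 1e-3)
})

test_that("vignette strength is recovered from the profile minimum", {
  for (v in c(0.1, 0.2, 0.35)) {
    r <- render_uniform_field(camera = noiseless_camera(
      blur_sigma0 = 0, vignette_strength = v), seed = 1)
    est <- estimate_vignette(uniformity_profile(r$image))
    expect_lt(abs(est - v), 0.02)
  }
  errs <- vapply(1:10, function(s) {
    r <- render_uniform_field(camera = camera_model(vignette_strength = 0.35),
                              seed = s)
    abs(estimate_vignette(uniformity_profile(r$image)) - 0.35)
  }, 0)
  expect_true(all(errs < 0.05))
})

test_that("masked regions are zeroed and excluded from the band statistics", {
  px <- matrix(rep(seq(100, 355), 300), 256, 300)
  img <- fgs_image(px, 16)
  expect_identical(masked_region_zeroing(img, list())$pixels, px)

  u0 <- uniformity_profile(img, band_half_width_px = 20)
  # mask the top half of the band in 10 columns; remaining rows decide
  band_top <- roi_rect("logo", row0 = 107, col0 = 40, height = 21,
                       width = 10)
  m <- masked_region_zeroing(img, list(band_top))
  expect_true(all(m$pixels[108:128, 41:50] == 0))
  um <- uniformity_profile(m, band_half_width_px = 20)
  # masked columns average the surviving rows 129..148 only
  expected <- colMeans(px[108:148, ])
  expected[41:50] <- colMeans(px[129:148, 41:50])
  expect_equal(um$profile, unname(expected / max(expected)),
               tolerance = 1e-9)

  # a fully masked column is interpolated from its neighbors
  full_col <- roi_rect("logo2", row0 = 0, col0 = 150, height = 256,
                       width = 1)
  uf <- uniformity_profile(masked_region_zeroing(img, list(full_col)),
                           band_half_width_px = 20)
  expect_identical(uf$interpolated_cols, 151L)
  expect_equal(uf$profile[151], mean(uf$profile[c(150, 152)]),
               tolerance = 1e-9)
})

test_that("dot spacings are exactly uniform without distortion", {
  g <- render_dot_grid(camera = noiseless_camera(blur_sigma0 = 0.5,
                                                 defocus_slope = 0,
                                                 vignette_strength = 0),
                       seed = 1)
  dd <- dot_distances(g$image)
  expect_length(dd$peak_positions_px, 9)
  expect_equal(dd$spacings_norm, rep(1, 8), tolerance = 1e-9)
  expect_equal(dd$distortion_index, 0, tolerance = 1e-9)
  expect_identical(dd$side_flags, "none")
  expect_equal(dd$spacings_px, rep(40, 8), tolerance = 1e-3)
})

test_that("barrel distortion compresses edge spacings as the Brown oracle says", {
  cam <- noiseless_camera(blur_sigma0 = 0.5, defocus_slope = 0,
                          vignette_strength = 0, k1 = -0.08)
  g <- render_dot_grid(camera = cam, seed = 1)
  dd <- dot_distances(g$image)
  mid <- ceiling(length(dd$spacings_norm) / 2)
  expect_lt(dd$spacings_norm[1], dd$spacings_norm[mid])
  expect_lt(dd$spacings_norm[length(dd$spacings_norm)],
            dd$spacings_norm[mid])
  expect_gt(dd$distortion_index, 0)

  # detected positions against the generator's distorted centers
  und <- g$truth$scene$centers_undistorted
  dis <- g$truth$scene$centers_distorted
  rows_sorted <- sort(unique(round(und[, 1], 9)))
  sel <- abs(und[, 1] - rows_sorted[3]) < 1e-9
  oracle_cols <- sort(dis[sel, 2])
  expect_length(dd$peak_positions_px, length(oracle_cols))
  expect_lt(max(abs(dd$peak_positions_px - oracle_cols)), 0.5)
  expect_equal(dd$spacings_px, diff(oracle_cols), tolerance = 0.5)
})

test_that("dot detection needs at least four prominent peaks", {
  px <- matrix(0, 64, 120)
  for (cc in c(30, 60, 90)) { # only three dots on the mid row
    d2 <- outer((1:64 - 32)^2, (1:120 - cc)^2, `+`)
    px <- px + 50000 * exp(-d2 / 8)
  }
  img <- fgs_image(pmin(px, 65535), 16)
  expect_error(dot_distances(img, row_bands = list(c(24, 16))),
               "insufficient dots")
})
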