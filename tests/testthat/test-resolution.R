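test_that("usaf element arithmetic matches the sixth-octave law", {
  cases <- list(
    list(g = 0, e = 1, lp = 1.0, width = 500),
    list(g = 1, e = 1, lp = 2.0, width = 250),
    list(g = 2, e = 5, lp = 2^(2 + 4 / 6), width = 1000 / (2^(3 + 4 / 6))),
    list(g = -1, e = 4, lp = 2^(-0.5), width = 1000 / (2 * 2^(-0.5))))
  for (cs in cases) {
    el <- usaf_element(cs$g, cs$e)
    expect_equal(el$lp_per_mm, cs$lp)
    expect_equal(el$line_width_um, cs$width)
    expect_equal(el$line_width_um, 1000 / (2 * el$lp_per_mm))
  }
  expect_error(usaf_element(3, 0), "1..6")
  expect_error(usaf_element(3, 7), "1..6")
  expect_error(usaf_element(2.5, 1), "integer")
})

test_that("compute_ctf reproduces hand-evaluated contrast values", {
  # balanced two-level region: full contrast
  px <- matrix(0, 20, 20); px[, 11:20] <- 1000
  img <- fgs_image(px, bit_depth = 16)
  full <- compute_ctf(img, roi_rect("r", 0, 0, 20, 20))
  expect_equal(full$ctf_percent, 100)
  expect_equal(full$max_r, 1000)
  expect_equal(full$min_r, 0)

  # constant region: zero contrast
  expect_equal(compute_ctf(fgs_image(matrix(500, 16, 16), 16),
                           roi_rect("r", 0, 0, 16, 16))$ctf_percent, 0)

  # hand case: top-20% mean 75, bottom-20% mean 25 -> 50%
  vals <- c(25, 25, 40, 50, 50, 55, 60, 65, 75, 75)
  img2 <- fgs_image(matrix(rep(vals, each = 16), 16, 40), 16)
  res <- compute_ctf(img2, roi_rect("r", 0, 0, 16, 40))
  expect_equal(res$max_r, 75)
  expect_equal(res$min_r, 25)
  expect_equal(res$ctf_percent, 50)

  expect_error(compute_ctf(img, roi_rect("r", 0, 0, 4, 4),
                           background_threshold = 0.05), "0.1")
  dark <- compute_ctf(fgs_image(matrix(0, 16, 16), 16),
                      roi_rect("r", 0, 0, 16, 16))
  expect_true(dark$degenerate)
  expect_true(is.na(dark$ctf_percent))
})

test_that("compute_ctf equals brute-force evaluation and is scale invariant", {
  r <- render_usaf(list(c(0, 1), c(1, 1)), px_per_mm = 16,
                   camera = noiseless_camera(blur_sigma0 = 1,
                                             defocus_slope = 0,
                                             vignette_strength = 0.1),
                   seed = 1)
  for (roi in r$layout$rois) {
    mine <- compute_ctf(r$image, roi)$ctf_percent
    oracle <- brute_force_ctf(roi_values(r$image, roi))
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
  # Eq-(1) algebra: scaling the intensities leaves the ratio unchanged
  roi <- r$layout$rois[[1]]
  scaled <- fgs_image(r$image$pixels / 4, bit_depth = 16)
  expect_equal(compute_ctf(scaled, roi)$ctf_percent,
               compute_ctf(r$image, roi)$ctf_percent, tolerance = 1e-12)
  expect_true(all(vapply(r$layout$rois, function(rr)
    compute_ctf(r$image, rr)$ctf_percent, 0) >= 0))
})

test_that("ctf is non-increasing in blur for a fixed element", {
  ctfs <- vapply(c(0.5, 1, 2, 3), function(sg) {
    r <- render_usaf(list(c(0, 1)), px_per_mm = 16,
                     camera = noiseless_camera(blur_sigma0 = sg,
                                               defocus_slope = 0,
                                               vignette_strength = 0),
                     seed = 1)
    ctf_element(r$image, r$layout$rois$g0e1_h,
                r$layout$rois$g0e1_v)$ctf_percent
  }, 0)
  expect_true(all(diff(ctfs) < 0))
})

test_that("sharpness curves rank elements and report the resolving limit", {
  ideal <- render_usaf(usaf_nine_element_set(), px_per_mm = 20,
                       camera = exact_camera(), seed = 1)
  s <- sharpness_curve(ideal$image, ideal$layout)
  expect_equal(nrow(s$table), 9)
  expect_equal(s$table$ctf_mean, rep(100, 9))
  expect_equal(s$resolving_limit_lp_per_mm, 2^(2 + 4 / 6))

  blurred <- render_usaf(usaf_nine_element_set(), px_per_mm = 20,
                         camera = noiseless_camera(blur_sigma0 = 1.25,
                                                   defocus_slope = 0,
                                                   vignette_strength = 0),
                         seed = 1)
  sb <- sharpness_curve(blurred$image, blurred$layout)
  # contrast falls with spatial frequency over the well-sampled elements
  # (bars >= 2 px); the sub-2 px finest element is excluded
  expect_true(all(diff(sb$table$ctf_mean[1:8]) < 0))
  expect_lt(sb$resolving_limit_lp_per_mm, 2^(2 + 4 / 6))

  heavy <- render_usaf(usaf_nine_element_set(), px_per_mm = 20,
                       camera = noiseless_camera(blur_sigma0 = 6,
                                                 defocus_slope = 0,
                                                 vignette_strength = 0),
                       seed = 1)
  sh <- sharpness_curve(heavy$image, heavy$layout)
  # nothing reaches the 40% criterion: limit reported below the scale
  expect_true(is.na(sh$resolving_limit_lp_per_mm))

  expect_error(sharpness_curve(ideal$image, ideal$layout,
                               expected_lp_per_mm = c(1, 8)),
               "missing")
})

test_that("dof curves peak at focus and recover the in-focus interval", {
  cam <- noiseless_camera(blur_sigma0 = 0.8, defocus_slope = 0.6,
                          vignette_strength = 0)
  zs <- -7:7
  lay <- render_usaf(list(c(0, 1)), 20, cam, z_cm = 0, seed = 1,
                     margin_px = 40)$layout
  stack <- lapply(zs, function(z) {
    list(z_cm = z,
         image = render_usaf(list(c(0, 1)), 20, cam, z_cm = z, seed = 1,
                             margin_px = 40)$image)
  })
  dc <- dof_curve(stack, lay$rois$g0e1_h, lay$rois$g0e1_v)
  v <- dc$table$ctf_percent
  expect_equal(which.max(v), which(dc$table$z_cm == 0))
  expect_true(all(diff(v[dc$table$z_cm >= 0]) <= 1e-9))
  expect_true(all(diff(rev(v[dc$table$z_cm <= 0])) <= 1e-9))
  # symmetric sigma(z): the interval is symmetric within one z step
  expect_lte(abs(dc$in_focus_range_cm[1] + dc$in_focus_range_cm[2]), 1)

  # blur-free stack: contrast is flat and the range spans the stack
  flat_stack <- lapply(c(-2, 0, 3), function(z) {
    list(z_cm = z,
         image = render_usaf(list(c(0, 1)), 20, exact_camera(), z_cm = z,
                             seed = 1, margin_px = 40)$image)
  })
  df <- dof_curve(flat_stack, lay$rois$g0e1_h, lay$rois$g0e1_v)
  expect_equal(df$table$ctf_percent, rep(100, 3))
  expect_equal(df$in_focus_range_cm, c(-2, 3))

  # asymmetric acquisition (-6 .. +7): the range respects the sampled span
  asym <- stack[zs >= -6]
  da <- dof_curve(asym, lay$rois$g0e1_h, lay$rois$g0e1_v)
  expect_gte(da$in_focus_range_cm[1], -6)
  expect_lte(da$in_focus_range_cm[2], 7)

  # nothing reaches threshold: empty range is signalled, not an error
  hv <- noiseless_camera(blur_sigma0 = 6, defocus_slope = 0,
                         vignette_strength = 0)
  hv_lay <- render_usaf(list(c(0, 1)), 20, hv, z_cm = 0, seed = 1,
                        margin_px = 40)$layout
  hv_stack <- lapply(c(-1, 0, 1), function(z) {
    list(z_cm = z,
         image = render_usaf(list(c(0, 1)), 20, hv, z_cm = z, seed = 1,
                             margin_px = 40)$image)
  })
  dh <- dof_curve(hv_stack, hv_lay$rois$g0e1_h, hv_lay$rois$g0e1_v)
  expect_null(dh$in_focus_range_cm)

  expect_error(dof_curve(stack[zs != 0], lay$rois$g0e1_h,
                         lay$rois$g0e1_v), "z = 0")
})
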