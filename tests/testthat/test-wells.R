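# build a panel object directly, bypassing image quantification, to probe
# the detection rules on exactly specified statistics
manual_panel <- function(labels, means, sds, roles = NULL, bit_depth = 16L) {
  n <- length(labels)
  if (is.null(roles)) roles <- c(rep("sample", n - 1L), "control")
  wells <- data.frame(name = paste0("well_", labels),
                      label = as.character(labels), role = roles,
                      mean = means, sd = sds)
  base <- max(wells$mean[wells$role != "qd800"], 1)
  wells$mean_norm <- wells$mean / base
  wells$sd_norm <- wells$sd / base
  ctrl <- wells[wells$role == "control", ]
  structure(list(wells = wells,
                 noise_floor = list(mean = ctrl$mean, sd = ctrl$sd),
                 edge_margin_px = 0, bit_depth = as.integer(bit_depth),
                 lod_label = NULL, saturated_labels = NULL,
                 max_reliable_depth_mm = NULL),
            class = "fgs_well_panel")
}

test_that("panel quantification normalizes to the ICG maximum", {
  wc <- render_wells("conc", camera = exact_camera(), seed = 1,
                     qd800_leak_dn = 64000)
  pan <- quantify_wells(wc$image, wc$layout)
  samples <- pan$wells$role == "sample"
  expect_equal(max(pan$wells$mean_norm[samples]), 1)
  expect_true(all(pan$wells$mean_norm >= 0))
  # the visible-leak QD800 well does not set the normalization base
  expect_equal(pan$wells$mean_norm[pan$wells$role == "qd800"],
               64640 / 65535, tolerance = 1e-3)
  expect_equal(pan$noise_floor$mean, 640)

  # a panel with all wells at the control level has no detectable signal
  flat <- manual_panel(c(100, 10, 1, 0), rep(50, 4), rep(0, 4))
  flat <- detect_floor_and_saturation(flat)
  expect_true(is.na(flat$lod_label))
})

test_that("well layouts must be disjoint and carry one control", {
  lay <- render_wells("conc", camera = exact_camera(), seed = 1)$layout
  img <- render_wells("conc", camera = exact_camera(), seed = 1)$image
  bad <- lay
  bad$rois[[2]]$geom[["center_row"]] <- bad$rois[[1]]$geom[["center_row"]]
  bad$rois[[2]]$geom[["center_col"]] <-
    bad$rois[[1]]$geom[["center_col"]] + 10
  expect_error(quantify_wells(img, bad), "overlap")
  noctrl <- lay
  noctrl$rois <- Filter(function(r) r$role != "control", noctrl$rois)
  expect_error(quantify_wells(img, noctrl), "control")
})

test_that("the k-sigma rule reproduces the hand-worked LoD example", {
  # control (mean 0, sd 2); 1 nM at 1; 3 nM at 10 -> threshold 6, LoD 3 nM
  pan <- manual_panel(c(3, 1, 0), c(10, 1, 0), c(1, 1, 2))
  pan <- detect_floor_and_saturation(pan, k_sigma = 3)
  expect_identical(pan$lod_label, "3")
  expect_equal(pan$criteria$detection_threshold, 6)
  # a stricter criterion pushes the LoD out of reach
  strict <- detect_floor_and_saturation(manual_panel(c(3, 1, 0),
                                                     c(10, 1, 0),
                                                     c(1, 1, 4)),
                                        k_sigma = 3)
  expect_true(is.na(strict$lod_label))
})

test_that("saturation flags pegged wells and top-connected plateaus only", {
  # two wells at the 16-bit ceiling
  pan <- manual_panel(c(1000, 300, 100, 0),
                      c(65535, 65535, 20000, 10), c(0, 0, 50, 2))
  pan <- detect_floor_and_saturation(pan)
  expect_setequal(pan$saturated_labels, c("1000", "300"))

  # strictly increasing, far from full scale: nothing saturates, even
  # though the 1 and 3 nM means differ by far less than 1% of full scale
  low <- manual_panel(c(1000, 300, 3, 1, 0),
                      c(30000, 9000, 120, 90, 10), rep(5, 5))
  low <- detect_floor_and_saturation(low)
  expect_length(low$saturated_labels, 0)

  # plateau hanging off a pegged top well is included
  pl <- manual_panel(c(1000, 300, 100, 0),
                     c(65500, 65100, 30000, 10), rep(5, 4))
  pl <- detect_floor_and_saturation(pl)
  expect_setequal(pl$saturated_labels, c("1000", "300"))
})

test_that("depth panels recover the attenuation length and the boundary", {
  wd <- render_wells("depth", camera = noiseless_camera(
    blur_sigma0 = 0.8, defocus_slope = 0, vignette_strength = 0), seed = 1)
  pan <- depth_response(quantify_wells(wd$image, wd$layout))
  expect_equal(pan$attenuation_fit$d_att_mm, 1.1, tolerance = 0.05)
  expect_equal(pan$attenuation_fit$i0_dn, 24000, tolerance = 0.1)

  # under the generator's default noise the designed boundary is 4 mm
  wn <- render_wells("depth", seed = 2)
  pn <- depth_response(quantify_wells(wn$image, wn$layout))
  expect_equal(pn$max_reliable_depth_mm, 4)

  # all wells below criterion: boundary undefined, fit skipped
  none <- manual_panel(c(1, 2, 3, "control"), c(10, 10, 10, 10),
                       c(1, 1, 1, 1))
  none <- depth_response(none)
  expect_true(is.na(none$max_reliable_depth_mm))
  expect_null(none$attenuation_fit)
  expect_match(none$fit_skipped_reason, "need >= 3")
})

test_that("sbr reproduces exact dB values on constructed regions", {
  b <- 30
  px <- matrix(b, 128, 128)
  ctr <- c(63.5, 63.5)
  d2 <- outer((0:127 - ctr[1])^2, (0:127 - ctr[2])^2, `+`)
  well <- roi_circle("w", ctr[1], ctr[2], 20)

  # identical signal and background: 0 dB
  res0 <- compute_sbr(fgs_image(px, 16), list(well))
  expect_equal(res0$panel_sbr_db, 0, tolerance = 1e-12)

  # 10x amplitude ratio: 10 * log10(100) = 20 dB
  px10 <- px
  px10[d2 <= 20^2] <- 10 * b
  img10 <- fgs_image(px10, 16)
  res10 <- compute_sbr(img10, list(well))
  expect_equal(res10$panel_sbr_db, 20, tolerance = 1e-12)

  # invariance to global intensity scaling
  scaled <- fgs_image(px10 * 3.7, 16)
  expect_equal(compute_sbr(scaled, list(well))$panel_sbr_db,
               res10$panel_sbr_db, tolerance = 1e-9)

  # raising only the background strictly lowers the ratio
  prev <- Inf
  for (extra in c(0, 40, 120)) {
    pxc <- px10
    pxc[d2 > 20^2] <- b + extra
    cur <- compute_sbr(fgs_image(pxc, 16), list(well))$panel_sbr_db
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("sbr annuli must clear neighboring wells", {
  wd <- render_wells("depth", camera = exact_camera(), seed = 1)
  rois <- wd$layout$rois
  wells_234 <- unname(rois[vapply(rois, function(r)
    r$label %in% c("2", "3", "4"), TRUE)])
  res <- compute_sbr(wd$image, wells_234, avoid = unname(rois))
  expect_equal(nrow(res$table), 3)
  expect_true(all(res$table$sbr_db > 0))
  expect_error(compute_sbr(wd$image, wells_234, annulus_factor = 4,
                           avoid = unname(rois)), "annulus|outside")
})
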