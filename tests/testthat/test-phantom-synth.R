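test_that("every render is a pure function of parameters and seed", {
  a <- render_dot_grid(seed = 5)
  b <- render_dot_grid(seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(render_dot_grid(seed = 6)$image$pixels,
                         a$image$pixels))
  u1 <- render_uniform_field(seed = 9)
  u2 <- render_uniform_field(seed = 9)
  expect_identical(u1$image$pixels, u2$image$pixels)
  w1 <- render_wells("conc", seed = 3)
  w2 <- render_wells("conc", seed = 3)
  expect_identical(w1$image$pixels, w2$image$pixels)
  # rendering must not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(render_wells("depth", seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("usaf bars have the exact period of the element frequency", {
  r <- render_usaf(list(c(0, 1)), px_per_mm = 10, camera = exact_camera(),
                   seed = 1)
  vals <- sort(unique(as.vector(r$image$pixels)))
  expect_length(vals, 2) # only background and bar levels survive
  expect_identical(vals[1], 0)
  # 1.0 lp/mm at 10 px/mm: period 10 px, 5 on / 5 off along the
  # horizontal-bar block's column
  roi <- r$layout$rois$g0e1_h
  col <- r$image$pixels[, roi$geom[["col0"]] + 3]
  runs <- rle(col > 0)
  bars <- runs$lengths[runs$values]
  expect_identical(bars, rep(5L, 3L))
  gaps <- runs$lengths[!runs$values][c(-1, -length(runs$lengths[!runs$values]))]
  expect_true(all(gaps == 5L))
  expect_error(
    render_usaf(list(c(5, 1)), px_per_mm = 10, camera = exact_camera()),
    "group 5 element 1")
})

test_that("uniform field follows the radial-quadratic vignette model", {
  flat <- render_uniform_field(camera = exact_camera(), seed = 1)
  expect_equal(stats::sd(as.vector(flat$image$pixels)), 0)
  v <- 0.35
  r <- render_uniform_field(size_px = c(301, 301), level_dn = 40000,
                            camera = noiseless_camera(
                              blur_sigma0 = 0, vignette_strength = v),
                            seed = 1)
  px <- r$image$pixels
  center <- px[151, 151]
  corner <- px[1, 1] # the corner sits at r = r_max, where V = 1 - v
  expect_equal(corner / center, 1 - v, tolerance = 1e-3)
})

test_that("dot grids are equidistant undistorted and follow the Brown model", {
  g0 <- render_dot_grid(camera = exact_camera(), seed = 1)
  cen <- g0$truth$scene$centers_distorted
  expect_equal(cen, g0$truth$scene$centers_undistorted)
  # nearest-neighbor spacing on the rendered lattice
  dists <- as.matrix(stats::dist(cen))
  diag(dists) <- Inf
  expect_equal(unname(apply(dists, 1, min)), rep(40, nrow(cen)))

  gb <- render_dot_grid(camera = exact_camera(k1 = -0.1), seed = 1)
  und <- gb$truth$scene$centers_undistorted
  dis <- gb$truth$scene$centers_distorted
  mid_row <- sort(unique(round(und[, 1], 9)))[3]
  sel <- abs(und[, 1] - mid_row) < 1e-9
  sp <- diff(sort(dis[sel, 2]))
  expect_lt(sp[1], sp[ceiling(length(sp) / 2)]) # barrel: edges compressed
  expect_lt(sp[length(sp)], sp[ceiling(length(sp) / 2)])
  # independent application of the displacement model to the lattice
  h <- 240; w <- 400 # image dims for the default 5 x 9 / spacing-40 grid
  expect_identical(dim(gb$image$pixels), c(240L, 400L))
  ctr <- c((h - 1) / 2, (w - 1) / 2)
  rn <- sqrt(sum(ctr^2))
  d <- sweep(und, 2, ctr)
  ru <- sqrt(rowSums(d^2)) / rn
  oracle <- sweep(d * (1 - 0.1 * ru^2), 2, ctr, `+`)
  expect_equal(dis, oracle, tolerance = 1e-12)

  expect_error(render_dot_grid(camera = exact_camera(k1 = 0.9)), "frame")
  expect_identical(render_dot_grid(camera = exact_camera(k1 = -0.05),
                                   seed = 1)$image$pixels,
                   render_dot_grid(camera = exact_camera(k1 = -0.05),
                                   seed = 2)$image$pixels)
})

test_that("well plates follow the stated latent model and clip at full scale", {
  cam <- exact_camera()
  wc <- render_wells("conc", camera = cam, seed = 1)
  pan <- quantify_wells(wc$image, wc$layout)
  w <- pan$wells
  expected <- pmin(640 + 256 * c(1000, 300, 100, 30, 10, 3, 1), 65535)
  expect_equal(w$mean[match(as.character(c(1000, 300, 100, 30, 10, 3, 1)),
                            w$label)], expected)
  expect_equal(w$mean[w$role == "control"], 640)
  # the pegged wells sit exactly at 2^16 - 1
  expect_equal(max(wc$image$pixels), 65535)
  expect_setequal(wc$truth$scene$clipped_labels, c("1000", "300"))

  wd <- render_wells("depth", camera = cam, seed = 1)
  pd <- quantify_wells(wd$image, wd$layout)
  dep <- as.numeric(pd$wells$label[pd$wells$role == "sample"])
  means <- pd$wells$mean[pd$wells$role == "sample"]
  o <- order(dep)
  expect_true(all(diff(means[o]) < 0)) # strictly decreasing with depth
  expect_equal(means[o], 640 + 24000 * exp(-dep[o] / 1.1), tolerance = 1e-3)

  # wells with equal concentration render with equal means
  we <- render_wells("conc", camera = cam, seed = 1,
                     concentrations_nm = c(100, 100, 100, 30, 10, 3, 1))
  qe <- quantify_wells(we$image, we$layout)
  m100 <- qe$wells$mean[qe$wells$label == "100"]
  expect_equal(max(m100) - min(m100), 0)
})

test_that("spectrum fixtures record the closed-form FWHM and degeneracy", {
  s <- render_spectrum(sigma_nm = 1.2, noise_sd = 0)
  expect_equal(s$truth$scene$true_fwhm_nm, 2 * sqrt(2 * log(2)) * 1.2)
  expect_false(s$truth$scene$degenerate)
  expect_true(render_spectrum(amplitude = 0)$truth$scene$degenerate)
  expect_error(render_spectrum(sigma_nm = 1, n_samples = 10), "coarse")
  s1 <- render_spectrum(noise_sd = 5, seed = 4)
  s2 <- render_spectrum(noise_sd = 5, seed = 4)
  expect_identical(s1$trace$intensity, s2$trace$intensity)
})

test_that("ground-truth sidecars re-render the fixture bit-identically", {
  dir <- withr::local_tempdir()
  for (kind in c("conc", "dots", "usaf")) {
    fx <- synth_fixture(kind, dir, seed = 7)
    truth <- load_truth(fx$truth)
    again <- re_render(truth)
    disk <- load_image(fx$image, bit_depth = 16)
    expect_identical(again$image$pixels, disk$pixels)
  }
  sp <- synth_fixture("spectrum", dir, seed = 3, noise_sd = 5)
  again <- re_render(load_truth(sp$truth))
  disk <- load_spectrum(sp$trace)
  expect_equal(again$trace$intensity, disk$intensity, tolerance = 1e-8)
})
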