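#' Render a synthetic USAF-1951 bar target
#'
#' Draws three-bar elements (bar length = 5x bar width, three bars per
#' orientation) for the requested `(group, element)` pairs, horizontal and
#' vertical blocks side by side, then pushes the scene through the camera
#' model at defocus `z_cm`. An element at spatial frequency
#' `lp/mm = 2^(group + (element - 1) / 6)` has bar width
#' `px_per_mm / (2 * lp_per_mm)` pixels; requesting an element whose bar
#' width falls below one pixel is an error naming the element.
#'
#' @param elements List of `c(group, element)` pairs, or a 2-column matrix.
#' @param px_per_mm Rendering scale in pixels per mm.
#' @param camera An [camera_model()].
#' @param z_cm Signed defocus distance in cm.
#' @param seed Integer seed (noise reproducibility).
#' @param amplitude_dn Latent bar intensity in DN (background is 0).
#' @param margin_px Optional frame margin around the bar blocks in px;
#'   defaults to one bar width of the coarsest element. Defocus stacks
#'   should use a margin of at least three times the largest blur sigma
#'   so the blurred target stays inside the frame (a real acquisition
#'   has the target small within the field of view).
#' @return A list with `image` ([fgs_image]), `layout` (an `fgs_layout`
#'   whose ROIs cover each element's horizontal and vertical bar block,
#'   tagged with `lp_per_mm` and `orientation`), and `truth` (the
#'   generating parameters, sufficient to re-render bit-identically).
#' @export
#' @examples
#' cam <- camera_model(blur_sigma0 = 0, read_noise_sd = 0, poisson_scale = 0)
#' r <- render_usaf(list(c(0, 1)), px_per_mm = 10, camera = cam, seed = 1)
#' sort(unique(as.vector(r$image$pixels)))
render_usaf <- function(elements, px_per_mm, camera = camera_model(),
                        z_cm = 0, seed = 1L, amplitude_dn = NULL,
                        margin_px = NULL) {
  if (is.matrix(elements)) elements <- asplit(elements, 1)
  stopifnot(length(elements) >= 1L, px_per_mm > 0)
  if (is.null(amplitude_dn)) amplitude_dn <- 0.75 * (2^camera$bit_depth - 1)
  els <- lapply(elements, function(ge) usaf_element(ge[1], ge[2]))
  widths <- vapply(els, function(e) px_per_mm / (2 * e$lp_per_mm), 0)
  bad <- widths < 1
  if (any(bad)) {
    e <- els[[which(bad)[1]]]
    stop(sprintf(
      "bar width %.2f px < 1 px for group %d element %d at %g px/mm",
      widths[which(bad)[1]], e$group, e$element, px_per_mm), call. = FALSE)
  }
  wmax <- max(widths)
  margin <- if (is.null(margin_px)) max(6, ceiling(wmax))
            else as.integer(margin_px)
  gap <- max(6, ceiling(2 * wmax))
  img_w <- ceiling(margin + 5 * wmax + gap + 5 * wmax + margin)
  heights <- ceiling(5 * widths) + margin
  img_h <- max(32L, margin + sum(heights))
  img_w <- max(32L, img_w)
  scene <- matrix(0, img_h, img_w)
  rois <- list()
  y0 <- margin
  for (i in seq_along(els)) {
    w <- widths[i]
    e <- els[[i]]
    x_h <- margin
    x_v <- margin + 5 * w + gap
    scene <- draw_bars(scene, y0, x_h, w, "horizontal", amplitude_dn)
    scene <- draw_bars(scene, y0, x_v, w, "vertical", amplitude_dn)
    nm <- sprintf("g%de%d", e$group, e$element)
    rois[[paste0(nm, "_h")]] <- block_roi(paste0(nm, "_h"), y0, x_h, w,
                                          "horizontal", e$lp_per_mm)
    rois[[paste0(nm, "_v")]] <- block_roi(paste0(nm, "_v"), y0, x_v, w,
                                          "vertical", e$lp_per_mm)
    y0 <- y0 + 5 * w + margin
  }
  image <- apply_camera(scene, camera, z_cm = z_cm, seed = seed,
                        source = sprintf("synthetic:usaf(seed=%d)", seed))
  layout <- structure(
    list(rois = rois, image_dim = dim(scene),
         meta = list(phantom = "usaf", bit_depth = camera$bit_depth,
                     px_per_mm = px_per_mm)),
    class = "fgs_layout")
  truth <- synth_truth("usaf", camera, seed,
                       args = list(elements = lapply(els, function(e)
                                     c(e$group, e$element)),
                                   px_per_mm = px_per_mm, z_cm = z_cm,
                                   amplitude_dn = amplitude_dn,
                                   margin_px = margin),
                       scene = list(bar_width_px = widths,
                                    lp_per_mm = vapply(els, `[[`, 0,
                                                       "lp_per_mm")))
  list(image = image, layout = layout, truth = truth)
}

# stripes evaluated at pixel centers (0-based index r covers [r, r + 1))
draw_bars <- function(scene, y0, x0, w, orientation, amp) {
  rows <- seq_len(nrow(scene)) - 0.5
  cols <- seq_len(ncol(scene)) - 0.5
  within <- function(u, from, len) u >= from & u < from + len
  if (orientation == "horizontal") {
    on_r <- within(rows, y0, 5 * w) & ((rows - y0) %% (2 * w)) < w
    on_c <- within(cols, x0, 5 * w)
  } else {
    on_r <- within(rows, y0, 5 * w)
    on_c <- within(cols, x0, 5 * w) & ((cols - x0) %% (2 * w)) < w
  }
  scene[on_r, on_c] <- amp
  scene
}

block_roi <- function(name, y0, x0, w, orientation, lp) {
  r0 <- ceiling(y0)
  c0 <- ceiling(x0)
  roi_rect(name, row0 = r0, col0 = c0,
           height = max(1, floor(y0 + 5 * w) - r0),
           width = max(1, floor(x0 + 5 * w) - c0),
           orientation = orientation, lp_per_mm = lp)
}

#' Render a homogeneous fluorescent slab (uniformity phantom)
#'
#' The latent scene is a constant `level_dn`; the observed image is
#' `level_dn * V(r)` plus configured noise, quantized. Emulates a
#' fluorescent slab larger than the field of view.
#'
#' @param size_px `c(height, width)` in pixels.
#' @param level_dn Latent intensity in DN.
#' @inheritParams render_usaf
#' @return A list with `image` and `truth`.
#' @export
render_uniform_field <- function(size_px = c(400, 400), level_dn = 40000,
                                 camera = camera_model(), seed = 1L) {
  stopifnot(length(size_px) == 2L, all(size_px >= 16), level_dn > 0)
  scene <- matrix(level_dn, size_px[1], size_px[2])
  image <- apply_camera(scene, camera, z_cm = 0, seed = seed,
                        source = sprintf("synthetic:uniform(seed=%d)", seed))
  truth <- synth_truth("uniform", camera, seed,
                       args = list(size_px = size_px, level_dn = level_dn))
  list(image = image, truth = truth)
}

#' Render an equidistant fluorescent dot grid with radial distortion
#'
#' Dots are placed on an ideal lattice and displaced about the image
#' center by the Brown model `r_d = r_u * (1 + k1 * r_u^2 + k2 * r_u^4)`,
#' with radii normalized by the half-diagonal. Each dot is a Gaussian blob
#' so its center survives at subpixel accuracy.
#'
#' @param spacing_px Lattice spacing in pixels.
#' @param rows,cols Lattice size.
#' @param dot_sigma_px Gaussian dot radius parameter (>= 1 px footprint).
#' @inheritParams render_usaf
#' @return A list with `image`, `truth` (including undistorted and
#'   distorted centers as `n x 2` `(row, col)` matrices).
#' @export
render_dot_grid <- function(spacing_px = 40, rows = 5, cols = 9,
                            camera = camera_model(), seed = 1L,
                            dot_sigma_px = 2, amplitude_dn = NULL) {
  stopifnot(spacing_px >= 4, rows >= 2, cols >= 4, dot_sigma_px >= 0.5)
  if (is.null(amplitude_dn)) amplitude_dn <- 0.75 * (2^camera$bit_depth - 1)
  margin <- spacing_px
  h <- (rows - 1) * spacing_px + 2 * margin
  w <- (cols - 1) * spacing_px + 2 * margin
  cr <- (h - 1) / 2
  cc <- (w - 1) / 2
  gr <- (seq_len(rows) - (rows + 1) / 2) * spacing_px + cr
  gc <- (seq_len(cols) - (cols + 1) / 2) * spacing_px + cc
  centers <- as.matrix(expand.grid(row = gr, col = gc))
  distorted <- brown_distort(centers, center = c(cr, cc),
                             r_norm = half_diagonal(c(h, w)),
                             k1 = camera$k1, k2 = camera$k2)
  pad <- 3 * dot_sigma_px
  if (any(distorted[, 1] < pad) || any(distorted[, 1] > h - 1 - pad) ||
      any(distorted[, 2] < pad) || any(distorted[, 2] > w - 1 - pad)) {
    stop("distorted dot leaves the frame; reduce |k1|/|k2| or the grid size",
         call. = FALSE)
  }
  scene <- matrix(0, h, w)
  rr <- matrix(seq_len(h) - 1, h, w)
  cc2 <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  for (i in seq_len(nrow(distorted))) {
    d2 <- (rr - distorted[i, 1])^2 + (cc2 - distorted[i, 2])^2
    scene <- scene + amplitude_dn * exp(-d2 / (2 * dot_sigma_px^2))
  }
  scene <- pmin(scene, 2^camera$bit_depth - 1)
  image <- apply_camera(scene, camera, z_cm = 0, seed = seed,
                        source = sprintf("synthetic:dots(seed=%d)", seed))
  truth <- synth_truth("dots", camera, seed,
                       args = list(spacing_px = spacing_px, rows = rows,
                                   cols = cols, dot_sigma_px = dot_sigma_px,
                                   amplitude_dn = amplitude_dn),
                       scene = list(centers_undistorted = centers,
                                    centers_distorted = distorted))
  list(image = image, truth = truth)
}

#' Apply Brown radial distortion to points
#'
#' @param points `n x 2` matrix of `(row, col)` coordinates.
#' @param center `(row, col)` distortion center.
#' @param r_norm Radius normalization (e.g. the half-diagonal).
#' @param k1,k2 Brown coefficients.
#' @return Displaced `n x 2` matrix.
#' @export
brown_distort <- function(points, center, r_norm, k1, k2) {
  d <- sweep(points, 2, center)
  ru <- sqrt(rowSums(d^2)) / r_norm
  f <- 1 + k1 * ru^2 + k2 * ru^4
  sweep(d * f, 2, center, `+`)
}

#' Render a nine-well phantom plate (concentration or depth series)
#'
#' `kind = "conc"` emulates a sensitivity plate: seven wells at
#' 1000/300/100/30/10/3/1 nM ICG-equivalent, a 0 nM control well, and a
#' QD800 well that only lights up when a visible-light leak is configured
#' (it emulates room-light leakage, not an ICG signal). Latent well
#' intensity is `floor + gain_dn_per_nm * C`; the sensor's full-scale
#' clamp provides saturation, so the default gain pegs the 1000 and
#' 300 nM wells at full scale.
#'
#' `kind = "depth"` emulates an imaging-depth plate: eight wells of
#' 1000 nM-equivalent signal under 0.5-6 mm of tissue-mimicking
#' overburden plus a control well of overburden only. Latent intensity is
#' `floor + i0_dn * exp(-depth_mm / attenuation_mm)`; the defaults place
#' the 3-sigma detectability boundary at 4 mm.
#'
#' Wells are 1 cm diameter disks on a 3 x 3 grid at `px_per_mm` scale;
#' the background sits at `floor_dn`.
#'
#' @param kind `"conc"` or `"depth"`.
#' @param concentrations_nm Concentration series in nM (conc plates).
#' @param depths_mm Overburden series in mm (depth plates).
#' @param floor_dn Dark/background floor in DN.
#' @param gain_dn_per_nm Well gain in DN per nM (conc plates).
#' @param i0_dn Surface intensity in DN at zero depth (depth plates).
#' @param attenuation_mm Attenuation length `d_att` in mm (depth plates).
#' @param qd800_leak_dn Visible-leak intensity of the QD800 well in DN;
#'   the well stays at the floor when 0.
#' @param px_per_mm Rendering scale (well radius = 5 mm * `px_per_mm`).
#' @inheritParams render_usaf
#' @return A list with `image`, `layout` (circular well ROIs labelled with
#'   concentration/depth and roles `sample`/`control`/`qd800`), and
#'   `truth` (latent well means, clipped labels, detectability design).
#' @export
render_wells <- function(kind = c("conc", "depth"),
                         camera = camera_model(), seed = 1L,
                         concentrations_nm = c(1000, 300, 100, 30, 10, 3, 1),
                         depths_mm = c(0.5, 1, 1.5, 2, 3, 4, 5, 6),
                         floor_dn = 640, gain_dn_per_nm = 256,
                         i0_dn = 24000, attenuation_mm = 1.1,
                         qd800_leak_dn = 0, px_per_mm = 4) {
  kind <- match.arg(kind)
  radius <- 5 * px_per_mm
  pitch <- 22.5 * px_per_mm
  side <- ceiling(3 * pitch)
  centers <- as.matrix(expand.grid(
    row = pitch * (0:2) + pitch / 2, col = pitch * (0:2) + pitch / 2))
  fs <- 2^camera$bit_depth - 1
  if (kind == "conc") {
    stopifnot(length(concentrations_nm) == 7L)
    latents <- floor_dn + gain_dn_per_nm * concentrations_nm
    labels <- as.character(concentrations_nm)
    roles <- rep("sample", 7L)
    latents <- c(latents, floor_dn, floor_dn + qd800_leak_dn)
    labels <- c(labels, "0", "qd800")
    roles <- c(roles, "control", "qd800")
  } else {
    stopifnot(length(depths_mm) == 8L)
    latents <- floor_dn + i0_dn * exp(-depths_mm / attenuation_mm)
    labels <- as.character(depths_mm)
    roles <- rep("sample", 8L)
    latents <- c(latents, floor_dn)
    labels <- c(labels, "control")
    roles <- c(roles, "control")
  }
  scene <- matrix(floor_dn, side, side)
  nms <- make.unique(ifelse(roles == "sample", paste0("well_", labels),
                            paste0("well_", roles)), sep = "_")
  rois <- list()
  for (i in seq_along(latents)) {
    m <- outer((seq_len(side) - 1 - centers[i, 1])^2,
               (seq_len(side) - 1 - centers[i, 2])^2, `+`) <= radius^2
    scene[m] <- latents[i]
    rois[[nms[i]]] <- roi_circle(nms[i], centers[i, 1], centers[i, 2],
                                 radius, label = labels[i], role = roles[i])
  }
  image <- apply_camera(scene, camera, z_cm = 0, seed = seed,
                        source = sprintf("synthetic:%s_wells(seed=%d)",
                                         kind, seed))
  # wells the sensor clamp clipped: every disk pixel reaches full scale
  # even under the worst-case vignette attenuation (1 - v)
  vmin <- 1 - camera$vignette_strength
  clipped <- labels[latents * camera$gain * vmin >= fs]
  layout <- structure(
    list(rois = rois, image_dim = c(side, side),
         meta = list(phantom = paste0(kind, "_wells"),
                     bit_depth = camera$bit_depth, px_per_mm = px_per_mm)),
    class = "fgs_layout")
  scene_info <- list(latent_dn = stats::setNames(latents, labels),
                     clipped_labels = clipped, floor_dn = floor_dn)
  if (kind == "conc") {
    scene_info$gain_dn_per_nm <- gain_dn_per_nm
  } else {
    scene_info$i0_dn <- i0_dn
    scene_info$attenuation_mm <- attenuation_mm
  }
  truth <- synth_truth(paste0(kind, "_wells"), camera, seed,
                       args = list(kind = kind,
                                   concentrations_nm = concentrations_nm,
                                   depths_mm = depths_mm,
                                   floor_dn = floor_dn,
                                   gain_dn_per_nm = gain_dn_per_nm,
                                   i0_dn = i0_dn,
                                   attenuation_mm = attenuation_mm,
                                   qd800_leak_dn = qd800_leak_dn,
                                   px_per_mm = px_per_mm),
                       scene = scene_info)
  list(image = image, layout = layout, truth = truth)
}

#' Render a near-Gaussian excitation spectrum
#'
#' A Gaussian band on a uniform wavelength grid spanning
#' `center_nm +/- 6 * sigma_nm`; the true FWHM
#' `2 * sqrt(2 * log(2)) * sigma_nm` is recorded in the ground truth.
#'
#' @param center_nm Band center in nm.
#' @param sigma_nm Gaussian sigma in nm.
#' @param amplitude Peak intensity above baseline (0 marks the fixture
#'   degenerate in its ground truth).
#' @param baseline Constant offset.
#' @param noise_sd Additive Gaussian noise sd.
#' @param n_samples Grid size; the step must not exceed `sigma_nm / 3`.
#' @param seed Integer seed for the noise draw.
#' @return A list with `trace` ([spectral_trace()]) and `truth`.
#' @export
render_spectrum <- function(center_nm = 780, sigma_nm = 1.25,
                            amplitude = 1000, baseline = 50, noise_sd = 0,
                            n_samples = 161, seed = 1L) {
  stopifnot(sigma_nm > 0, n_samples >= 8, amplitude >= 0, baseline >= 0)
  wl <- seq(center_nm - 6 * sigma_nm, center_nm + 6 * sigma_nm,
            length.out = n_samples)
  step <- wl[2] - wl[1]
  if (step > sigma_nm / 3 + 1e-12) {
    stop(sprintf("grid step %.3g nm too coarse for sigma %.3g nm (need <= sigma/3)",
                 step, sigma_nm), call. = FALSE)
  }
  it <- baseline + amplitude * exp(-(wl - center_nm)^2 / (2 * sigma_nm^2))
  if (noise_sd > 0) {
    it <- with_seed(seed, pmax(it + stats::rnorm(length(it), 0, noise_sd), 0))
  }
  truth <- synth_truth("spectrum", NULL, seed,
                       args = list(center_nm = center_nm, sigma_nm = sigma_nm,
                                   amplitude = amplitude, baseline = baseline,
                                   noise_sd = noise_sd,
                                   n_samples = n_samples),
                       scene = list(true_fwhm_nm = 2 * sqrt(2 * log(2)) *
                                      sigma_nm,
                                    degenerate = amplitude == 0))
  list(trace = spectral_trace(wl, it), truth = truth)
}

synth_truth <- function(kind, camera, seed, args, scene = list()) {
  structure(list(kind = kind,
                 camera = if (is.null(camera)) NULL else camera_to_list(camera),
                 rng_seed = as.integer(seed), args = args, scene = scene),
            class = "fgs_truth")
}

#' Re-render a synthetic fixture from its ground-truth sidecar
#'
#' Every ground-truth record is sufficient to regenerate its fixture
#' bit-identically (LUT functions excepted; they are not serializable).
#'
#' @param truth An `fgs_truth` (or the equivalent list parsed from a
#'   ground-truth JSON sidecar).
#' @return The same structure the original `render_*` call returned.
#' @export
re_render <- function(truth) {
  camera <- if (!is.null(truth$camera)) {
    do.call(camera_model, truth$camera)
  } else NULL
  a <- truth$args
  switch(truth$kind,
    usaf = render_usaf(a$elements, a$px_per_mm, camera, z_cm = a$z_cm,
                       seed = truth$rng_seed, amplitude_dn = a$amplitude_dn,
                       margin_px = a$margin_px),
    uniform = render_uniform_field(unlist(a$size_px), a$level_dn, camera,
                                   seed = truth$rng_seed),
    dots = render_dot_grid(a$spacing_px, a$rows, a$cols, camera,
                           seed = truth$rng_seed,
                           dot_sigma_px = a$dot_sigma_px,
                           amplitude_dn = a$amplitude_dn),
    conc_wells = ,
    depth_wells = render_wells(a$kind, camera, seed = truth$rng_seed,
                               concentrations_nm = unlist(a$concentrations_nm),
                               depths_mm = unlist(a$depths_mm),
                               floor_dn = a$floor_dn,
                               gain_dn_per_nm = a$gain_dn_per_nm,
                               i0_dn = a$i0_dn,
                               attenuation_mm = a$attenuation_mm,
                               qd800_leak_dn = a$qd800_leak_dn,
                               px_per_mm = a$px_per_mm),
    spectrum = render_spectrum(a$center_nm, a$sigma_nm, a$amplitude,
                               a$baseline, a$noise_sd, a$n_samples,
                               seed = truth$rng_seed),
    stop("unknown fixture kind: ", truth$kind, call. = FALSE))
}
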