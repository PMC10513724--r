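#' Write a synthetic fixture set to disk
#'
#' Renders one synthetic phantom under the package's default study
#' conditions and writes: the image as a 16-bit TIFF (or the spectrum as
#' a two-column CSV), a ground-truth JSON sidecar sufficient to
#' regenerate the fixture (see [re_render()]), and, where the fixture has
#' ROIs, a layout YAML consumable by [load_layout()].
#'
#' @param kind One of `"usaf"`, `"uniform"`, `"dots"`, `"conc"`,
#'   `"depth"`, `"spectrum"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param camera Camera model; defaults to [camera_model()].
#' @param ... Extra arguments passed to the matching `render_*` function.
#' @return Invisibly, a named list of the written paths plus the render.
#' @export
synth_fixture <- function(kind = c("usaf", "uniform", "dots", "conc",
                                   "depth", "spectrum"),
                          out_dir, seed = 1L, camera = camera_model(), ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  r <- switch(kind,
    usaf = render_usaf(elements = usaf_nine_element_set(), px_per_mm = 20,
                       camera = camera, seed = seed, ...),
    uniform = render_uniform_field(camera = camera, seed = seed, ...),
    dots = render_dot_grid(camera = camera, seed = seed, ...),
    conc = render_wells("conc", camera = camera, seed = seed, ...),
    depth = render_wells("depth", camera = camera, seed = seed, ...),
    spectrum = render_spectrum(seed = seed, ...))
  base <- file.path(out_dir, kind)
  paths <- list()
  if (kind == "spectrum") {
    paths$trace <- paste0(base, ".csv")
    utils::write.csv(data.frame(wavelength_nm = r$trace$wavelength_nm,
                                intensity = r$trace$intensity),
                     paths$trace, row.names = FALSE)
  } else {
    paths$image <- paste0(base, ".tif")
    write_image(r$image, paths$image)
  }
  if (!is.null(r$layout)) {
    paths$layout <- paste0(base, "_layout.yaml")
    write_layout(r$layout, paths$layout)
  }
  paths$truth <- paste0(base, "_truth.json")
  jsonlite::write_json(truth_to_list(r$truth), paths$truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(render = r)))
}

#' The nine-element frequency set used for sharpness curves
#'
#' `(group, element)` pairs covering 1.0, 1.26, 1.59, 2.0, 2.52, 3.17,
#' 4.0, 5.04, and 6.35 lp/mm (every second sixth-octave step from group 0
#' element 1).
#'
#' @return A list of `c(group, element)` pairs.
#' @export
usaf_nine_element_set <- function() {
  list(c(0, 1), c(0, 3), c(0, 5), c(1, 1), c(1, 3), c(1, 5),
       c(2, 1), c(2, 3), c(2, 5))
}

truth_to_list <- function(truth) {
  out <- unclass(truth)
  out$scene <- lapply(out$scene, function(x) {
    if (is.matrix(x)) {
      list(matrix = TRUE, nrow = nrow(x), data = as.vector(x))
    } else x
  })
  out
}

truth_from_list <- function(x) {
  x$scene <- lapply(x$scene, function(s) {
    if (is.list(s) && isTRUE(s$matrix)) {
      matrix(unlist(s$data), nrow = s$nrow)
    } else if (is.list(s)) unlist(s) else s
  })
  if (!is.null(x$camera)) x$camera <- lapply(x$camera, function(v) v)
  x$args <- x$args
  structure(x, class = "fgs_truth")
}

#' Load a ground-truth sidecar written by [synth_fixture()]
#'
#' @param path Path to a `*_truth.json` file.
#' @return An `fgs_truth` usable with [re_render()].
#' @export
load_truth <- function(path) {
  truth_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Generate a complete synthetic system for a protocol run
#'
#' Writes every fixture the nine-test protocol consumes (spectrum, USAF
#' target, defocus stack, uniformity slab, dot grid, concentration and
#' depth plates) plus a ready-to-run protocol configuration YAML.
#' The defocus stack spans `z_stack_cm` (1 cm steps by default, matching
#' the convention of acquiring 1-7 cm on both sides of focus).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; sub-fixtures derive their seeds from it.
#' @param camera Camera model shared by all image fixtures.
#' @param z_stack_cm Defocus distances for the DOF stack.
#' @param power_density_mw_cm2 Illumination power density recorded as
#'   metadata (the protocol books it, it is not measured from images).
#' @param system_id Identifier written into the config.
#' @return The path of the written config YAML.
#' @export
synth_protocol <- function(out_dir, seed = 1L, camera = camera_model(),
                           z_stack_cm = -7:7,
                           power_density_mw_cm2 = 15,
                           system_id = "synthetic-system") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  spectrum <- synth_fixture("spectrum", out_dir, seed = seed + 1L,
                            noise_sd = 5)
  usaf <- synth_fixture("usaf", out_dir, seed = seed + 2L, camera = camera)
  uniform <- synth_fixture("uniform", out_dir, seed = seed + 3L,
                           camera = camera)
  dots <- synth_fixture("dots", out_dir, seed = seed + 4L, camera = camera)
  conc <- synth_fixture("conc", out_dir, seed = seed + 5L, camera = camera)
  depth <- synth_fixture("depth", out_dir, seed = seed + 6L, camera = camera)
  dof_dir <- file.path(out_dir, "dof")
  dir.create(dof_dir, showWarnings = FALSE)
  dof_paths <- vapply(seq_along(z_stack_cm), function(i) {
    z <- z_stack_cm[i]
    r <- render_usaf(list(c(0, 1)), px_per_mm = 20, camera = camera,
                     z_cm = z, seed = seed + 100L + i, margin_px = 40)
    p <- file.path(dof_dir, sprintf("z_%+03d.tif", z))
    write_image(r$image, p)
    if (z == 0) write_layout(r$layout, file.path(dof_dir, "layout.yaml"))
    p
  }, "")
  manifest <- file.path(dof_dir, "manifest.csv")
  utils::write.csv(data.frame(z_cm = z_stack_cm, path = dof_paths),
                   manifest, row.names = FALSE)
  config <- list(
    system = list(system_id = system_id, reported_peak_nm = 780,
                  working_distance_cm = 20,
                  fov_cm = c(12, 12),
                  power_density_mw_cm2 = power_density_mw_cm2,
                  notes = "synthetic fixtures"),
    params = list(background_threshold = 0.2, k_sigma = 3, sat_frac = 0.99,
                  annulus_factor = 1.5, ctf_criterion_percent = 40,
                  dof_threshold_percent = 60, band_half_width_px = 50),
    tests = list(
      excitation_band = list(trace = spectrum$trace),
      power_density = list(value_mw_cm2 = power_density_mw_cm2),
      resolution = list(image = usaf$image, layout = usaf$layout),
      uniformity = list(image = uniform$image),
      distortion = list(image = dots$image),
      dof = list(manifest = manifest,
                 layout = file.path(dof_dir, "layout.yaml")),
      sensitivity = list(image = conc$image, layout = conc$layout),
      depth = list(image = depth$image, layout = depth$layout),
      sbr = list(image = depth$image, layout = depth$layout,
                 well_labels = c("2", "3", "4"))))
  cfg_path <- file.path(out_dir, "protocol.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
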