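#' Parametric camera model for synthetic phantoms
#'
#' The forward model every synthetic fixture is pushed through, in a fixed
#' order: scene -> defocus blur -> vignette x gain -> Poisson-Gaussian
#' noise -> optional LUT -> bit-depth quantization (which also implements
#' sensor saturation by clamping at full scale).
#'
#' * Defocus blur is Gaussian with `sigma(z) = blur_sigma0 +
#'   defocus_slope * |z_cm|`: blur grows linearly with distance from the
#'   plane of focus, the only property a depth-of-field test needs.
#' * Vignetting is the radial quadratic `V(r) = 1 - v * (r / r_max)^2`
#'   with `r_max` the half-diagonal, so `v < 1` keeps `V > 0` everywhere.
#' * Radial distortion follows the Brown model
#'   `r_d = r_u * (1 + k1 * r_u^2 + k2 * r_u^4)` in half-diagonal units
#'   (applied to scene geometry by [render_dot_grid()]).
#' * Noise is `Poisson(latent * poisson_scale) / poisson_scale` plus
#'   Gaussian read noise; set `poisson_scale = 0` and
#'   `read_noise_sd = 0` for exact noiseless renders.
#'
#' @param blur_sigma0 In-focus blur sigma in px (>= 0).
#' @param defocus_slope Blur growth in px per cm of defocus (>= 0).
#' @param vignette_strength `v` in `[0, 1)`.
#' @param k1,k2 Brown radial distortion coefficients.
#' @param gain Multiplicative detector gain (> 0).
#' @param read_noise_sd Gaussian read noise sd in DN (>= 0).
#' @param poisson_scale Photon-noise scale in events per DN (>= 0; 0 = off).
#' @param bit_depth Sensor bit depth.
#' @param lut Optional monotone function DN -> DN applied before
#'   quantization (emulates vendor display look-up tables).
#'
#' @return An object of class `fgs_camera`.
#' @export
#' @examples
#' cam <- camera_model(read_noise_sd = 0, poisson_scale = 0)
camera_model <- function(blur_sigma0 = 0.8, defocus_slope = 0.6,
                         vignette_strength = 0.05, k1 = 0, k2 = 0,
                         gain = 1, read_noise_sd = 96, poisson_scale = 0.125,
                         bit_depth = 16L, lut = NULL) {
  stopifnot(blur_sigma0 >= 0, defocus_slope >= 0,
            vignette_strength >= 0, vignette_strength < 1,
            gain > 0, read_noise_sd >= 0, poisson_scale >= 0)
  if (!is.null(lut)) stopifnot(is.function(lut))
  structure(list(blur_sigma0 = blur_sigma0, defocus_slope = defocus_slope,
                 vignette_strength = vignette_strength, k1 = k1, k2 = k2,
                 gain = gain, read_noise_sd = read_noise_sd,
                 poisson_scale = poisson_scale,
                 bit_depth = as.integer(bit_depth), lut = lut),
            class = "fgs_camera")
}

#' @export
print.fgs_camera <- function(x, ...) {
  cat(sprintf(paste0("<fgs_camera> sigma(z)=%g+%g|z| px, v=%g, k1=%g, ",
                     "k2=%g, gain=%g, read=%g DN, poisson=%g, %d-bit\n"),
              x$blur_sigma0, x$defocus_slope, x$vignette_strength, x$k1,
              x$k2, x$gain, x$read_noise_sd, x$poisson_scale, x$bit_depth))
  invisible(x)
}

blur_sigma_at <- function(camera, z_cm) {
  camera$blur_sigma0 + camera$defocus_slope * abs(z_cm)
}

# half-diagonal of the pixel-center grid; shared by the vignette model,
# the Brown distortion normalization, and the vignette estimator
half_diagonal <- function(dim) {
  sqrt(((dim[1] - 1) / 2)^2 + ((dim[2] - 1) / 2)^2)
}

vignette_field <- function(camera, dim) {
  cr <- (dim[1] - 1) / 2
  cc <- (dim[2] - 1) / 2
  r2 <- outer(((seq_len(dim[1]) - 1) - cr)^2,
              ((seq_len(dim[2]) - 1) - cc)^2, `+`)
  1 - camera$vignette_strength * r2 / half_diagonal(dim)^2
}

#' Push a latent scene through a camera model
#'
#' Applies the fixed forward-model order (blur, vignette and gain, noise,
#' LUT, quantization with clamping at full scale) to a latent scene in DN.
#'
#' @param scene Numeric matrix, latent noiseless scene in DN.
#' @param camera An [camera_model()].
#' @param z_cm Signed defocus distance in cm (0 = plane of focus).
#' @param seed Integer seed for the noise draw (ignored when noiseless).
#' @param source Provenance string for the output image.
#' @return An [fgs_image].
#' @export
apply_camera <- function(scene, camera, z_cm = 0, seed = 1L,
                         source = "synthetic") {
  stopifnot(inherits(camera, "fgs_camera"), is.matrix(scene))
  sigma <- blur_sigma_at(camera, z_cm)
  px <- scene
  if (sigma > 0) {
    px <- EBImage::gblur(px, sigma = sigma, boundary = "replicate")
    px <- pmax(px, 0)
  }
  px <- px * vignette_field(camera, dim(px)) * camera$gain
  if (camera$poisson_scale > 0 || camera$read_noise_sd > 0) {
    px <- with_seed(seed, {
      out <- px
      if (camera$poisson_scale > 0) {
        out <- stats::rpois(length(out), out * camera$poisson_scale) /
          camera$poisson_scale
        dim(out) <- dim(px)
      }
      if (camera$read_noise_sd > 0) {
        out <- out + stats::rnorm(length(out), 0, camera$read_noise_sd)
      }
      out
    })
    px <- pmax(px, 0)
  }
  if (!is.null(camera$lut)) px <- pmax(camera$lut(px), 0)
  fs <- 2^camera$bit_depth - 1
  px <- pmin(pmax(round(px), 0), fs)
  fgs_image(px, bit_depth = camera$bit_depth, source = source)
}

camera_to_list <- function(camera) {
  out <- unclass(camera)
  out$lut <- NULL # functions are not serialized; re-attach when re-rendering
  out
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
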