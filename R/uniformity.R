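#' Field-of-view illumination uniformity profile
#'
#' Extracts the horizontal band centered on the middle of the image
#' (`band_half_width_px` rows above and below), averages it per column,
#' and normalizes the resulting profile to its maximum. The profile is
#' invariant to global intensity scaling. Pixels excluded by
#' [masked_region_zeroing()] (e.g. burned-in vendor logos) do not enter
#' the column means; a fully masked column is interpolated from its
#' neighbors and flagged.
#'
#' @param image An [fgs_image].
#' @param band_half_width_px Rows selected above and below the mid-row
#'   (default 50).
#' @param median_window Optional odd window for a moving-median hot-pixel
#'   guard applied before normalization; `NULL` (default) disables it.
#' @return An object of class `fgs_uniformity`: `x_norm` (columns mapped
#'   to `[0, 1]`), `profile` (normalized column means, max = 1),
#'   `band_rows` (1-based row indices used), `image_dim`,
#'   `interpolated_cols`, and `summary` with `frac_ge_090` (fraction of
#'   columns at or above 0.9), `min_profile`, `center_to_edge_ratio`.
#' @export
#' @examples
#' u <- uniformity_profile(render_uniform_field(
#'   camera = camera_model(vignette_strength = 0.3, read_noise_sd = 0,
#'                         poisson_scale = 0),
#'   seed = 1)$image)
#' u$summary$min_profile
uniformity_profile <- function(image, band_half_width_px = 50,
                               median_window = NULL) {
  assert_image(image)
  d <- dim(image$pixels)
  h <- as.integer(band_half_width_px)
  if (d[1] <= 2L * h) {
    stop(sprintf("band of +/-%d rows does not fit a %d-row image", h, d[1]),
         call. = FALSE)
  }
  mid <- floor((d[1] - 1) / 2) + 1L # 1-based middle row
  band_rows <- seq.int(max(1L, mid - h), min(d[1], mid + h))
  band <- image$pixels[band_rows, , drop = FALSE]
  excluded <- image$excluded
  interpolated <- integer(0)
  if (!is.null(excluded)) {
    exb <- excluded[band_rows, , drop = FALSE]
    band[exb] <- NA_real_
    col_means <- colMeans(band, na.rm = TRUE)
    interpolated <- which(!is.finite(col_means))
    if (length(interpolated) > 0L) {
      good <- which(is.finite(col_means))
      if (length(good) < 2L) stop("band almost entirely masked",
                                  call. = FALSE)
      col_means[interpolated] <- stats::approx(
        good, col_means[good], xout = interpolated, rule = 2)$y
    }
  } else {
    col_means <- colMeans(band)
  }
  if (!is.null(median_window)) {
    stopifnot(median_window %% 2 == 1, median_window >= 3)
    col_means <- as.numeric(stats::runmed(col_means, median_window,
                                          endrule = "median"))
  }
  mx <- max(col_means)
  if (mx <= 0) stop("band is entirely dark", call. = FALSE)
  profile <- col_means / mx
  center_col <- floor((d[2] - 1) / 2) + 1L
  summary <- list(
    frac_ge_090 = mean(profile >= 0.9),
    min_profile = min(profile),
    center_to_edge_ratio = profile[center_col] /
      mean(profile[c(1L, d[2])]))
  structure(list(x_norm = (seq_len(d[2]) - 1) / (d[2] - 1),
                 profile = profile, band_rows = band_rows,
                 band_half_width_px = h, image_dim = d,
                 interpolated_cols = interpolated,
                 median_window = median_window, summary = summary),
            class = "fgs_uniformity")
}

#' @export
print.fgs_uniformity <- function(x, ...) {
  cat(sprintf(paste0("<fgs_uniformity> %d columns; min %.3f, ",
                     ">=0.9 fraction %.2f, center/edge %.3f\n"),
              length(x$profile), x$summary$min_profile,
              x$summary$frac_ge_090, x$summary$center_to_edge_ratio))
  invisible(x)
}

#' Zero out masked regions and exclude them from uniformity statistics
#'
#' Emulates the treatment of burned-in vendor overlays: masked pixels are
#' set to 0 for display and recorded so that [uniformity_profile()] can
#' exclude them from its column means.
#'
#' @param image An [fgs_image].
#' @param masks A list of ROIs to mask (empty list is the identity).
#' @return The image with masked pixels set to 0 and an `excluded`
#'   logical matrix attached.
#' @export
masked_region_zeroing <- function(image, masks) {
  assert_image(image)
  if (length(masks) == 0L) return(image)
  d <- dim(image$pixels)
  excl <- if (is.null(image$excluded)) matrix(FALSE, d[1], d[2])
          else image$excluded
  for (roi in masks) {
    validate_roi(roi, image)
    excl <- excl | roi_mask(roi, d)
  }
  image$pixels[excl] <- 0
  image$excluded <- excl
  image
}

#' Estimate vignette strength from a uniformity profile
#'
#' Inverts the radial-quadratic vignette model
#' `V(r) = 1 - v * (r / r_max)^2` (with `r_max` the half-diagonal) from
#' the minimum of a normalized band profile, accounting for both the
#' band's vertical extent and the normalization of the profile to its
#' (center) maximum.
#'
#' @param profile An `fgs_uniformity` result.
#' @return Estimated vignette strength `v`.
#' @export
estimate_vignette <- function(profile) {
  stopifnot(inherits(profile, "fgs_uniformity"))
  d <- profile$image_dim
  cr <- (d[1] - 1) / 2
  cc <- (d[2] - 1) / 2
  rmax2 <- half_diagonal(d)^2
  m2 <- mean(((profile$band_rows - 1) - cr)^2)
  i_min <- which.min(profile$profile)
  x2 <- ((i_min - 1) - cc)^2
  a <- m2 / rmax2 # mean squared radius (relative) at the profile maximum
  b <- (x2 + m2) / rmax2 # at the profile minimum
  p <- profile$summary$min_profile
  (1 - p) / (b - p * a)
}
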