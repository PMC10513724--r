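#' Radial distortion from a dot-grid phantom
#'
#' Quantifies spatial distortion from the spacing of equidistant
#' fluorescent dots along the middle of the field of view. Two horizontal
#' bands over the dot rows nearest mid-height are reduced to 1-D column
#' profiles; dot positions are the profile's local maxima at the stated
#' prominence, refined to subpixel accuracy by 3-point parabolic
#' interpolation; spacings are successive differences. Spacings are
#' normalized by the maximum spacing, so an undistorted grid reads
#' exactly 1 everywhere and distortion pulls values below 1
#' (`distortion_index = 1 - min(spacings_norm)`).
#'
#' @param image An [fgs_image] of a dot grid.
#' @param row_bands Optional list of one or two `c(row0, height)` bands
#'   (0-based, half-open). By default the two dot rows nearest mid-height
#'   are auto-detected from the row-mean profile and banded to a quarter
#'   of the row pitch on each side.
#' @param min_prominence_frac Minimum peak prominence as a fraction of
#'   the profile range (default 0.2).
#' @return An object of class `fgs_dotgrid`: `peak_positions_px`
#'   (subpixel 0-based column positions, averaged over bands when both
#'   yield the same dot count), `spacings_px`, `spacings_norm`,
#'   `distortion_index`, `side_flags` (`"left"`, `"right"`, or `"none"`),
#'   and `per_band` positions.
#' @export
dot_distances <- function(image, row_bands = NULL,
                          min_prominence_frac = 0.2) {
  assert_image(image)
  px <- image$pixels
  d <- dim(px)
  if (is.null(row_bands)) row_bands <- auto_row_bands(px, min_prominence_frac)
  stopifnot(length(row_bands) >= 1L, length(row_bands) <= 2L)
  per_band <- lapply(row_bands, function(b) {
    rows <- seq.int(b[1] + 1L, min(d[1], b[1] + b[2]))
    prof <- colMeans(px[rows, , drop = FALSE])
    band_peaks(prof, min_prominence_frac)
  })
  counts <- lengths(per_band)
  positions <- if (length(per_band) == 2L && counts[1] == counts[2]) {
    (per_band[[1]] + per_band[[2]]) / 2
  } else {
    per_band[[which.max(counts)]]
  }
  if (length(positions) < 4L) {
    stop(sprintf("insufficient dots: %d peaks found, need >= 4",
                 length(positions)), call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("detection error: non-monotone dot positions", call. = FALSE)
  }
  spacings <- diff(positions)
  spacings_norm <- spacings / max(spacings)
  distortion_index <- 1 - min(spacings_norm)
  side <- if (distortion_index < 1e-9) {
    "none"
  } else {
    i <- which.min(spacings_norm)
    mid_of_min <- (positions[i] + positions[i + 1]) / 2
    if (mid_of_min < (d[2] - 1) / 2) "left" else "right"
  }
  structure(list(peak_positions_px = positions, spacings_px = spacings,
                 spacings_norm = spacings_norm,
                 distortion_index = distortion_index, side_flags = side,
                 per_band = per_band, row_bands = row_bands,
                 min_prominence_frac = min_prominence_frac),
            class = "fgs_dotgrid")
}

#' @export
print.fgs_dotgrid <- function(x, ...) {
  cat(sprintf(paste0("<fgs_dotgrid> %d dots, spacing %.2f-%.2f px, ",
                     "distortion index %.4f (%s side)\n"),
              length(x$peak_positions_px), min(x$spacings_px),
              max(x$spacings_px), x$distortion_index, x$side_flags))
  invisible(x)
}

# locate the two dot rows nearest mid-height and band each to a quarter
# of the row pitch
auto_row_bands <- function(px, min_prominence_frac) {
  d <- dim(px)
  prof <- rowMeans(px)
  rows <- band_peaks(prof, min_prominence_frac)
  if (length(rows) < 1L) stop("no dot rows detected", call. = FALSE)
  mid <- (d[1] - 1) / 2
  rows <- rows[order(abs(rows - mid))]
  pick <- sort(utils::head(rows, 2L))
  pitch <- if (length(rows) >= 2L) stats::median(diff(sort(rows)))
           else d[1] / 4
  half <- max(2L, floor(pitch / 4))
  lapply(pick, function(r) {
    r0 <- max(0L, floor(r - half))
    c(r0, min(d[1], ceiling(r + half) + 1L) - r0)
  })
}

band_peaks <- function(prof, min_prominence_frac) {
  rng <- diff(range(prof))
  if (rng <= 0) return(numeric(0))
  idx <- find_peaks(prof, min_prominence = min_prominence_frac * rng)
  if (length(idx) == 0L) return(numeric(0))
  # enforce a minimum separation of half the median spacing, keeping the
  # taller peak (deterministic: height desc, then position)
  if (length(idx) >= 2L) {
    min_sep <- stats::median(diff(idx)) / 2
    keep <- integer(0)
    for (i in idx[order(-prof[idx], idx)]) {
      if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  vapply(idx, function(i) refine_parabolic(prof, i), 0)
}

# local maxima (plateau centers) with a prominence cut
find_peaks <- function(y, min_prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j == n || y[j + 1L] < y[i]) {
        peaks <- c(peaks, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0L) return(peaks)
  prom <- vapply(peaks, function(p) peak_prominence(y, p), 0)
  peaks[prom >= min_prominence]
}

peak_prominence <- function(y, p) {
  left <- if (p == 1L) y[1] else {
    higher <- which(y[seq_len(p - 1L)] > y[p])
    lo <- if (length(higher) == 0L) 1L else max(higher)
    min(y[lo:p])
  }
  right <- if (p == length(y)) y[p] else {
    after <- seq.int(p + 1L, length(y))
    higher <- after[y[after] > y[p]]
    hi <- if (length(higher) == 0L) length(y) else min(higher)
    min(y[p:hi])
  }
  y[p] - max(left, right)
}

# 3-point parabolic subpixel refinement; returns a 0-based position
refine_parabolic <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(i - 1)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(i - 1) # flat or non-concave: keep the sample
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  (i - 1) + max(-0.5, min(0.5, delta))
}
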