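#' Load a phantom image from disk
#'
#' Reads TIFF, PNG, or JPEG frames into the shared [fgs_image] container.
#' Pixel values are rescaled from the reader's `[0, 1]` convention back to
#' digital numbers at the container's bit depth. Color frames are reduced to
#' a single channel according to `channel_policy`: systems that render
#' fluorescence as a display overlay carry no defensible channel weighting,
#' so the default luminance reduction is the unweighted channel mean;
#' systems that encode fluorescence in one channel should use
#' `"named_channel"` with `channel_index`.
#'
#' MP4 video is part of some vendors' acquisition conventions (one frame at
#' position 1/totalframes, i.e. the first frame, is used for
#' quantification); decoding it requires an ffmpeg-backed reader, which this
#' package does not bundle, so MP4 paths raise an unsupported-format error.
#'
#' @param path Path to a `.tif`/`.tiff`, `.png`, or `.jpg`/`.jpeg` file.
#' @param frame_policy `"first_frame"` (default) or `"index"`; recorded in
#'   provenance. Multi-frame TIFFs use frame `frame_index` under `"index"`.
#' @param frame_index 1-based frame index when `frame_policy = "index"`.
#' @param channel_policy `"luminance"` (unweighted channel mean, default),
#'   `"as_is"` (requires a single-channel file), or `"named_channel"`.
#' @param channel_index 1-based channel picked under `"named_channel"`.
#' @param bit_depth Optional override of the container-inferred bit depth,
#'   e.g. when a 12-bit sensor image travels in a 16-bit TIFF (the sidecar
#'   metadata of synthetic fixtures records the true depth).
#'
#' @return An [fgs_image]. JPEG inputs are flagged `lossy`.
#' @export
load_image <- function(path,
                       frame_policy = c("first_frame", "index"),
                       frame_index = 1L,
                       channel_policy = c("luminance", "as_is",
                                          "named_channel"),
                       channel_index = 1L,
                       bit_depth = NULL) {
  frame_policy <- match.arg(frame_policy)
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lossy <- FALSE
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(frames) == 0L) stop("no frames in ", path, call. = FALSE)
    idx <- if (frame_policy == "first_frame") 1L else as.integer(frame_index)
    if (idx < 1L || idx > length(frames)) {
      stop(sprintf("frame %d not present (%d frames)", idx, length(frames)),
           call. = FALSE)
    }
    arr <- frames[[idx]]
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    idx <- 1L
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- unclass(EBImage::imageData(EBImage::readImage(path)))
    # EBImage stores images x-by-y; transpose back to row-major
    arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
    bits <- 8L
    idx <- 1L
    lossy <- TRUE
  } else if (ext == "mp4") {
    stop("MP4 input is not supported by this build (no ffmpeg-backed ",
         "reader available); extract the first frame to TIFF/PNG first",
         call. = FALSE)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  px <- reduce_channels(arr, channel_policy, channel_index)
  px <- matrix(as.numeric(px), nrow = nrow(px)) # drop reader attributes
  inferred <- as.integer(round(bits))
  depth <- if (is.null(bit_depth)) inferred else as.integer(bit_depth)
  px <- round(px * (2^inferred - 1))
  if (!is.null(bit_depth)) px <- pmin(px, 2^depth - 1)
  fgs_image(px, bit_depth = depth,
            source = sprintf("%s#frame=%d;policy=%s;channels=%s", path, idx,
                             frame_policy, channel_policy),
            lossy = lossy)
}

reduce_channels <- function(arr, channel_policy, channel_index) {
  nd <- length(dim(arr))
  if (nd == 2L) return(unclass(arr))
  if (nd != 3L) stop("unexpected image array rank: ", nd, call. = FALSE)
  nch <- dim(arr)[3]
  # drop a pure alpha channel from the average
  color <- if (nch == 4L) arr[, , 1:3, drop = FALSE] else arr
  switch(channel_policy,
    as_is = stop("`as_is` channel policy on a ", nch,
                 "-channel image; use luminance or named_channel",
                 call. = FALSE),
    luminance = apply(color, c(1, 2), mean),
    named_channel = {
      k <- as.integer(channel_index)
      if (k < 1L || k > dim(color)[3]) {
        stop("channel_index out of range", call. = FALSE)
      }
      color[, , k]
    })
}

#' Write an image to a 16-bit TIFF
#'
#' Digital numbers are stored as `DN / 65535`, so any image with
#' `bit_depth <= 16` round-trips bit-identically through [load_image()]
#' (the container then reports 16-bit; pass the true depth back via
#' `bit_depth` on load, or through a layout sidecar).
#'
#' @param image An [fgs_image] with `bit_depth <= 16`.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  if (image$bit_depth > 16L) stop("only bit depths <= 16 can be written",
                                  call. = FALSE)
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Construct a spectral trace
#'
#' @param wavelength_nm Strictly increasing vector of positive wavelengths.
#' @param intensity Non-negative intensities (arbitrary units), same length.
#' @return An object of class `spectral_trace`.
#' @export
spectral_trace <- function(wavelength_nm, intensity) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(intensity),
            length(wavelength_nm) == length(intensity))
  if (length(wavelength_nm) < 8L) {
    stop("a spectral trace needs at least 8 samples", call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0) ||
      any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be positive, finite, strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0) ||
      !any(intensity > 0)) {
    stop("intensities must be finite, non-negative, not all zero",
         call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity)),
            class = "spectral_trace")
}

#' @export
print.spectral_trace <- function(x, ...) {
  cat(sprintf("<spectral_trace> %d samples, %.1f-%.1f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Load an excitation spectrum from a two-column CSV
#'
#' Expects columns (wavelength_nm, intensity); a header row is optional.
#' Rows are sorted by wavelength and duplicate wavelengths are collapsed by
#' their mean intensity.
#'
#' @param path CSV path.
#' @return A [spectral_trace()].
#' @export
load_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("wavelength_nm", "intensity"),
                        colClasses = "character")
  wl <- suppressWarnings(as.numeric(df$wavelength_nm))
  it <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(wl) || anyNA(it)) {
    stop("non-numeric rows in spectrum file ", path, call. = FALSE)
  }
  if (length(wl) < 8L) {
    stop("insufficient data: spectrum has fewer than 8 rows", call. = FALSE)
  }
  o <- order(wl)
  wl <- wl[o]; it <- it[o]
  if (anyDuplicated(wl)) {
    it <- as.numeric(tapply(it, wl, mean))
    wl <- sort(unique(wl))
  }
  spectral_trace(wl, it)
}

#' Load a phantom layout (named ROIs + metadata) from YAML or JSON
#'
#' A layout file declares the image dimensions it applies to, a list of
#' named ROIs (see [roi_rect()], [roi_circle()]), and free-form phantom
#' metadata (e.g. sensor `bit_depth`, well concentrations in nM, depths in
#' mm). Every ROI is validated against the declared dimensions; duplicate
#' ROI names are a configuration error.
#'
#' @param path `.yaml`/`.yml` or `.json` layout file.
#' @return A list of class `fgs_layout`: `rois` (named list of `fgs_roi`),
#'   `image_dim` (`c(nrow, ncol)` or `NULL`), `meta` (everything else).
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("layout must be YAML or JSON, got .", ext, call. = FALSE)
  }
  layout_from_list(raw, where = path)
}

layout_from_list <- function(raw, where = "layout") {
  if (is.null(raw$rois)) stop("no `rois` entry in ", where, call. = FALSE)
  rois <- lapply(raw$rois, roi_from_list)
  names(rois) <- vapply(rois, `[[`, "", "name")
  if (anyDuplicated(names(rois))) {
    stop("duplicate ROI names in ", where, ": ",
         paste(unique(names(rois)[duplicated(names(rois))]), collapse = ", "),
         call. = FALSE)
  }
  image_dim <- NULL
  if (!is.null(raw$image)) {
    image_dim <- c(raw$image$height, raw$image$width)
    for (roi in rois) validate_roi(roi, image_dim)
  }
  meta <- raw[setdiff(names(raw), c("rois", "image"))]
  structure(list(rois = rois, image_dim = image_dim, meta = meta),
            class = "fgs_layout")
}

#' @export
print.fgs_layout <- function(x, ...) {
  cat(sprintf("<fgs_layout> %d ROIs%s\n", length(x$rois),
              if (!is.null(x$image_dim))
                sprintf(" for a %d x %d image", x$image_dim[1], x$image_dim[2])
              else ""))
  invisible(x)
}

#' Write a layout to YAML
#'
#' @param layout An `fgs_layout` (see [load_layout()]).
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "fgs_layout"))
  out <- layout$meta
  if (!is.null(layout$image_dim)) {
    out$image <- list(height = layout$image_dim[1],
                      width = layout$image_dim[2])
  }
  out$rois <- lapply(unname(layout$rois), roi_to_list)
  yaml::write_yaml(out, path)
  invisible(path)
}
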