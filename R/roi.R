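#' Regions of interest on phantom images
#'
#' ROIs locate phantom features (USAF elements, wells, bands) in pixel
#' coordinates. Coordinates are 0-based, row-major, origin at the top-left;
#' rectangles are half-open (`row0 <= r < row0 + height`). Circle centers
#' may be fractional; a pixel belongs to a disk when its 0-based index
#' center lies within `radius_px` of the ROI center.
#'
#' @param name ROI name, unique within a layout.
#' @param row0,col0 0-based top-left corner of the rectangle.
#' @param height,width Positive extents in pixels.
#' @param center_row,center_col 0-based disk center (may be fractional).
#' @param radius_px Positive disk radius in pixels.
#' @param label Optional label carried through panel quantification:
#'   a concentration in nM, a depth in mm, `"control"`, or `"qd800"`.
#' @param role Optional role string, e.g. `"sample"`, `"control"`, `"qd800"`.
#' @param orientation Optional bar orientation for USAF element ROIs:
#'   `"horizontal"` or `"vertical"`.
#' @param lp_per_mm Optional spatial frequency of the USAF element the ROI
#'   covers, in line pairs per mm.
#'
#' @return An object of class `fgs_roi`.
#' @export
#' @examples
#' roi_rect("band", row0 = 10, col0 = 0, height = 20, width = 64)
#' roi_circle("well_1000", 40, 40, 12, label = "1000", role = "sample")
roi_rect <- function(name, row0, col0, height, width, label = NULL,
                     role = NULL, orientation = NULL, lp_per_mm = NULL) {
  stopifnot(height > 0, width > 0, row0 >= 0, col0 >= 0)
  new_roi(name, "rect",
          geom = c(row0 = unname(row0), col0 = unname(col0),
                   height = unname(height), width = unname(width)),
          label, role, orientation, lp_per_mm)
}

#' @rdname roi_rect
#' @export
roi_circle <- function(name, center_row, center_col, radius_px, label = NULL,
                       role = NULL, orientation = NULL, lp_per_mm = NULL) {
  if (!is.numeric(radius_px) || radius_px <= 0) {
    stop("`radius_px` must be > 0", call. = FALSE)
  }
  new_roi(name, "circle",
          geom = c(center_row = unname(center_row),
                   center_col = unname(center_col),
                   radius_px = unname(radius_px)),
          label, role, orientation, lp_per_mm)
}

new_roi <- function(name, shape, geom, label, role, orientation, lp_per_mm) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation, c("horizontal", "vertical"))
  }
  structure(
    list(name = name, shape = shape, geom = geom,
         label = if (is.null(label)) NULL else as.character(label),
         role = role, orientation = orientation, lp_per_mm = lp_per_mm),
    class = "fgs_roi"
  )
}

#' @export
print.fgs_roi <- function(x, ...) {
  g <- paste(sprintf("%s=%g", names(x$geom), x$geom), collapse = ", ")
  cat(sprintf("<fgs_roi> %s [%s] %s%s\n", x$name, x$shape, g,
              if (!is.null(x$label)) paste0(" label=", x$label) else ""))
  invisible(x)
}

is_roi <- function(x) inherits(x, "fgs_roi")

#' Validate that an ROI lies fully inside an image
#'
#' @param roi An [roi_rect()] / [roi_circle()] object.
#' @param image An [fgs_image], or an integer `c(nrow, ncol)` dimension pair.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_roi <- function(roi, image) {
  stopifnot(is_roi(roi))
  d <- if (is_fgs_image(image)) dim(image$pixels) else as.numeric(image)
  g <- roi$geom
  ok <- if (roi$shape == "rect") {
    g["row0"] >= 0 && g["col0"] >= 0 &&
      g["row0"] + g["height"] <= d[1] && g["col0"] + g["width"] <= d[2]
  } else {
    g["center_row"] - g["radius_px"] >= -0.5 &&
      g["center_col"] - g["radius_px"] >= -0.5 &&
      g["center_row"] + g["radius_px"] <= d[1] - 0.5 &&
      g["center_col"] + g["radius_px"] <= d[2] - 0.5
  }
  if (!ok) {
    stop(sprintf("ROI '%s' extends outside the %d x %d image", roi$name,
                 d[1], d[2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Logical membership mask of an ROI
#'
#' @param dim Integer `c(nrow, ncol)` of the target image.
#' @inheritParams validate_roi
#' @return Logical matrix of the given dimension, `TRUE` inside the ROI.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(is_roi(roi), length(dim) == 2L)
  m <- matrix(FALSE, dim[1], dim[2])
  g <- roi$geom
  if (roi$shape == "rect") {
    rows <- seq.int(g[["row0"]] + 1L, g[["row0"]] + g[["height"]])
    cols <- seq.int(g[["col0"]] + 1L, g[["col0"]] + g[["width"]])
    m[rows, cols] <- TRUE
  } else {
    r <- (seq_len(dim[1]) - 1) - g[["center_row"]]
    c <- (seq_len(dim[2]) - 1) - g[["center_col"]]
    m <- outer(r^2, c^2, `+`) <= g[["radius_px"]]^2
  }
  m
}

#' Extract the pixel values covered by an ROI
#'
#' @inheritParams validate_roi
#' @return Numeric vector of pixel values (row-major over the mask).
#' @export
roi_values <- function(image, roi) {
  assert_image(image)
  validate_roi(roi, image)
  image$pixels[roi_mask(roi, dim(image$pixels))]
}

roi_to_list <- function(roi) {
  out <- c(list(name = roi$name, shape = roi$shape), as.list(roi$geom))
  for (f in c("label", "role", "orientation", "lp_per_mm")) {
    if (!is.null(roi[[f]])) out[[f]] <- roi[[f]]
  }
  out
}

roi_from_list <- function(x) {
  stopifnot(!is.null(x$name), !is.null(x$shape))
  if (x$shape == "rect") {
    roi_rect(x$name, x$row0, x$col0, x$height, x$width, label = x$label,
             role = x$role, orientation = x$orientation,
             lp_per_mm = x$lp_per_mm)
  } else if (x$shape == "circle") {
    roi_circle(x$name, x$center_row, x$center_col, x$radius_px,
               label = x$label, role = x$role, orientation = x$orientation,
               lp_per_mm = x$lp_per_mm)
  } else {
    stop("unknown ROI shape: ", x$shape, call. = FALSE)
  }
}
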