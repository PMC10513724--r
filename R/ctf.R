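#' Contrast transfer function of a resolution-element region
#'
#' Computes `CTF(%) = 100 * (max(r) - min(r)) / (max(r) + min(r))` over an
#' element region `r`, where `max(r)` and `min(r)` are the means of the
#' top and bottom 20% of the region's pixel values (not single extrema).
#' The 20% counts are by value rank with stable ordering; fractional
#' counts round up, with at least one pixel on each side.
#'
#' A target-extent mask is formed from pixels at or above
#' `background_threshold` times the image maximum; it localizes and
#' validates the target (the covered fraction of the ROI is recorded) but
#' does not remove pixels from the percentile statistics, since dark bars
#' legitimately fall below the threshold.
#'
#' An all-dark region (`max + min = 0`) yields a degenerate result with
#' `ctf_percent = NA` and `degenerate = TRUE` rather than an error.
#'
#' @param image An [fgs_image].
#' @param roi An ROI covering one bar block of one element.
#' @param background_threshold Fraction of the image maximum used for the
#'   target mask; must lie in `[0.1, 0.4]`.
#' @return An object of class `fgs_ctf` with fields `roi_name`,
#'   `orientation`, `lp_per_mm`, `max_r`, `min_r`, `ctf_percent`,
#'   `threshold_used`, `mask_fraction`, `n_pixels`, `degenerate`.
#' @export
#' @examples
#' img <- fgs_image(matrix(c(0, 1000), 20, 20), bit_depth = 16)
#' compute_ctf(img, roi_rect("e", 0, 0, 20, 20))$ctf_percent # 100
compute_ctf <- function(image, roi, background_threshold = 0.2) {
  assert_image(image)
  if (background_threshold < 0.1 || background_threshold > 0.4) {
    stop("`background_threshold` must lie in [0.1, 0.4]", call. = FALSE)
  }
  v <- roi_values(image, roi)
  thr <- background_threshold * max(image$pixels)
  mask_fraction <- mean(v >= thr)
  k <- max(1L, ceiling(0.2 * length(v)))
  sv <- sort(v)
  min_r <- mean(sv[seq_len(k)])
  max_r <- mean(sv[seq.int(length(sv) - k + 1L, length(sv))])
  degenerate <- (max_r + min_r) == 0
  ctf <- if (degenerate) NA_real_ else 100 * (max_r - min_r) / (max_r + min_r)
  structure(list(roi_name = roi$name,
                 orientation = if (is.null(roi$orientation)) "single"
                               else roi$orientation,
                 lp_per_mm = roi$lp_per_mm, max_r = max_r, min_r = min_r,
                 ctf_percent = ctf, threshold_used = background_threshold,
                 mask_fraction = mask_fraction, n_pixels = length(v),
                 degenerate = degenerate),
            class = "fgs_ctf")
}

#' @export
print.fgs_ctf <- function(x, ...) {
  cat(sprintf("<fgs_ctf> %s [%s]: CTF %.2f%% (max %.1f, min %.1f, thr %.2f)\n",
              x$roi_name, x$orientation,
              if (is.na(x$ctf_percent)) NaN else x$ctf_percent,
              x$max_r, x$min_r, x$threshold_used))
  invisible(x)
}

#' Element-level CTF: horizontal and vertical blocks scored separately
#'
#' Scores the horizontal-bar and vertical-bar regions of one USAF element
#' separately and reports their mean as `orientation = "mean"`.
#'
#' @inheritParams compute_ctf
#' @param roi_h,roi_v ROIs over the element's horizontal and vertical bar
#'   blocks.
#' @return An `fgs_ctf` with `orientation = "mean"` plus the per-orientation
#'   results in `$horizontal` and `$vertical`.
#' @export
ctf_element <- function(image, roi_h, roi_v, background_threshold = 0.2) {
  ch <- compute_ctf(image, roi_h, background_threshold)
  cv <- compute_ctf(image, roi_v, background_threshold)
  degenerate <- ch$degenerate && cv$degenerate
  ctf <- mean(c(ch$ctf_percent, cv$ctf_percent))
  structure(list(roi_name = sub("_[hv]$", "", roi_h$name),
                 orientation = "mean",
                 lp_per_mm = roi_h$lp_per_mm,
                 max_r = mean(c(ch$max_r, cv$max_r)),
                 min_r = mean(c(ch$min_r, cv$min_r)),
                 ctf_percent = ctf,
                 threshold_used = background_threshold,
                 mask_fraction = mean(c(ch$mask_fraction, cv$mask_fraction)),
                 n_pixels = ch$n_pixels + cv$n_pixels,
                 degenerate = degenerate,
                 horizontal = ch, vertical = cv),
            class = "fgs_ctf")
}

#' Sharpness curve over a set of USAF elements
#'
#' Scores every element present in the layout (ROIs tagged with
#' `lp_per_mm` and `orientation`), ordered by spatial frequency, and
#' summarizes the resolving limit: the highest lp/mm whose mean-orientation
#' CTF still reaches `criterion_percent`.
#'
#' @inheritParams compute_ctf
#' @param layout An `fgs_layout` whose ROIs carry `lp_per_mm` and
#'   `orientation` (as produced by [render_usaf()]).
#' @param criterion_percent Resolving-limit CTF criterion (default 40).
#' @param expected_lp_per_mm Optional vector of element frequencies that
#'   must be present; a missing element is an error naming it.
#' @return An object of class `fgs_sharpness`: a list with `table`
#'   (data frame of `lp_per_mm`, `ctf_h`, `ctf_v`, `ctf_mean`),
#'   `resolving_limit_lp_per_mm` (NA when no element meets the criterion),
#'   `criterion_percent`, `threshold_used`, and per-element results.
#' @export
sharpness_curve <- function(image, layout, criterion_percent = 40,
                            background_threshold = 0.2,
                            expected_lp_per_mm = NULL) {
  stopifnot(inherits(layout, "fgs_layout"))
  rois <- Filter(function(r) !is.null(r$lp_per_mm), layout$rois)
  if (length(rois) == 0L) stop("layout has no USAF element ROIs",
                               call. = FALSE)
  lp <- vapply(rois, `[[`, 0, "lp_per_mm")
  lps <- sort(unique(lp))
  if (!is.null(expected_lp_per_mm)) {
    missing <- setdiff(round(expected_lp_per_mm, 6), round(lps, 6))
    if (length(missing) > 0L) {
      stop("layout is missing element ROIs for lp/mm: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  results <- lapply(lps, function(f) {
    sub <- rois[abs(lp - f) < 1e-9]
    ori <- vapply(sub, `[[`, "", "orientation")
    h <- sub[ori == "horizontal"]
    v <- sub[ori == "vertical"]
    if (length(h) != 1L || length(v) != 1L) {
      stop(sprintf(
        "element at %.4g lp/mm needs one horizontal and one vertical ROI", f),
        call. = FALSE)
    }
    ctf_element(image, h[[1]], v[[1]], background_threshold)
  })
  tab <- data.frame(
    lp_per_mm = lps,
    ctf_h = vapply(results, function(r) r$horizontal$ctf_percent, 0),
    ctf_v = vapply(results, function(r) r$vertical$ctf_percent, 0),
    ctf_mean = vapply(results, `[[`, 0, "ctf_percent"))
  ok <- !is.na(tab$ctf_mean) & tab$ctf_mean >= criterion_percent
  limit <- if (any(ok)) max(tab$lp_per_mm[ok]) else NA_real_
  structure(list(table = tab, resolving_limit_lp_per_mm = limit,
                 criterion_percent = criterion_percent,
                 threshold_used = background_threshold, elements = results),
            class = "fgs_sharpness")
}

#' @export
print.fgs_sharpness <- function(x, ...) {
  cat("<fgs_sharpness>\n")
  print(transform(x$table, ctf_h = round(ctf_h, 2), ctf_v = round(ctf_v, 2),
                  ctf_mean = round(ctf_mean, 2)), row.names = FALSE)
  cat(sprintf("resolving limit (CTF >= %g%%): %s lp/mm\n",
              x$criterion_percent,
              if (is.na(x$resolving_limit_lp_per_mm)) "none"
              else format(x$resolving_limit_lp_per_mm, digits = 4)))
  invisible(x)
}

#' Depth-of-field curve from a defocus image stack
#'
#' Scores the 1.0 lp/mm element (horizontal and vertical blocks
#' separately, then their mean) in every frame of a `(z_cm, image)` stack
#' and reports the in-focus range: the widest contiguous interval of
#' sampled z with CTF at or above `threshold_percent`, ties broken toward
#' the interval containing the plane of focus `z = 0`. Negative z is
#' closer to the lens. When no frame reaches the threshold the range is
#' empty (`NULL`) and flagged, not an error.
#'
#' @param stack A list of `list(z_cm =, image =)` entries; z values must
#'   be unique and include 0.
#' @param roi_h,roi_v ROIs over the element's bar blocks, valid in every
#'   frame.
#' @param threshold_percent In-focus CTF criterion (default 60).
#' @inheritParams compute_ctf
#' @return An object of class `fgs_dof`: `table` (data frame `z_cm`,
#'   `ctf_percent`), `in_focus_range_cm` (`c(lo, hi)` or `NULL`),
#'   `threshold_percent`.
#' @export
dof_curve <- function(stack, roi_h, roi_v, threshold_percent = 60,
                      background_threshold = 0.2) {
  z <- vapply(stack, `[[`, 0, "z_cm")
  if (anyDuplicated(z)) stop("z values must be unique", call. = FALSE)
  if (!any(z == 0)) stop("the stack must include the plane of focus z = 0",
                         call. = FALSE)
  o <- order(z)
  z <- z[o]
  ctf <- vapply(stack[o], function(fr) {
    ctf_element(fr$image, roi_h, roi_v, background_threshold)$ctf_percent
  }, 0)
  ok <- !is.na(ctf) & ctf >= threshold_percent
  range_cm <- widest_run(z, ok)
  structure(list(table = data.frame(z_cm = z, ctf_percent = ctf),
                 in_focus_range_cm = range_cm,
                 threshold_percent = threshold_percent,
                 threshold_used = background_threshold),
            class = "fgs_dof")
}

# widest contiguous TRUE run over sorted z; ties favor the run holding z = 0
widest_run <- function(z, ok) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  width <- z[ends[runs]] - z[starts[runs]]
  has0 <- vapply(runs, function(i) {
    any(z[starts[i]:ends[i]] == 0)
  }, TRUE)
  best <- runs[order(-width, !has0)][1]
  c(z[starts[best]], z[ends[best]])
}

#' @export
print.fgs_dof <- function(x, ...) {
  cat("<fgs_dof>\n")
  print(transform(x$table, ctf_percent = round(ctf_percent, 2)),
        row.names = FALSE)
  if (is.null(x$in_focus_range_cm)) {
    cat(sprintf("no z reaches the %g%% criterion\n", x$threshold_percent))
  } else {
    cat(sprintf("in-focus range (CTF >= %g%%): [%g, %g] cm\n",
                x$threshold_percent, x$in_focus_range_cm[1],
                x$in_focus_range_cm[2]))
  }
  invisible(x)
}
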