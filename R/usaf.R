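#' USAF-1951 element arithmetic
#'
#' An USAF-1951 resolution target element at `(group, element)` has
#' spatial frequency `lp_per_mm = 2^(group + (element - 1) / 6)` line
#' pairs per millimetre and single-line width
#' `1000 / (2 * lp_per_mm)` micrometres (one line pair = one bright +
#' one dark bar). Group 0 element 1 is 1.0 lp/mm (500 um/line); group 7
#' element 6 is 228.07 lp/mm (2.19 um/line). Values are held at full
#' precision; round only for display.
#'
#' @param group Integer group number (may be negative).
#' @param element Element number in 1..6.
#' @return An object of class `usaf_element` with fields `group`,
#'   `element`, `lp_per_mm`, `line_width_um`.
#' @export
#' @examples
#' usaf_element(0, 1)$line_width_um # 500
#' round(usaf_element(7, 6)$lp_per_mm, 1) # 228.1
usaf_element <- function(group, element) {
  stopifnot(length(group) == 1L, length(element) == 1L)
  if (group != round(group) || element != round(element)) {
    stop("`group` and `element` must be integers", call. = FALSE)
  }
  element <- as.integer(element)
  if (element < 1L || element > 6L) {
    stop("`element` must be in 1..6", call. = FALSE)
  }
  lp <- 2^(group + (element - 1) / 6)
  structure(list(group = as.integer(group), element = element,
                 lp_per_mm = lp, line_width_um = 1000 / (2 * lp)),
            class = "usaf_element")
}

#' @export
print.usaf_element <- function(x, ...) {
  cat(sprintf("<usaf_element> group %d element %d: %.4g lp/mm, %.4g um/line\n",
              x$group, x$element, x$lp_per_mm, x$line_width_um))
  invisible(x)
}
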