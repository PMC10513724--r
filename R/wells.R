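#' Quantify a well-plate phantom panel
#'
#' Computes per-well mean and standard deviation over each circular well
#' disk, then normalizes means and sds to the maximum well mean of the
#' panel. The QD800 well (a visible-light control, not an ICG signal) is
#' reported but excluded from the normalization of the ICG series. A
#' panel must contain exactly one control well (role `"control"`).
#'
#' Statistics are taken over a disk inset by `edge_margin_px` from the
#' declared well radius, the usual plate-assay guard against
#' partial-volume pixels at the well rim (optics blur mixes rim pixels
#' with the surrounding background); the declared radius itself remains
#' the geometric well boundary used by [compute_sbr()].
#'
#' @param image An [fgs_image].
#' @param layout An `fgs_layout` whose circular ROIs carry `label`
#'   (concentration in nM, depth in mm, or `"control"`/`"qd800"`) and
#'   `role` (`"sample"`, `"control"`, `"qd800"`).
#' @param edge_margin_px Rim exclusion margin in pixels (default 3; the
#'   analysis radius never drops below 2 px).
#' @return An object of class `fgs_well_panel`: `wells` (data frame with
#'   `name`, `label`, `role`, `mean`, `sd`, `mean_norm`, `sd_norm`),
#'   `noise_floor` (control-well mean and sd), `bit_depth`, and slots
#'   filled by [detect_floor_and_saturation()] / [depth_response()].
#' @export
quantify_wells <- function(image, layout, edge_margin_px = 3) {
  assert_image(image)
  stopifnot(inherits(layout, "fgs_layout"))
  rois <- Filter(function(r) r$shape == "circle" && !is.null(r$role),
                 layout$rois)
  if (length(rois) < 2L) stop("layout has fewer than 2 well ROIs",
                              call. = FALSE)
  assert_disjoint_wells(rois)
  roles <- vapply(rois, `[[`, "", "role")
  if (sum(roles == "control") != 1L) {
    stop("panel must contain exactly one control well", call. = FALSE)
  }
  stats_ <- lapply(rois, function(r) {
    g <- r$geom
    inner <- roi_circle(r$name, g[["center_row"]], g[["center_col"]],
                        max(2, g[["radius_px"]] - edge_margin_px))
    v <- roi_values(image, inner)
    c(mean = mean(v), sd = stats::sd(v))
  })
  wells <- data.frame(
    name = vapply(rois, `[[`, "", "name"),
    label = vapply(rois, function(r) r$label %||% r$name, ""),
    role = roles,
    mean = vapply(stats_, `[[`, 0, "mean"),
    sd = vapply(stats_, `[[`, 0, "sd"),
    row.names = NULL)
  norm_base <- max(wells$mean[wells$role != "qd800"])
  if (norm_base <= 0) norm_base <- 1
  wells$mean_norm <- wells$mean / norm_base
  wells$sd_norm <- wells$sd / norm_base
  ctrl <- wells[wells$role == "control", ]
  structure(list(wells = wells,
                 noise_floor = list(mean = ctrl$mean, sd = ctrl$sd),
                 edge_margin_px = edge_margin_px,
                 bit_depth = image$bit_depth,
                 lod_label = NULL, saturated_labels = NULL,
                 max_reliable_depth_mm = NULL),
            class = "fgs_well_panel")
}

assert_disjoint_wells <- function(rois) {
  n <- length(rois)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      gi <- rois[[i]]$geom
      gj <- rois[[j]]$geom
      dd <- sqrt((gi[["center_row"]] - gj[["center_row"]])^2 +
                 (gi[["center_col"]] - gj[["center_col"]])^2)
      if (dd < gi[["radius_px"]] + gj[["radius_px"]]) {
        stop(sprintf("wells '%s' and '%s' overlap", rois[[i]]$name,
                     rois[[j]]$name), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fgs_well_panel <- function(x, ...) {
  cat("<fgs_well_panel>\n")
  print(transform(x$wells, mean = round(mean, 1), sd = round(sd, 2),
                  mean_norm = round(mean_norm, 4),
                  sd_norm = round(sd_norm, 4)), row.names = FALSE)
  if (!is.null(x$lod_label)) cat("LoD:", x$lod_label, "nM\n")
  if (!is.null(x$saturated_labels) && length(x$saturated_labels)) {
    cat("saturated:", paste(x$saturated_labels, collapse = ", "), "\n")
  }
  if (!is.null(x$max_reliable_depth_mm)) {
    cat("max reliable depth:", x$max_reliable_depth_mm, "mm\n")
  }
  invisible(x)
}

#' Noise floor, limit of detection, and saturation of a concentration panel
#'
#' The limit of detection (LoD) is the lowest concentration whose well
#' mean exceeds `control_mean + k_sigma * control_sd` (the conventional
#' 3-sigma rule by default). Saturation is flagged from the top of the
#' concentration series downward: the highest well is saturated when its
#' raw mean reaches `sat_frac` of full scale, and each next-lower well is
#' saturated when the well above it is and their means differ by less
#' than 1% of full scale (the plateau criterion applies only to the
#' plateau connected to the top, so small spacings at the dim end of the
#' series are not mistaken for saturation).
#'
#' @param panel An `fgs_well_panel` from [quantify_wells()] whose sample
#'   labels are concentrations in nM.
#' @param k_sigma Detection criterion in control-well sigmas (default 3).
#' @param sat_frac Fraction of full scale treated as pegged (default 0.99).
#' @return The panel with `lod_label` (NA when undetermined, flagged),
#'   `saturated_labels`, and the criteria recorded.
#' @export
detect_floor_and_saturation <- function(panel, k_sigma = 3,
                                        sat_frac = 0.99) {
  stopifnot(inherits(panel, "fgs_well_panel"))
  w <- panel$wells[panel$wells$role == "sample", ]
  conc <- suppressWarnings(as.numeric(w$label))
  if (anyNA(conc)) stop("sample labels are not concentrations", call. = FALSE)
  if (nrow(w) < 2L) stop("need at least 2 concentration wells",
                         call. = FALSE)
  o <- order(conc)
  w <- w[o, ]; conc <- conc[o]
  criterion <- panel$noise_floor$mean + k_sigma * panel$noise_floor$sd
  detectable <- w$mean > criterion
  lod <- if (any(detectable)) w$label[which(detectable)[1]] else NA_character_
  if (panel$noise_floor$sd == 0 && all(w$mean == panel$noise_floor$mean)) {
    lod <- NA_character_
  }
  fs <- 2^panel$bit_depth - 1
  sat <- logical(nrow(w))
  for (i in rev(seq_len(nrow(w)))) { # descend from the top concentration
    pegged <- w$mean[i] >= sat_frac * fs
    plateau <- i < nrow(w) && sat[i + 1L] &&
      abs(w$mean[i + 1L] - w$mean[i]) < 0.01 * fs
    sat[i] <- pegged || plateau
  }
  panel$lod_label <- lod
  panel$saturated_labels <- w$label[sat]
  panel$criteria <- list(k_sigma = k_sigma, sat_frac = sat_frac,
                         detection_threshold = criterion)
  panel
}

#' Imaging-depth summary of a depth panel
#'
#' Reports the deepest well whose mean still exceeds
#' `control_mean + k_sigma * control_sd`, plus an optional attenuation
#' fit: a log-linear regression of `mean - floor` against depth over the
#' detectable, non-saturated wells, whose negative inverse slope is the
#' attenuation length `d_att` in mm. The fit is skipped (and flagged)
#' with fewer than 3 usable wells.
#'
#' @param panel An `fgs_well_panel` whose sample labels are depths in mm.
#' @param k_sigma Detection criterion in control-well sigmas.
#' @param sat_frac Fraction of full scale treated as saturated and
#'   excluded from the fit.
#' @return The panel with `max_reliable_depth_mm` (NA when no depth is
#'   detectable) and `attenuation_fit` (list with `d_att_mm`, `i0_dn`,
#'   `n_wells`, or `NULL` with `fit_skipped_reason`).
#' @export
depth_response <- function(panel, k_sigma = 3, sat_frac = 0.99) {
  stopifnot(inherits(panel, "fgs_well_panel"))
  w <- panel$wells[panel$wells$role == "sample", ]
  depth <- suppressWarnings(as.numeric(w$label))
  if (anyNA(depth)) stop("sample labels are not depths", call. = FALSE)
  o <- order(depth)
  w <- w[o, ]; depth <- depth[o]
  floor_mean <- panel$noise_floor$mean
  criterion <- floor_mean + k_sigma * panel$noise_floor$sd
  detectable <- w$mean > criterion
  panel$max_reliable_depth_mm <- if (any(detectable)) {
    max(depth[detectable])
  } else NA_real_
  fs <- 2^panel$bit_depth - 1
  usable <- detectable & w$mean < sat_frac * fs & (w$mean - floor_mean) > 0
  if (sum(usable) >= 3L) {
    fit <- stats::lm(log(w$mean[usable] - floor_mean) ~ depth[usable])
    slope <- unname(stats::coef(fit)[2])
    panel$attenuation_fit <- list(
      d_att_mm = -1 / slope,
      i0_dn = exp(unname(stats::coef(fit)[1])),
      n_wells = sum(usable))
  } else {
    panel$attenuation_fit <- NULL
    panel$fit_skipped_reason <- sprintf(
      "only %d detectable non-saturated wells (need >= 3)", sum(usable))
  }
  panel$criteria <- list(k_sigma = k_sigma, sat_frac = sat_frac,
                         detection_threshold = criterion)
  panel
}

#' Signal-to-background ratio of well regions, in dB
#'
#' For each well disk the background is the surrounding annulus from the
#' well radius out to `annulus_factor` times it ("0.5 units more than the
#' well radius" for the default 1.5). Signal and background powers are
#' area-normalized (mean of squared pixel values), so disk and annulus
#' geometry does not leak into the ratio, and
#' `sbr_db = 10 * log10(signal_power / background_power)`. The panel
#' value is the mean over the given wells (conventionally the 2, 3, and
#' 4 mm depth wells). The result is invariant to global intensity
#' scaling.
#'
#' @param image An [fgs_image].
#' @param wells A list of circular ROIs (typically 3).
#' @param annulus_factor Outer radius as a multiple of the well radius.
#' @param avoid Optional list of additional ROIs (e.g. the full well
#'   layout) that no annulus may intersect.
#' @return An object of class `fgs_sbr`: `table` (per-well `label`,
#'   `signal_power`, `background_power`, `sbr_db`), `panel_sbr_db`,
#'   `annulus_factor`.
#' @export
#' @examples
#' px <- matrix(10, 64, 64)
#' img <- fgs_image(px, bit_depth = 16)
#' w <- roi_circle("w", 31.5, 31.5, 8)
#' compute_sbr(img, list(w))$panel_sbr_db # 0 dB: signal equals background
compute_sbr <- function(image, wells, annulus_factor = 1.5, avoid = NULL) {
  assert_image(image)
  stopifnot(length(wells) >= 1L, annulus_factor > 1)
  d <- dim(image$pixels)
  others <- c(wells, avoid %||% list())
  rows <- lapply(wells, function(w) {
    g <- w$geom
    r <- g[["radius_px"]]
    outer_r <- annulus_factor * r
    validate_roi(roi_circle(w$name, g[["center_row"]], g[["center_col"]],
                            outer_r), image)
    dist2 <- outer((seq_len(d[1]) - 1 - g[["center_row"]])^2,
                   (seq_len(d[2]) - 1 - g[["center_col"]])^2, `+`)
    disk <- dist2 <= r^2
    annulus <- dist2 > r^2 & dist2 <= outer_r^2
    for (o in others) {
      if (identical(o$name, w$name) || o$shape != "circle") next
      go <- o$geom
      cd <- sqrt((go[["center_row"]] - g[["center_row"]])^2 +
                 (go[["center_col"]] - g[["center_col"]])^2)
      if (cd < outer_r + go[["radius_px"]]) {
        stop(sprintf(
          "annulus of '%s' overlaps well '%s'; use a smaller annulus_factor",
          w$name, o$name), call. = FALSE)
      }
    }
    if (sum(annulus) < sum(disk) / 4) {
      stop("annulus too small relative to the well disk", call. = FALSE)
    }
    sig <- mean(image$pixels[disk]^2)
    bg <- mean(image$pixels[annulus]^2)
    if (bg <= 0) stop("background power is zero in the annulus of '",
                      w$name, "'", call. = FALSE)
    data.frame(label = w$label %||% w$name, signal_power = sig,
               background_power = bg, sbr_db = 10 * log10(sig / bg))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, panel_sbr_db = mean(tab$sbr_db),
                 annulus_factor = annulus_factor),
            class = "fgs_sbr")
}

#' @export
print.fgs_sbr <- function(x, ...) {
  cat("<fgs_sbr>\n")
  print(transform(x$table, signal_power = signif(signal_power, 5),
                  background_power = signif(background_power, 5),
                  sbr_db = round(sbr_db, 2)), row.names = FALSE)
  cat(sprintf("panel SBR: %.2f dB (annulus factor %g)\n", x$panel_sbr_db,
              x$annulus_factor))
  invisible(x)
}
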