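#' Run the nine-test characterization protocol
#'
#' Executes the configured subset of the nine system tests in protocol
#' order -- (1) excitation band, (2) illumination power density (recorded
#' as metadata, not measured), (3) spatial resolution and sharpness,
#' (4) FOV uniformity, (5) spatial distortion, (6) depth of field,
#' (7) concentration sensitivity, (8) imaging depth, (9) signal to
#' background ratio -- over one system's input files. Tests are
#' independent stages: a failure in one is recorded and does not abort
#' the others, and no cross-test correction (e.g. flat-fielding) is
#' applied. Absent tests are explicitly marked skipped, never silently
#' omitted.
#'
#' The configuration is a YAML file with `system` metadata, optional
#' `params` overriding decision parameters (`background_threshold`,
#' `k_sigma`, `sat_frac`, `annulus_factor`, `ctf_criterion_percent`,
#' `dof_threshold_percent`, `band_half_width_px`), and a `tests` mapping
#' naming the input files per test (see [synth_protocol()] for a complete
#' generated example). Relative paths resolve against the config's
#' directory. Every report carries the parameters each result was
#' computed with and MD5 hashes of the config and inputs.
#'
#' @param config Path to a YAML configuration.
#' @return An object of class `fgs_report`.
#' @export
run_protocol <- function(config) {
  if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
  cfg <- yaml::read_yaml(config)
  if (!is.list(cfg) || is.null(cfg$tests)) {
    stop("malformed config: no `tests` mapping", call. = FALSE)
  }
  base_dir <- dirname(normalizePath(config))
  params <- utils::modifyList(
    list(background_threshold = 0.2, k_sigma = 3, sat_frac = 0.99,
         annulus_factor = 1.5, ctf_criterion_percent = 40,
         dof_threshold_percent = 60, band_half_width_px = 50),
    cfg$params %||% list())
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  input_hashes <- character(0)
  note_input <- function(p) {
    if (!is.null(p) && file.exists(p)) {
      input_hashes[[p]] <<- unname(tools::md5sum(p))
    }
    p
  }
  load_cfg_image <- function(tc) {
    lay <- NULL
    if (!is.null(tc$layout)) lay <- load_layout(note_input(resolve(tc$layout)))
    depth_override <- tc$bit_depth %||% lay$meta$bit_depth
    img <- load_image(note_input(resolve(tc$image)),
                      bit_depth = depth_override)
    list(image = img, layout = lay)
  }
  stage <- function(name, fun) {
    tc <- cfg$tests[[name]]
    if (is.null(tc)) {
      return(list(status = "skipped", reason = "not configured"))
    }
    tryCatch(list(status = "ok", result = fun(tc)),
             error = function(e) list(status = "failed",
                                      reason = conditionMessage(e)))
  }
  tests <- list(
    excitation_band = stage("excitation_band", function(tc) {
      compute_fwhm(load_spectrum(note_input(resolve(tc$trace))))
    }),
    power_density = stage("power_density", function(tc) {
      list(value_mw_cm2 = tc$value_mw_cm2,
           note = "recorded from configuration; not measured from images")
    }),
    resolution = stage("resolution", function(tc) {
      x <- load_cfg_image(tc)
      sharpness_curve(x$image, x$layout,
                      criterion_percent = params$ctf_criterion_percent,
                      background_threshold = params$background_threshold)
    }),
    uniformity = stage("uniformity", function(tc) {
      x <- load_cfg_image(tc)
      img <- x$image
      if (!is.null(tc$masks) && !is.null(x$layout)) {
        img <- masked_region_zeroing(img, x$layout$rois[unlist(tc$masks)])
      }
      uniformity_profile(img,
                         band_half_width_px = params$band_half_width_px)
    }),
    distortion = stage("distortion", function(tc) {
      x <- load_cfg_image(tc)
      dot_distances(x$image)
    }),
    dof = stage("dof", function(tc) {
      man <- utils::read.csv(note_input(resolve(tc$manifest)))
      lay <- load_layout(note_input(resolve(tc$layout)))
      rois <- Filter(function(r) !is.null(r$lp_per_mm), lay$rois)
      lp <- vapply(rois, `[[`, 0, "lp_per_mm")
      sel <- rois[abs(lp - min(lp)) < 1e-9]
      ori <- vapply(sel, `[[`, "", "orientation")
      stack <- lapply(seq_len(nrow(man)), function(i) {
        list(z_cm = man$z_cm[i],
             image = load_image(note_input(resolve(man$path[i])),
                                bit_depth = lay$meta$bit_depth))
      })
      dof_curve(stack, sel[ori == "horizontal"][[1]],
                sel[ori == "vertical"][[1]],
                threshold_percent = params$dof_threshold_percent,
                background_threshold = params$background_threshold)
    }),
    sensitivity = stage("sensitivity", function(tc) {
      x <- load_cfg_image(tc)
      detect_floor_and_saturation(quantify_wells(x$image, x$layout),
                                  k_sigma = params$k_sigma,
                                  sat_frac = params$sat_frac)
    }),
    depth = stage("depth", function(tc) {
      x <- load_cfg_image(tc)
      depth_response(quantify_wells(x$image, x$layout),
                     k_sigma = params$k_sigma, sat_frac = params$sat_frac)
    }),
    sbr = stage("sbr", function(tc) {
      x <- load_cfg_image(tc)
      labels <- as.character(unlist(tc$well_labels %||% c("2", "3", "4")))
      wl <- vapply(x$layout$rois, function(r) r$label %||% "", "")
      wells <- x$layout$rois[wl %in% labels]
      if (length(wells) == 0L) stop("no wells matching labels ",
                                    paste(labels, collapse = ", "))
      compute_sbr(x$image, unname(wells),
                  annulus_factor = params$annulus_factor,
                  avoid = unname(x$layout$rois))
    }))
  structure(list(
    schema_version = 1L,
    system = cfg$system %||% list(),
    params = params,
    tests = tests,
    provenance = list(
      tool = "fgsqc",
      tool_version = as.character(utils::packageVersion("fgsqc")),
      config = config,
      config_md5 = unname(tools::md5sum(config)),
      input_md5 = as.list(input_hashes))),
    class = "fgs_report")
}

#' @export
print.fgs_report <- function(x, ...) {
  cat(sprintf("<fgs_report> %s (schema v%d)\n",
              x$system$system_id %||% "unnamed system", x$schema_version))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-16s %s%s\n", nm, t$status,
                if (t$status != "ok") paste0(" (", t$reason, ")") else ""))
  }
  invisible(x)
}

#' Serialize a report to JSON and a CSV summary
#'
#' The JSON is a lossless, versioned rendering of the report (apart from
#' an ISO timestamp); the CSV mirrors a system-summary table: one row of
#' identifying metadata and headline metrics per report.
#'
#' @param report An `fgs_report`.
#' @param dir Output directory.
#' @param stem File stem (default `"report"`).
#' @param timestamp Logical; write a generation timestamp into the JSON.
#'   Disable for byte-reproducible output.
#' @return Named list of the written paths, invisibly.
#' @export
write_report <- function(report, dir, stem = "report", timestamp = TRUE) {
  stopifnot(inherits(report, "fgs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- report_to_list(report)
  if (timestamp) out$provenance$generated <- format(Sys.time(), tz = "UTC")
  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- file.path(dir, paste0(stem, "_summary.csv"))
  utils::write.csv(report_summary_row(report), csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}

#' Read back a serialized report
#'
#' @param path A `report.json` written by [write_report()].
#' @return An `fgs_report`-like list (classes of nested results are not
#'   restored; the summary fields used by [compare_reports()] are).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version)) {
    stop("not an fgsqc report: missing schema_version", call. = FALSE)
  }
  structure(x, class = "fgs_report")
}

report_metric <- function(report, test, path) {
  t <- report$tests[[test]]
  if (is.null(t) || !identical(t$status, "ok")) return(NA)
  out <- t$result
  for (p in path) {
    out <- out[[p]]
    if (is.null(out)) return(NA)
  }
  out
}

report_summary_row <- function(report) {
  num <- function(x) if (is.null(x) || length(x) == 0L || all(is.na(x)))
    NA_real_ else as.numeric(x)[1]
  sat <- report_metric(report, "sensitivity", "saturated_labels")
  sat_onset <- if (all(is.na(sat)) || length(sat) == 0L) NA_real_ else {
    suppressWarnings(min(as.numeric(sat)))
  }
  rng <- report_metric(report, "dof", "in_focus_range_cm")
  data.frame(
    system_id = report$system$system_id %||% NA_character_,
    reported_peak_nm = num(report$system$reported_peak_nm),
    working_distance_cm = num(report$system$working_distance_cm),
    power_density_mw_cm2 = num(report_metric(report, "power_density",
                                             "value_mw_cm2")),
    peak_nm = num(report_metric(report, "excitation_band", "peak_nm")),
    fwhm_nm = num(report_metric(report, "excitation_band", "fwhm_nm")),
    resolving_limit_lp_per_mm = num(report_metric(
      report, "resolution", "resolving_limit_lp_per_mm")),
    uniformity_min = num(report_metric(report, "uniformity",
                                       c("summary", "min_profile"))),
    uniformity_frac_ge_090 = num(report_metric(
      report, "uniformity", c("summary", "frac_ge_090"))),
    distortion_index = num(report_metric(report, "distortion",
                                         "distortion_index")),
    dof_low_cm = if (all(is.na(rng))) NA_real_ else num(rng[1]),
    dof_high_cm = if (all(is.na(rng)) || length(rng) < 2L) NA_real_
                  else as.numeric(rng[2]),
    lod_nm = suppressWarnings(num(as.numeric(
      report_metric(report, "sensitivity", "lod_label")))),
    saturation_onset_nm = sat_onset,
    max_reliable_depth_mm = num(report_metric(report, "depth",
                                              "max_reliable_depth_mm")),
    panel_sbr_db = num(report_metric(report, "sbr", "panel_sbr_db")),
    stringsAsFactors = FALSE)
}

#' Side-by-side comparison of system reports
#'
#' Builds a comparison table of the headline metrics (FWHM, resolving
#' limit, uniformity minimum, distortion index, in-focus range, LoD,
#' saturation onset, max reliable depth, panel SBR) across two or more
#' reports. Skipped or failed tests appear as `NA`. Reports produced by
#' different tool versions are compared but flagged.
#'
#' @param reports A list of `fgs_report` objects (length >= 2, or 1 for
#'   a self-comparison).
#' @return A data frame, one row per report, with an attribute
#'   `version_mismatch` when tool versions differ.
#' @export
compare_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  schemas <- vapply(reports, function(r) as.integer(r$schema_version), 0L)
  if (length(unique(schemas)) > 1L) {
    stop("incompatible report schema versions: ",
         paste(unique(schemas), collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, lapply(reports, report_summary_row))
  versions <- vapply(reports, function(r)
    r$provenance$tool_version %||% NA_character_, "")
  attr(tab, "version_mismatch") <- length(unique(versions)) > 1L
  tab
}
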