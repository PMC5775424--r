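#' Field analysis configuration
#'
#' Builds (and validates) the configuration driving [run_field_analysis()].
#' A configuration can also be read from a YAML file with
#' [read_run_config()]; [write_run_config()] serializes it next to the
#' outputs so every run is reproducible from its archived config.
#'
#' @param cyan_path,red_path Paths to the cyan/red channel rasters
#'   (TIFF/PNG) of the field.
#' @param probe_movie_path,red_movie_path Optional multi-page TIFFs holding
#'   the pH-probe movie and the matching red-channel movie (for per-frame
#'   Otsu osteoclast masks); both are required for the BRI time course.
#' @param pixel_size_um Pixel edge, um.
#' @param scale CMI downscale factor (default 1/4).
#' @param method CMI method, `"approx"` or `"exact"`.
#' @param min_area_cyan_um2,min_area_red_um2 Debris gates, um^2.
#' @param frame_interval_min BRI sampling step, minutes.
#' @param window_min BRI averaging window, minutes (default 240 = 4 h).
#' @param bri Set `TRUE` to require the BRI statistics (errors if the probe
#'   movie is missing rather than silently skipping).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param seed Seed recorded for provenance.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cyan_path = NULL, red_path = NULL,
                       probe_movie_path = NULL, red_movie_path = NULL,
                       pixel_size_um = 1, scale = 1 / 4,
                       method = c("approx", "exact"),
                       min_area_cyan_um2 = 5, min_area_red_um2 = 10,
                       frame_interval_min = 5, window_min = 240,
                       bri = FALSE, out_dir = NULL, seed = 1L) {
  method <- match.arg(method)
  cfg <- as.list(environment())
  if (is.null(cfg$cyan_path) || is.null(cfg$red_path)) {
    abort("a field needs both `cyan_path` and `red_path`")
  }
  if (isTRUE(cfg$bri) && is.null(cfg$probe_movie_path)) {
    abort("BRI requested but the probe channel is missing: set `probe_movie_path`")
  }
  if (isTRUE(cfg$bri) && is.null(cfg$red_movie_path)) {
    abort("BRI requested but the red movie is missing: set `red_movie_path`")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Analyze one imaging field end to end
#'
#' Runs the cell mixture pipeline on the field's cyan/red rasters and, when
#' a probe movie is configured, the BRI time course with per-frame Otsu
#' osteoclast masks and the windowed 4-hour mean. Every automatically chosen
#' threshold is reported in the result, and all artifacts (field report
#' JSON, GLI curve CSV, BRI series CSV, archived config) are written to
#' `out_dir` when set.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return A one-row tibble (`"field_report"`): `cmi`, `method`, `n_pixels`,
#'   `area_cyan_um2`, `area_red_um2`, `threshold_cyan`, `threshold_red`,
#'   `mean_bri_4h`, `n_bri_frames`.
#' @export
run_field_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cyan <- read_channel_image(config$cyan_path, "cyan", config$pixel_size_um)
  red <- read_channel_image(config$red_path, "red", config$pixel_size_um)
  cmi_res <- compute_cmi(cyan, red, scale = config$scale,
                         method = config$method,
                         min_area_cyan_um2 = config$min_area_cyan_um2,
                         min_area_red_um2 = config$min_area_red_um2)
  series <- NULL
  if (!is.null(config$probe_movie_path)) {
    if (is.null(config$red_movie_path)) {
      abort("probe movie configured without a red movie: osteoclast masks unavailable")
    }
    probes <- read_stack(config$probe_movie_path, "probe", config$pixel_size_um)
    reds <- read_stack(config$red_movie_path, "red", config$pixel_size_um)
    if (length(probes) != length(reds)) {
      abort("probe and red movies differ in frame count")
    }
    frames <- purrr::map2(probes, reds, function(p, r) list(probe = p, red = r))
    series <- bri_series(frames, config$frame_interval_min)
  } else if (isTRUE(config$bri)) {
    abort("BRI requested but the probe channel is missing: set `probe_movie_path`")
  }
  report <- tibble(
    cmi = cmi_res$cmi, method = cmi_res$method, n_pixels = cmi_res$N,
    area_cyan_um2 = cmi_res$areas$cyan, area_red_um2 = cmi_res$areas$red,
    threshold_cyan = cmi_res$thresholds$cyan,
    threshold_red = cmi_res$thresholds$red,
    mean_bri_4h = if (is.null(series)) NA_real_ else
      window_mean_bri(series, config$window_min),
    n_bri_frames = if (is.null(series)) 0L else nrow(series)
  )
  class(report) <- c("field_report", class(report))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tidy(cmi_res), file.path(config$out_dir, "gli_curve.csv"),
                     row.names = FALSE)
    if (!is.null(series)) {
      utils::write.csv(as.data.frame(series),
                       file.path(config$out_dir, "bri_series.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(as.list(report),
                         file.path(config$out_dir, "field_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
  }
  report
}

#' Per-field statistics of a synthetic cohort
#'
#' Applies the CMI pipeline to each field's two-channel scene and the
#' BRI pipeline (per-frame Otsu masks, windowed mean) to its probe movie.
#'
#' @param cohort Output of [generate_cohort()].
#' @param scale,method Passed to [compute_cmi()].
#' @param frame_interval_min,window_min Passed to the BRI pipeline.
#' @return A tibble with one row per field: `field`, `theta`, `cmi`,
#'   `mean_bri_4h`.
#' @export
analyze_cohort <- function(cohort, scale = 1 / 4, method = "approx",
                           frame_interval_min = 5, window_min = 240) {
  purrr::map_dfr(seq_along(cohort$fields), function(f) {
    fld <- cohort$fields[[f]]
    cmi <- compute_cmi(fld$cmi_scene$cyan, fld$cmi_scene$red,
                       scale = scale, method = method)
    series <- bri_series(fld$bri_frames, frame_interval_min)
    tibble(field = f, theta = fld$theta, cmi = cmi$cmi,
           mean_bri_4h = window_mean_bri(series, window_min))
  })
}

#' Spearman correlation between CMI and mean BRI across fields
#'
#' Two-tailed Spearman rank correlation of per-field (CMI, windowed-mean
#' BRI) pairs — the statistic relating spatial mixing of the two cell types
#' to osteoclast resorbing activity. The p-value uses the exact permutation
#' distribution for `n <= 10` fields and the t approximation otherwise.
#'
#' @param reports A data frame with columns `cmi` and `mean_bri_4h` (e.g.
#'   rows of [run_field_analysis()] or [analyze_cohort()]); at least 5
#'   complete pairs.
#' @return A one-row tibble: `spearman_r`, `p_value`, `n_fields`.
#' @export
correlate_cmi_bri <- function(reports) {
  ok <- stats::complete.cases(reports[, c("cmi", "mean_bri_4h")])
  x <- reports$cmi[ok]
  y <- reports$mean_bri_4h[ok]
  if (length(x) < 5L) {
    abort(sprintf("need at least 5 fields with both statistics, got %d",
                  length(x)))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "two.sided",
             exact = length(x) <= 10L))
  tibble(spearman_r = unname(ct$estimate), p_value = ct$p.value,
         n_fields = length(x))
}
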