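#' Bone Resorbing Index of one frame
#'
#' The BRI is the ratio of the mean pH-probe intensity inside the osteoclast
#' (red-channel) mask to the mean intensity outside it — a signal-to-noise
#' statistic that rises when an osteoclast acidifies the bone surface
#' beneath it. It is scale-free: multiplying the probe image by any positive
#' constant leaves the BRI unchanged.
#'
#' @param probe A [channel_image] of the pH-probe channel.
#' @param moc_mask A [binary_mask] of the osteoclast areas, same shape as
#'   `probe`; must contain at least one foreground and one background pixel.
#' @return A one-row tibble with `signal`, `noise` and `bri = signal/noise`.
#' @export
compute_bri <- function(probe, moc_mask) {
  stopifnot(inherits(probe, "channel_image"), inherits(moc_mask, "binary_mask"))
  if (!identical(dim(probe$pixels), dim(moc_mask$bits))) {
    abort("probe image and osteoclast mask must have identical shape")
  }
  nin <- sum(moc_mask$bits)
  if (nin == 0L || nin == length(moc_mask$bits)) {
    abort(paste0("BRI needs both an inside and an outside region: mask is all-",
                 if (nin == 0L) "background" else "foreground"))
  }
  signal <- mean(probe$pixels[moc_mask$bits])
  noise <- mean(probe$pixels[!moc_mask$bits])
  if (noise <= 0) abort("outside-mask mean intensity is zero: BRI undefined")
  tibble(signal = signal, noise = noise, bri = signal / noise)
}

#' BRI time course of a movie
#'
#' Computes one BRI per frame of a probe/osteoclast movie. Each frame is a
#' list with a `probe` [channel_image] and either a precomputed `mask`
#' ([binary_mask]) or a raw `red` [channel_image], in which case the
#' osteoclast area is extracted automatically with a per-frame Otsu
#' threshold — mirroring the automated binarization used for resorption
#' scoring.
#'
#' @param frames List of frames in time order.
#' @param frame_interval_min Minutes between frames (default 5, the usual
#'   acquisition step).
#' @return A tibble of class `"bri_series"` with columns `t_min`, `signal`,
#'   `noise`, `bri`, one row per frame.
#' @export
bri_series <- function(frames, frame_interval_min = 5) {
  if (length(frames) < 1L) abort("empty movie: no frames to measure")
  rows <- purrr::imap(frames, function(fr, i) {
    mask <- fr$mask
    if (is.null(mask)) {
      if (is.null(fr$red)) {
        abort(sprintf("frame %d: needs either a `mask` or a raw `red` channel", i))
      }
      mask <- binarize(fr$red, otsu_threshold(fr$red))
    }
    res <- tryCatch(compute_bri(fr$probe, mask), error = function(e) {
      abort(sprintf("frame %d: %s", i, conditionMessage(e)))
    })
    dplyr::mutate(res, t_min = (i - 1) * frame_interval_min, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "frame_interval_min") <- frame_interval_min
  class(out) <- c("bri_series", class(out))
  out
}

#' Windowed mean BRI (4h-BRI)
#'
#' Averages all BRI samples with `t` in `[0, window_min]`, both endpoints
#' included; at the default 5-minute sampling a 240-minute window therefore
#' averages 49 samples. The 4-hour mean is the summary used to relate
#' resorbing activity to the spatial mixing of a field.
#'
#' @param series A `"bri_series"`.
#' @param window_min Window length in minutes (default 240).
#' @return The mean BRI over the window, a single number.
#' @export
window_mean_bri <- function(series, window_min = 240) {
  stopifnot(inherits(series, "bri_series"))
  if (max(series$t_min) < window_min) {
    abort(sprintf("series spans %g min, shorter than the %g min window",
                  max(series$t_min), window_min))
  }
  mean(series$bri[series$t_min <= window_min])
}

#' Cell Deformation Index between two time points
#'
#' The CDI is the cell area changed over a short interval (10 minutes by
#' convention) divided by the cell area at the interval start — a motility
#' proxy for osteoclasts. "Changed" defaults to the symmetric difference
#' (pixels lost plus pixels gained), the only convention under which
#' identical shapes give exactly 0; `mode = "gained_only"` counts only newly
#' acquired pixels.
#'
#' @param mask_t0,mask_t1 [binary_mask]s of the cell at the start and end of
#'   the interval, identical shape; `mask_t0` must be non-empty.
#' @param mode `"symmetric"` (default) or `"gained_only"`.
#' @param t0_min,t1_min Optional time stamps (minutes) recorded in the
#'   result.
#' @return A one-row tibble: `t0_min`, `t1_min`, `changed_area_px`,
#'   `total_area_t0_px`, `cdi`.
#' @export
compute_cdi <- function(mask_t0, mask_t1, mode = c("symmetric", "gained_only"),
                        t0_min = 0, t1_min = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask_t0, "binary_mask"), inherits(mask_t1, "binary_mask"))
  if (!identical(dim(mask_t0$bits), dim(mask_t1$bits))) {
    abort("masks must have identical shape")
  }
  total <- sum(mask_t0$bits)
  if (total == 0L) abort("cell mask at t0 is empty: CDI undefined")
  changed <- if (mode == "symmetric") {
    sum(xor(mask_t0$bits, mask_t1$bits))
  } else {
    sum(mask_t1$bits & !mask_t0$bits)
  }
  tibble(t0_min = t0_min, t1_min = t1_min,
         changed_area_px = changed, total_area_t0_px = total,
         cdi = changed / total)
}

#' CDI along a mask sequence
#'
#' Convenience wrapper computing [compute_cdi()] between consecutive frames
#' of a mask sequence.
#'
#' @param masks List of [binary_mask]s in time order (>= 2).
#' @param interval_min Minutes between consecutive masks (default 10).
#' @inheritParams compute_cdi
#' @return A tibble with one row per interval.
#' @export
cdi_series <- function(masks, interval_min = 10,
                       mode = c("symmetric", "gained_only")) {
  mode <- match.arg(mode)
  if (length(masks) < 2L) abort("need at least two masks for a CDI series")
  purrr::map_dfr(seq_len(length(masks) - 1L), function(i) {
    compute_cdi(masks[[i]], masks[[i + 1L]], mode = mode,
                t0_min = (i - 1) * interval_min, t1_min = i * interval_min)
  })
}

#' @export
autoplot.bri_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_min, y = .data$bri)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "bone resorbing index (BRI)") +
    ggplot2::theme_minimal()
}

#' @export
glance.bri_series <- function(x, ...) {
  tibble(
    n_frames = nrow(x),
    frame_interval_min = attr(x, "frame_interval_min"),
    mean_bri = mean(x$bri),
    mean_bri_4h = if (max(x$t_min) >= 240) window_mean_bri(x, 240) else NA_real_
  )
}
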