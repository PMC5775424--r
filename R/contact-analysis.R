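#' One time point of a two-channel 3D stack
#'
#' Bundles congruent cyan (osteoblast) and red (osteoclast) intensity
#' volumes with their voxel geometry and acquisition time. Arrays are
#' indexed `(row, col, z)`.
#'
#' @param cyan,red 3D non-negative numeric arrays of identical dimension.
#' @param voxel_size_um In-plane voxel edge (um).
#' @param voxel_depth_um Z-step (um).
#' @param t_min Acquisition time in minutes.
#' @return An object of class `"volume_frame"`.
#' @export
volume_frame <- function(cyan, red, voxel_size_um = 1, voxel_depth_um = 1,
                         t_min = 0) {
  if (!identical(dim(cyan), dim(red)) || length(dim(cyan)) != 3L) {
    abort("cyan and red must be 3D arrays of identical dimension")
  }
  if (any(cyan < 0) || any(red < 0)) abort("intensities must be >= 0")
  if (voxel_size_um <= 0 || voxel_depth_um <= 0) {
    abort("voxel dimensions must be positive")
  }
  structure(list(cyan = cyan, red = red,
                 voxel_size_um = voxel_size_um,
                 voxel_depth_um = voxel_depth_um, t_min = t_min),
            class = "volume_frame")
}

#' @export
print.volume_frame <- function(x, ...) {
  cat(sprintf("<volume_frame> %s voxels, %.3g x %.3g um, t = %g min\n",
              paste(dim(x$cyan), collapse = " x "),
              x$voxel_size_um, x$voxel_depth_um, x$t_min))
  invisible(x)
}

#' Directional Sobel kernels
#'
#' Returns the four compass Sobel kernels (0, 45, 90 and 135 degrees) at
#' size 3x3 or 5x5. The diagonal kernels are obtained by rotating the
#' horizontal-derivative kernel 45 degrees along each concentric ring of the
#' stencil.
#'
#' @param size 3 or 5. The 3x3 set suits 1.0x-zoom acquisitions, the 5x5
#'   set higher-zoom acquisitions where edges span more pixels.
#' @return A list of four matrices.
#' @export
sobel_kernels <- function(size = c(3, 5)) {
  size <- match.arg(as.character(size[1]), c("3", "5"))
  k0 <- if (size == "3") {
    outer(c(1, 2, 1), c(-1, 0, 1))
  } else {
    outer(c(1, 4, 6, 4, 1), c(-1, -2, 0, 2, 1))
  }
  k45 <- rotate45(k0)
  k90 <- rotate45(k45)
  k135 <- rotate45(k90)
  list(deg0 = k0, deg45 = k45, deg90 = k90, deg135 = k135)
}

# rotate a square odd-sized kernel by 45 degrees counterclockwise:
# each concentric ring of radius r (8r cells) shifts by r positions
rotate45 <- function(k) {
  n <- nrow(k)
  c0 <- (n + 1) / 2
  out <- k
  for (r in seq_len((n - 1) / 2)) {
    ring <- ring_cells(c0, r)
    vals <- k[ring]
    out[ring] <- vals[((seq_along(vals) - 1 - r) %% length(vals)) + 1]
  }
  out
}

# ring positions in counterclockwise order starting east (image rows grow
# downward, so counterclockwise means decreasing row first)
ring_cells <- function(c0, r) {
  pos <- c(c0, c0 + r)
  dirs <- rbind(c(-1, 0), c(0, -1), c(1, 0), c(0, 1)) # up, left, down, right
  lens <- c(r, 2 * r, 2 * r, 2 * r, r)
  path <- matrix(NA_real_, 8 * r, 2)
  i <- 1
  path[i, ] <- pos
  for (seg in seq_along(lens)) {
    d <- dirs[((seg - 1) %% 4) + 1, ]
    for (s in seq_len(lens[seg])) {
      pos <- pos + d
      i <- i + 1
      if (i > 8 * r) break
      path[i, ] <- pos
    }
    if (i > 8 * r) break
  }
  cbind(path[, 1], path[, 2])
}

# 2D correlation with replicated borders (exact arithmetic, small kernels)
conv2_replicate <- function(img, k) {
  p <- (nrow(k) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2 * p) - p, 1), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * p) - p, 1), nc)
  pad <- img[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[i:(i + nr - 1), j:(j + nc - 1)]
    }
  }
  out
}

#' Sobel edge enhancement of a volume frame
#'
#' Per z-slice and channel, computes the maximal absolute response over the
#' four directional Sobel kernels, then takes the voxelwise maximum of the
#' raw and edge images (a "Lighten" composite). Cell borders are brightened
#' while interior intensities are preserved, which sharpens the subsequent
#' surface segmentation. The gradient magnitude is normalized by the sum of
#' the kernel's positive weights, so an ideal intensity step of height `h`
#' responds with `h`: the edge image lives on the same intensity scale as
#' the raw data, as a Lighten blend presumes.
#'
#' @param frame A [volume_frame].
#' @param kernel 3 or 5 (see [sobel_kernels()]).
#' @return The edge-enhanced [volume_frame].
#' @export
edge_enhance <- function(frame, kernel = 3) {
  stopifnot(inherits(frame, "volume_frame"))
  ks <- sobel_kernels(kernel)
  norm <- vapply(ks, function(k) sum(k[k > 0]), numeric(1))
  enhance_vol <- function(vol) {
    for (z in seq_len(dim(vol)[3])) {
      slice <- vol[, , z]
      edge <- matrix(0, nrow(slice), ncol(slice))
      for (i in seq_along(ks)) {
        edge <- pmax(edge, abs(conv2_replicate(slice, ks[[i]])) / norm[i])
      }
      vol[, , z] <- pmax(slice, edge)
    }
    vol
  }
  volume_frame(enhance_vol(frame$cyan), enhance_vol(frame$red),
               frame$voxel_size_um, frame$voxel_depth_um, frame$t_min)
}

#' Segment cell surfaces in one channel of a volume
#'
#' Thresholds the volume (per-channel Otsu by default), labels 26-connected
#' components, and discards components whose volume is `<=` the channel's
#' gate — 125 um^3 for cyan and 1,000 um^3 for red by convention, below
#' which objects are unlikely to be whole cells. Surviving surfaces are
#' numbered by descending volume. The surface area is estimated by counting
#' exposed voxel faces.
#'
#' @param vol 3D numeric array (one channel of a [volume_frame]).
#' @param voxel_size_um,voxel_depth_um Voxel geometry (um).
#' @param min_volume_um3 Inclusive exclusion gate in um^3.
#' @param channel Channel tag stored in the result.
#' @param threshold Intensity cut; `NULL` for Otsu.
#' @return A tibble of class `"cell_surfaces"`: `id`, `channel`,
#'   `n_voxels`, `volume_um3`, `surface_area_um2`, and a `voxels`
#'   list-column of linear voxel indices (grid dimension kept as an
#'   attribute). Zero rows when nothing survives the gate.
#' @export
segment_surfaces <- function(vol, voxel_size_um = 1, voxel_depth_um = 1,
                             min_volume_um3 = 0, channel = "cyan",
                             threshold = NULL) {
  stopifnot(length(dim(vol)) == 3L)
  if (is.null(threshold)) threshold <- otsu_threshold(vol)
  bits <- vol > threshold
  lab <- label_components(bits)
  voxel_vol <- voxel_size_um^2 * voxel_depth_um
  k <- max(lab)
  empty <- tibble(id = integer(), channel = character(), n_voxels = integer(),
                  volume_um3 = numeric(), surface_area_um2 = numeric(),
                  voxels = list())
  if (k == 0L) return(as_cell_surfaces(empty, dim(vol), voxel_size_um,
                                       voxel_depth_um, threshold))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(sizes * voxel_vol > min_volume_um3)
  if (length(keep) == 0L) return(as_cell_surfaces(empty, dim(vol),
                                                  voxel_size_um,
                                                  voxel_depth_um, threshold))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  vox_by_lab <- split(which(lab > 0L), lab[lab > 0L])
  rows <- purrr::imap(keep, function(labid, newid) {
    vox <- vox_by_lab[[as.character(labid)]]
    tibble(id = as.integer(newid), channel = channel,
           n_voxels = length(vox),
           volume_um3 = length(vox) * voxel_vol,
           surface_area_um2 = exposed_face_area(vox, dim(vol), voxel_size_um,
                                                voxel_depth_um),
           voxels = list(vox))
  })
  as_cell_surfaces(dplyr::bind_rows(rows), dim(vol), voxel_size_um,
                   voxel_depth_um, threshold)
}

as_cell_surfaces <- function(tbl, dm, vx, vz, threshold) {
  attr(tbl, "dim3") <- dm
  attr(tbl, "voxel_size_um") <- vx
  attr(tbl, "voxel_depth_um") <- vz
  attr(tbl, "threshold") <- threshold
  class(tbl) <- c("cell_surfaces", class(tbl))
  tbl
}

# surface area = count of voxel faces bordering background or the grid edge
exposed_face_area <- function(vox, dm, vx, vz) {
  inset <- array(FALSE, dm)
  inset[vox] <- TRUE
  co <- arrayInd(vox, dm)
  area <- 0
  face_area <- c(vx * vz, vx * vz, vx * vx) # normals along row, col, z
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- co
      nb[, axis] <- nb[, axis] + s
      outside <- nb[, axis] < 1L | nb[, axis] > dm[axis]
      exposed <- outside
      if (any(!outside)) {
        lin <- linear_index(nb[!outside, , drop = FALSE], dm)
        exposed[!outside] <- !inset[lin]
      }
      area <- area + sum(exposed) * face_area[axis]
    }
  }
  area
}

#' Colocalized contact voxels between cyan and red surfaces
#'
#' Two surfaces are in contact when their voxel sets touch under
#' 26-adjacency; the contact region is the set of voxels of one surface
#' lying within one voxel of the other (computed symmetrically via a
#' one-voxel dilation of each side). This generalizes fluorescence
#' colocalization to binary segmented cells, which rarely share voxels
#' outright.
#'
#' @param cyan_surfaces,red_surfaces `"cell_surfaces"` tables from the same
#'   frame.
#' @return A tibble with one row per touching `(cyan_id, red_id)` pair:
#'   `n_contact_voxels` and the contact `voxels` (linear indices).
#' @export
colocalize <- function(cyan_surfaces, red_surfaces) {
  dm <- attr(cyan_surfaces, "dim3")
  if (!identical(dm, attr(red_surfaces, "dim3"))) {
    abort("surfaces come from volumes of different dimension")
  }
  out <- tibble(cyan_id = integer(), red_id = integer(),
                n_contact_voxels = integer(), voxels = list())
  if (nrow(cyan_surfaces) == 0L || nrow(red_surfaces) == 0L) return(out)
  dil_c <- lapply(cyan_surfaces$voxels, dilate_indices, dm = dm)
  dil_r <- lapply(red_surfaces$voxels, dilate_indices, dm = dm)
  rows <- list()
  for (i in seq_len(nrow(cyan_surfaces))) {
    for (j in seq_len(nrow(red_surfaces))) {
      contact <- union(intersect(dil_c[[i]], red_surfaces$voxels[[j]]),
                       intersect(cyan_surfaces$voxels[[i]], dil_r[[j]]))
      if (length(contact) > 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          cyan_id = cyan_surfaces$id[i], red_id = red_surfaces$id[j],
          n_contact_voxels = length(contact), voxels = list(sort(contact)))
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else out
}

# one-voxel 26-neighbourhood dilation of a linear-index voxel set
dilate_indices <- function(vox, dm) {
  co <- arrayInd(vox, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[k, ], `+`)
    inside <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
      nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    res[[k]] <- linear_index(nb[inside, , drop = FALSE], dm)
  }
  unique(unlist(res))
}

#' Detect and track osteoblast-osteoclast contact events in a movie
#'
#' Runs the full 3D contact pipeline on a uniformly sampled list of
#' [volume_frame]s: optional Sobel edge enhancement, per-channel surface
#' segmentation with volume gating, per-frame colocalization, and tracking.
#' Surface identity is carried across frames by greedy maximal voxel-overlap
#' matching within each channel; a contact event is a maximal run of
#' consecutive frames in which the same (cyan, red) surface pair is in
#' contact, and any gap ends the event. A single-frame contact has duration
#' one frame interval (`duration = (last - first + 1) * interval`).
#'
#' @param frames List of [volume_frame]s with uniformly spaced `t_min`.
#' @param frame_interval_min Minutes between frames (default 30); checked
#'   against the frames' time stamps.
#' @param kernel Sobel kernel size (3 or 5), or `NULL` to skip enhancement.
#' @param gate_cyan_um3,gate_red_um3 Volume gates (um^3), inclusive
#'   exclusion.
#' @param thresholds Optional list with `cyan`/`red` intensity cuts; Otsu
#'   per frame and channel otherwise.
#' @return A `"contact_tracks"` list with `events` (one row per event:
#'   `event_id`, `cyan_track`, `red_track`, `first_frame`, `last_frame`,
#'   `duration_min`, `max_contact_voxels`), `summary` (one row:
#'   `n_events`, `movie_hours`, `events_per_hour`,
#'   `mean_cyan_area_um2`, `mean_red_area_um2`,
#'   `events_per_um2_mob`, `events_per_um2_moc`, `mean_duration_min`),
#'   and `per_frame` (surface counts and contact pairs per frame).
#' @export
track_contacts <- function(frames, frame_interval_min = 30, kernel = 3,
                           gate_cyan_um3 = 125, gate_red_um3 = 1000,
                           thresholds = NULL) {
  if (length(frames) < 2L) abort("contact tracking needs at least 2 frames")
  ts <- vapply(frames, function(f) f$t_min, numeric(1))
  dts <- diff(ts)
  if (any(abs(dts - frame_interval_min) > 1e-9)) {
    abort("frames are not uniformly spaced at `frame_interval_min`")
  }
  n_frames <- length(frames)
  surf_c <- surf_r <- vector("list", n_frames)
  contacts <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- frames[[f]]
    if (!is.null(kernel)) fr <- edge_enhance(fr, kernel)
    surf_c[[f]] <- segment_surfaces(fr$cyan, fr$voxel_size_um,
                                    fr$voxel_depth_um, gate_cyan_um3, "cyan",
                                    thresholds$cyan)
    surf_r[[f]] <- segment_surfaces(fr$red, fr$voxel_size_um,
                                    fr$voxel_depth_um, gate_red_um3, "red",
                                    thresholds$red)
    contacts[[f]] <- colocalize(surf_c[[f]], surf_r[[f]])
  }
  track_c <- assign_tracks(surf_c)
  track_r <- assign_tracks(surf_r)
  # per-frame contact pairs in track coordinates
  pair_rows <- purrr::map_dfr(seq_len(n_frames), function(f) {
    ct <- contacts[[f]]
    if (nrow(ct) == 0L) return(tibble())
    tibble(frame = f,
           cyan_track = track_c[[f]][ct$cyan_id],
           red_track = track_r[[f]][ct$red_id],
           n_contact_voxels = ct$n_contact_voxels)
  })
  events <- contact_runs(pair_rows, frame_interval_min)
  movie_hours <- (n_frames - 1) * frame_interval_min / 60
  mean_area <- function(surfs) {
    mean(vapply(surfs, function(s) sum(s$surface_area_um2), numeric(1)))
  }
  mca <- mean_area(surf_c)
  mra <- mean_area(surf_r)
  summary <- tibble(
    n_events = nrow(events),
    movie_hours = movie_hours,
    events_per_hour = nrow(events) / movie_hours,
    mean_cyan_area_um2 = mca,
    mean_red_area_um2 = mra,
    events_per_um2_mob = nrow(events) / mca,
    events_per_um2_moc = nrow(events) / mra,
    mean_duration_min = if (nrow(events)) mean(events$duration_min) else NA_real_
  )
  per_frame <- tibble(
    frame = seq_len(n_frames), t_min = ts,
    n_cyan_surfaces = vapply(surf_c, nrow, integer(1)),
    n_red_surfaces = vapply(surf_r, nrow, integer(1)),
    n_contact_pairs = vapply(contacts, nrow, integer(1))
  )
  structure(list(events = events, summary = summary, per_frame = per_frame,
                 frame_interval_min = frame_interval_min),
            class = "contact_tracks")
}

# greedy maximal voxel-overlap matching of surfaces between consecutive
# frames; returns, per frame, a map surface id -> persistent track id
assign_tracks <- function(surfs) {
  n_frames <- length(surfs)
  maps <- vector("list", n_frames)
  next_track <- 0L
  prev_vox <- list(); prev_tracks <- integer()
  for (f in seq_len(n_frames)) {
    s <- surfs[[f]]
    k <- nrow(s)
    map <- integer(k)
    if (k > 0L && length(prev_vox) > 0L) {
      ov <- matrix(0L, length(prev_vox), k)
      for (i in seq_along(prev_vox)) {
        for (j in seq_len(k)) {
          ov[i, j] <- length(intersect(prev_vox[[i]], s$voxels[[j]]))
        }
      }
      while (any(ov > 0L)) {
        best <- arrayInd(which.max(ov), dim(ov))
        map[best[2]] <- prev_tracks[best[1]]
        ov[best[1], ] <- 0L
        ov[, best[2]] <- 0L
      }
    }
    for (j in seq_len(k)) {
      if (map[j] == 0L) {
        next_track <- next_track + 1L
        map[j] <- next_track
      }
    }
    maps[[f]] <- map
    prev_vox <- s$voxels
    prev_tracks <- map
  }
  maps
}

# maximal runs of consecutive frames per (cyan_track, red_track) pair
contact_runs <- function(pair_rows, frame_interval_min) {
  empty <- tibble(event_id = integer(), cyan_track = integer(),
                  red_track = integer(), first_frame = integer(),
                  last_frame = integer(), duration_min = numeric(),
                  max_contact_voxels = integer())
  if (nrow(pair_rows) == 0L) return(empty)
  ev <- pair_rows |>
    dplyr::group_by(.data$cyan_track, .data$red_track) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$frame) > 1L))) |>
    dplyr::group_by(.data$cyan_track, .data$red_track, .data$run) |>
    dplyr::summarise(first_frame = min(.data$frame),
                     last_frame = max(.data$frame),
                     max_contact_voxels = max(.data$n_contact_voxels),
                     .groups = "drop") |>
    dplyr::arrange(.data$first_frame, .data$cyan_track, .data$red_track) |>
    dplyr::mutate(
      event_id = dplyr::row_number(),
      duration_min = (.data$last_frame - .data$first_frame + 1) *
        frame_interval_min) |>
    dplyr::select("event_id", "cyan_track", "red_track", "first_frame",
                  "last_frame", "duration_min", "max_contact_voxels")
  ev
}

#' @export
print.contact_tracks <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<contact_tracks> %d events over %.3g h (%.3g events/h), mean duration %.3g min\n",
    s$n_events, s$movie_hours, s$events_per_hour, s$mean_duration_min))
  invisible(x)
}

#' @export
tidy.contact_tracks <- function(x, ...) x$events

#' @export
glance.contact_tracks <- function(x, ...) x$summary

#' @export
autoplot.contact_tracks <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(y = factor(.data$event_id))) +
    ggplot2::geom_segment(ggplot2::aes(
      x = (.data$first_frame - 1) * object$frame_interval_min,
      xend = .data$last_frame * object$frame_interval_min,
      yend = factor(.data$event_id))) +
    ggplot2::labs(x = "time (min)", y = "contact event") +
    ggplot2::theme_minimal()
}
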