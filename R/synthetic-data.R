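#' Specification of a synthetic two-channel field
#'
#' Parameters of the synthetic scene generators. Cells are rendered as
#' filled discs: realistic morphology is irrelevant to the statistics under
#' test, which depend on spatial arrangement and intensity ratios. The
#' defaults describe a 256 x 256 um field at 1 um/px holding 25 cells of
#' each type with radii around 6 um, foreground intensity 200 over a
#' background of 20, and additive Gaussian noise with standard deviation 5%
#' of the foreground level (clipped at zero).
#'
#' The mixing parameter `theta` interpolates between fully segregated
#' single-colour colonies occupying opposite half-planes (`theta = 0`) and
#' both cell types drawn from one common uniform distribution over the
#' whole field (`theta = 1`): a fraction `theta` of each colour's cells is
#' displaced from its colony into the common field.
#'
#' @param size_px Field edge length in pixels (square field).
#' @param pixel_size_um Pixel edge in um.
#' @param n_cyan,n_red Cell counts per channel.
#' @param theta Mixing parameter in `[0, 1]`.
#' @param radius_mean_um,radius_sd_um Cell radius distribution (truncated
#'   below at 3 um).
#' @param fg_intensity,bg_intensity Foreground/background intensity levels.
#' @param noise_sd_frac Noise standard deviation as a fraction of
#'   `fg_intensity`.
#' @param probe_baseline pH-probe baseline intensity outside resorption
#'   sites.
#' @param probe_noise_frac Probe-channel noise standard deviation as a
#'   fraction of `probe_baseline` (0.1 corresponds to a signal-to-noise
#'   ratio of 10).
#' @param seed Integer seed fixing every random draw of a generator call.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(size_px = 256, pixel_size_um = 1,
                       n_cyan = 25, n_red = 25, theta = 0.5,
                       radius_mean_um = 6, radius_sd_um = 1.5,
                       fg_intensity = 200, bg_intensity = 20,
                       noise_sd_frac = 0.05,
                       probe_baseline = 50, probe_noise_frac = 0.1,
                       seed = 1) {
  if (theta < 0 || theta > 1) abort("`theta` must lie in [0, 1]")
  if (n_cyan < 0 || n_red < 0) abort("cell counts must be >= 0")
  structure(as.list(environment()), class = "scene_spec")
}

draw_radii <- function(n, spec) {
  pmax(3, rnorm(n, spec$radius_mean_um, spec$radius_sd_um)) / spec$pixel_size_um
}

# paint a filled disc of the given intensity onto a matrix (maximum blend)
paint_disc <- function(img, row, col, radius, value) {
  n <- nrow(img)
  rr <- max(1, floor(row - radius)):min(n, ceiling(row + radius))
  cc <- max(1, floor(col - radius)):min(ncol(img), ceiling(col + radius))
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  sub <- img[rr, cc]
  sub[d2 <= radius^2] <- pmax(sub[d2 <= radius^2], value)
  img[rr, cc] <- sub
  img
}

add_noise <- function(img, sd) {
  if (sd <= 0) return(img)
  pmax(img + rnorm(length(img), 0, sd), 0)
}

#' Synthetic two-colour distribution field
#'
#' Renders a cyan/red cell field at a prescribed mixing level with full
#' ground truth (see [scene_spec()] for the mixing model). Deterministic for
#' a given spec and seed.
#'
#' @param spec A [scene_spec()].
#' @return A list: `cyan` and `red` [channel_image]s, and `truth`, itself a
#'   list with the per-cell table (`cells`: id, color, row, col, radius_px,
#'   displaced), noise-free foreground pixel counts per channel
#'   (`area_px`), and `theta`.
#' @export
generate_distribution_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::local_seed(spec$seed)
  s <- spec$size_px
  place <- function(n, color) {
    if (n == 0L) {
      return(tibble(color = character(), row = numeric(), col = numeric(),
                    radius_px = numeric(), displaced = logical()))
    }
    radii <- draw_radii(n, spec)
    half <- s / 2
    lo <- if (color == "cyan") 1 + radii else half + radii + 1
    hi <- if (color == "cyan") half - radii else s - radii
    n_disp <- round(spec$theta * n)
    displaced <- seq_len(n) <= n_disp
    if (any(s - radii < 1 + radii) ||
        any(hi[!displaced] < lo[!displaced])) {
      abort("cells do not fit inside their colony half-plane: enlarge the field")
    }
    col <- numeric(n); row <- numeric(n)
    for (i in seq_len(n)) {
      if (displaced[i]) { # common field over the whole frame
        col[i] <- runif(1, 1 + radii[i], s - radii[i])
      } else {
        col[i] <- runif(1, lo[i], hi[i])
      }
      row[i] <- runif(1, 1 + radii[i], s - radii[i])
    }
    tibble(color = color, row = row, col = col, radius_px = radii,
           displaced = displaced)
  }
  cells <- dplyr::bind_rows(place(spec$n_cyan, "cyan"),
                            place(spec$n_red, "red"))
  cells$id <- seq_len(nrow(cells))
  render <- function(color) {
    img <- matrix(spec$bg_intensity, s, s)
    sub <- cells[cells$color == color, ]
    for (i in seq_len(nrow(sub))) {
      img <- paint_disc(img, sub$row[i], sub$col[i], sub$radius_px[i],
                        spec$fg_intensity)
    }
    img
  }
  cyan_clean <- render("cyan")
  red_clean <- render("red")
  area_px <- list(cyan = sum(cyan_clean > spec$bg_intensity),
                  red = sum(red_clean > spec$bg_intensity))
  sd <- spec$noise_sd_frac * spec$fg_intensity
  list(
    cyan = channel_image(add_noise(cyan_clean, sd), "cyan", spec$pixel_size_um),
    red = channel_image(add_noise(red_clean, sd), "red", spec$pixel_size_um),
    truth = list(cells = cells, area_px = area_px, theta = spec$theta)
  )
}

#' Synthetic pH-probe (resorption) scene
#'
#' Renders a red osteoclast channel plus a pH-probe channel whose intensity
#' is `probe_baseline` everywhere except under resorbing cells, where it is
#' `probe_baseline * rho`. Noise is added last to both channels.
#'
#' @param spec A [scene_spec()]; `n_red` cells are placed uniformly over the
#'   field (the cyan channel plays no role here).
#' @param resorbing Logical vector (length `n_red`, recycled from length 1)
#'   flagging which cells secrete acid.
#' @param rho Inside/outside probe intensity ratio, `>= 1`; scalar or
#'   per-cell.
#' @param seed Seed override (defaults to `spec$seed`), so one scene layout
#'   can be re-noised per movie frame.
#' @return A list: `probe` and `red` [channel_image]s, `moc_mask` (the
#'   noise-free red foreground as a [binary_mask]), and `truth` (cells
#'   table with `resorbing` and `rho`).
#' @export
generate_phocas_scene <- function(spec, resorbing = TRUE, rho = 3,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (any(rho < 1)) abort("`rho` must be >= 1 (probe never dims under a cell)")
  n <- spec$n_red
  resorbing <- rep_len(resorbing, n)
  rho <- rep_len(rho, n)
  withr::local_seed(seed)
  s <- spec$size_px
  radii <- draw_radii(n, spec)
  row <- runif(n, 1 + radii, s - radii)
  col <- runif(n, 1 + radii, s - radii)
  red <- matrix(spec$bg_intensity, s, s)
  probe <- matrix(spec$probe_baseline, s, s)
  for (i in seq_len(n)) {
    red <- paint_disc(red, row[i], col[i], radii[i], spec$fg_intensity)
    if (resorbing[i]) {
      probe <- paint_disc(probe, row[i], col[i], radii[i],
                          spec$probe_baseline * rho[i])
    }
  }
  moc_mask <- binary_mask(red > spec$bg_intensity, "red", spec$pixel_size_um)
  list(
    probe = channel_image(
      add_noise(probe, spec$probe_noise_frac * spec$probe_baseline),
      "probe", spec$pixel_size_um),
    red = channel_image(add_noise(red, spec$noise_sd_frac * spec$fg_intensity),
                        "red", spec$pixel_size_um),
    moc_mask = moc_mask,
    truth = tibble(cell = seq_len(n), row = row, col = col, radius_px = radii,
                   resorbing = resorbing, rho = rho)
  )
}

#' Synthetic deforming cell mask sequence
#'
#' Produces a star-convex blob whose boundary radii are perturbed each frame
#' by a seeded, circularly smoothed Gaussian field of scale `motility`
#' (pixels per step). The per-step changed-area fraction of the rendered
#' masks is recorded as ground truth, so recovered CDI values can be checked
#' exactly. `motility = 0` yields identical frames.
#'
#' @param motility Standard deviation of the per-spoke radial step, px.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param size_px Frame edge, px.
#' @param radius_px Initial blob radius, px.
#' @param pixel_size_um Pixel edge, um.
#' @return A list: `masks` (list of [binary_mask]) and `truth` (tibble with
#'   `step`, `changed_area_px`, `area_t0_px`, `changed_frac`).
#' @export
generate_deforming_cell <- function(motility, n_frames = 6, seed = 1,
                                    size_px = 96, radius_px = 25,
                                    pixel_size_um = 1) {
  if (motility < 0) abort("`motility` must be >= 0")
  if (n_frames < 2) abort("need at least 2 frames")
  withr::local_seed(seed)
  n_spokes <- 64
  centre <- (size_px + 1) / 2
  idx <- which(matrix(TRUE, size_px, size_px), arr.ind = TRUE)
  dr <- idx[, 1] - centre
  dc <- idx[, 2] - centre
  ang <- atan2(dc, dr) %% (2 * pi)
  dist <- sqrt(dr^2 + dc^2)
  spoke_angles <- seq(0, 2 * pi, length.out = n_spokes + 1)[-(n_spokes + 1)]
  render <- function(radii) {
    # linear interpolation of spoke radii around the circle
    r_at <- stats::approx(c(spoke_angles, 2 * pi), c(radii, radii[1]),
                          xout = ang, rule = 2)$y
    m <- matrix(FALSE, size_px, size_px)
    m[idx[dist <= r_at, ]] <- TRUE
    m
  }
  smooth_circ <- function(x, w = 5) {
    k <- (w - 1) / 2
    n <- length(x)
    sapply(seq_len(n), function(i) mean(x[((i - k - 1):(i + k - 1)) %% n + 1]))
  }
  radii <- rep(radius_px, n_spokes)
  masks <- vector("list", n_frames)
  masks[[1]] <- render(radii)
  for (f in 2:n_frames) {
    if (motility > 0) {
      step <- smooth_circ(rnorm(n_spokes, 0, motility))
      radii <- pmin(pmax(radii + step, 0.4 * radius_px),
                    min(1.6 * radius_px, centre - 1))
    }
    masks[[f]] <- render(radii)
  }
  truth <- purrr::map_dfr(seq_len(n_frames - 1L), function(f) {
    changed <- sum(xor(masks[[f]], masks[[f + 1]]))
    tibble(step = f, changed_area_px = changed,
           area_t0_px = sum(masks[[f]]),
           changed_frac = changed / sum(masks[[f]]))
  })
  list(masks = lapply(masks, binary_mask, channel = "red",
                      pixel_size_um = pixel_size_um),
       truth = truth)
}

#' Synthetic 3D contact movie from a scripted schedule
#'
#' Builds a two-channel volume movie in which ellipsoidal (spherical) cells
#' sit at fixed, well-separated home positions; during each scripted event a
#' cyan cell is repositioned flush against its partner red cell (surfaces
#' overlapping by one voxel) for exactly the scheduled frame span, then
#' returns home. Cell radii are chosen above the channel volume gates
#' (red 7 um, about 1,440 um^3; cyan 4 um, about 270 um^3), so every cell
#' survives segmentation. The script is the machine-readable ground truth.
#'
#' @param script Tibble/data.frame with columns `cyan_cell`, `red_cell`,
#'   `first_frame`, `last_frame` (1-based frames, inclusive). A cell
#'   scheduled in two events with overlapping spans is rejected as
#'   infeasible.
#' @param n_frames Number of frames.
#' @param n_cyan,n_red Cell counts (default: enough for the script).
#' @param frame_interval_min Minutes between frames (default 30).
#' @param noise_sd Additive Gaussian noise SD on both channels (0 = clean).
#' @param seed Seed for the noise draws.
#' @return A list: `frames` (list of [volume_frame]) and `truth` (the
#'   script plus cell geometry).
#' @export
generate_contact_movie <- function(script, n_frames = 17,
                                   n_cyan = NULL, n_red = NULL,
                                   frame_interval_min = 30,
                                   noise_sd = 0, seed = 1) {
  script <- as_tibble(script)
  needed <- c("cyan_cell", "red_cell", "first_frame", "last_frame")
  if (nrow(script) > 0 && !all(needed %in% names(script))) {
    abort("script needs columns cyan_cell, red_cell, first_frame, last_frame")
  }
  if (nrow(script) > 0) {
    if (any(script$first_frame < 1 | script$last_frame > n_frames |
            script$first_frame > script$last_frame)) {
      abort("script spans must satisfy 1 <= first_frame <= last_frame <= n_frames")
    }
    overlap_conflict <- function(col) {
      by_cell <- split(script, script[[col]])
      any(vapply(by_cell, function(b) {
        if (nrow(b) < 2) return(FALSE)
        b <- b[order(b$first_frame), ]
        any(b$first_frame[-1] <= b$last_frame[-nrow(b)])
      }, logical(1)))
    }
    if (overlap_conflict("cyan_cell") || overlap_conflict("red_cell")) {
      abort("infeasible script: a cell is booked in two overlapping events")
    }
  }
  n_cyan <- n_cyan %||% max(1L, if (nrow(script)) max(script$cyan_cell) else 1L)
  n_red <- n_red %||% max(1L, if (nrow(script)) max(script$red_cell) else 1L)
  r_cyan <- 4; r_red <- 7
  zc <- 9L
  dims <- c(56L,
            as.integer(max(16 + 30 * (n_red - 1) + 16,
                           10 + 12 * (n_cyan - 1) + 10)),
            17L)
  red_home <- cbind(row = rep(14, n_red), col = 16 + 30 * (seq_len(n_red) - 1),
                    z = zc)
  cyan_home <- cbind(row = rep(44, n_cyan),
                     col = 10 + 12 * (seq_len(n_cyan) - 1), z = zc)
  withr::local_seed(seed)
  paint_sphere <- function(vol, centre, radius, value) {
    rng <- function(c0, d) max(1, floor(c0 - radius)):min(d, ceiling(c0 + radius))
    rr <- rng(centre[1], dims[1]); cc <- rng(centre[2], dims[2])
    zz <- rng(centre[3], dims[3])
    d2 <- outer(outer((rr - centre[1])^2, (cc - centre[2])^2, `+`),
                (zz - centre[3])^2, `+`)
    sub <- vol[rr, cc, zz, drop = FALSE]
    sel <- d2 <= radius^2
    sub[sel] <- pmax(sub[sel], value)
    vol[rr, cc, zz] <- sub
    vol
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    cyan_pos <- cyan_home
    active <- if (nrow(script) == 0L) script else
      script[script$first_frame <= f & script$last_frame >= f, ]
    for (e in seq_len(nrow(active))) {
      # flush against the partner red cell, one voxel of overlap; the
      # approach direction depends on the cyan cell so that successive
      # events with different partners occupy distinct positions
      tgt <- red_home[active$red_cell[e], ]
      d <- r_red + r_cyan - 1
      dir <- switch((active$cyan_cell[e] %% 3L) + 1L,
                    c(d, 0, 0), c(0, d, 0), c(0, -d, 0))
      cyan_pos[active$cyan_cell[e], ] <- tgt + dir
    }
    cy <- array(10, dims); rd <- array(10, dims)
    for (i in seq_len(n_red)) rd <- paint_sphere(rd, red_home[i, ], r_red, 200)
    for (i in seq_len(n_cyan)) cy <- paint_sphere(cy, cyan_pos[i, ], r_cyan, 200)
    if (noise_sd > 0) {
      cy <- pmax(cy + rnorm(length(cy), 0, noise_sd), 0)
      rd <- pmax(rd + rnorm(length(rd), 0, noise_sd), 0)
    }
    frames[[f]] <- volume_frame(cy, rd, 1, 1, t_min = (f - 1) * frame_interval_min)
  }
  list(frames = frames,
       truth = list(script = script,
                    cells = list(cyan = cyan_home, red = red_home,
                                 r_cyan_um = r_cyan, r_red_um = r_red),
                    frame_interval_min = frame_interval_min))
}

#' Synthetic cohort of fields coupling spatial mixing to resorption
#'
#' Emulates, at generator level, the contact-inhibition rule by which
#' osteoblast contact suppresses osteoclast acid secretion: fields with a
#' higher mixing parameter theta receive a larger fraction of
#' non-resorbing osteoclasts (`P(non-resorbing) = coupling * theta`). Each
#' field carries a two-channel scene for the CMI pipeline and a pH-probe
#' movie for the 4-hour BRI pipeline. With `coupling = 1` the cohort
#' reproduces a negative CMI-vs-mean-BRI association; with `coupling = 0`
#' resorption is independent of mixing.
#'
#' @param n_fields Number of fields (default 24).
#' @param coupling Strength of the mixing-to-inhibition rule in `[0, 1]`.
#' @param seed Master seed; per-field seeds are derived from it.
#' @param n_bri_frames Probe movie length (default 49 frames = 4 h at 5-min
#'   steps).
#' @param rho_resorbing Probe ratio of resorbing cells (default 3).
#' @return A list with `fields` (per field: `cmi_scene`, `bri_frames`,
#'   `theta`, `resorbing`) and `truth` (tibble: field, theta,
#'   frac_resorbing, seed).
#' @export
generate_cohort <- function(n_fields = 24, coupling = 1, seed = 1,
                            n_bri_frames = 49, rho_resorbing = 3) {
  if (coupling < 0 || coupling > 1) abort("`coupling` must lie in [0, 1]")
  thetas <- seq(0, 1, length.out = n_fields)
  fields <- vector("list", n_fields)
  truth <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    fseed <- (seed * 7919L + f * 104729L) %% 2147483647L
    spec_cmi <- scene_spec(size_px = 128, n_cyan = 12, n_red = 12,
                           theta = thetas[f], seed = fseed)
    scene <- generate_distribution_image(spec_cmi)
    spec_bri <- scene_spec(size_px = 64, n_red = 6, radius_mean_um = 5,
                           radius_sd_um = 1, theta = thetas[f], seed = fseed)
    withr::with_seed(fseed + 1L, {
      resorbing <- runif(spec_bri$n_red) >= coupling * thetas[f]
    })
    bri_frames <- lapply(seq_len(n_bri_frames), function(k) {
      sc <- generate_phocas_scene(spec_bri, resorbing = resorbing,
                                  rho = rho_resorbing,
                                  seed = (fseed + 13L * k) %% 2147483647L)
      list(probe = sc$probe, red = sc$red)
    })
    fields[[f]] <- list(cmi_scene = scene, bri_frames = bri_frames,
                        theta = thetas[f], resorbing = resorbing)
    truth[[f]] <- tibble(field = f, theta = thetas[f],
                         frac_resorbing = mean(resorbing), seed = fseed)
  }
  list(fields = fields, truth = dplyr::bind_rows(truth))
}
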