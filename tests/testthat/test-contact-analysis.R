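# small helper: a constant-background volume with one bright ball
ball_volume <- function(dims, centre, radius, fg = 200, bg = 10) {
  vol <- array(bg, dims)
  idx <- which(vol > -Inf)
  co <- arrayInd(idx, dims)
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
    (co[, 3] - centre[3])^2
  vol[idx[d2 <= radius^2]] <- fg
  vol
}

test_that("directional Sobel kernels are zero-sum rotations of each other", {
  for (sz in c(3, 5)) {
    ks <- sobel_kernels(sz)
    expect_length(ks, 4L)
    for (k in ks) expect_equal(sum(k), 0)
    # the four kernels are one stencil in four orientations
    expect_equal(sort(as.vector(ks$deg0)), sort(as.vector(ks$deg45)))
    expect_equal(ks$deg90, t(ks$deg0)[nrow(ks$deg0):1, ])
  }
})

test_that("edge enhancement leaves constant volumes unchanged and never darkens", {
  vol <- array(5, c(8, 8, 3))
  fr <- volume_frame(vol, vol, 1, 1)
  out <- edge_enhance(fr, 3)
  expect_equal(out$cyan, vol)
  expect_equal(out$red, vol)

  blob <- ball_volume(c(16, 16, 5), c(8, 8, 3), 4)
  fr2 <- volume_frame(blob, blob, 1, 1)
  out2 <- edge_enhance(fr2, 5)
  expect_true(all(out2$cyan >= blob))
})

test_that("a vertical step edge responds with the normalized hand-evaluated magnitude", {
  h <- 120
  slice <- matrix(rep(c(0, h), each = 10 * 5), 10, 10)  # step between cols 5 and 6
  vol <- array(slice, c(10, 10, 1))
  out <- edge_enhance(volume_frame(vol, vol, 1, 1), 3)
  # at a pixel adjacent to the step the horizontal kernel sums to 4h,
  # normalized by the positive weight sum 4 -> h; Lighten keeps max(h, raw)
  expect_equal(out$cyan[5, 5, 1], h)
  expect_equal(out$cyan[5, 6, 1], h)
  # far from the edge the raw value survives
  expect_equal(out$cyan[5, 1, 1], 0)
  expect_equal(out$cyan[5, 10, 1], h)
})

test_that("volume gates drop small surfaces with the printed inclusive rule", {
  dims <- c(24, 24, 17)
  sphere5 <- ball_volume(dims, c(12, 12, 9), 5)  # ~520 um^3 at 1 um voxels
  red <- segment_surfaces(sphere5, 1, 1, min_volume_um3 = 1000, channel = "red")
  expect_identical(nrow(red), 0L)
  cyan <- segment_surfaces(sphere5, 1, 1, min_volume_um3 = 125, channel = "cyan")
  expect_identical(nrow(cyan), 1L)
  expect_gt(cyan$volume_um3, 125)
  expect_equal(cyan$volume_um3, cyan$n_voxels * 1)

  # an exactly-at-gate component is removed (<= excluded)
  cube <- array(10, c(10, 10, 10))
  cube[2:6, 2:6, 2:6] <- 200  # 125 voxels = 125 um^3
  expect_identical(nrow(segment_surfaces(cube, 1, 1, 125, "cyan")), 0L)
  expect_identical(nrow(segment_surfaces(cube, 1, 1, 124, "cyan")), 1L)
})

test_that("segmented surfaces carry counting-oracle volumes and ordered ids", {
  dims <- c(40, 60, 17)
  vol <- pmax(ball_volume(dims, c(14, 15, 9), 6),
              ball_volume(dims, c(26, 45, 9), 4))
  surfs <- segment_surfaces(vol, 1, 1, 0, "red")
  expect_identical(nrow(surfs), 2L)
  expect_true(all(diff(surfs$volume_um3) <= 0))  # descending volume
  mask <- vol > otsu_threshold(vol)
  expect_equal(sum(surfs$n_voxels), sum(mask))
  # face-count surface area of a cube is exact
  cube <- array(10, c(12, 12, 12)); cube[3:7, 3:7, 3:7] <- 200
  s <- segment_surfaces(cube, 2, 3, 0, "cyan")  # 2 um xy, 3 um z voxels
  expect_equal(s$volume_um3, 125 * 2 * 2 * 3)
  expect_equal(s$surface_area_um2, 2 * 25 * 4 + 4 * 25 * 6)
})

test_that("colocalization finds touching pairs and only touching pairs", {
  dims <- c(40, 70, 17)
  far_c <- segment_surfaces(ball_volume(dims, c(10, 10, 9), 4), 1, 1, 0, "cyan")
  far_r <- segment_surfaces(ball_volume(dims, c(10, 40, 9), 7), 1, 1, 0, "red")
  expect_identical(nrow(colocalize(far_c, far_r)), 0L)

  near_c <- segment_surfaces(ball_volume(dims, c(10, 30, 9), 4), 1, 1, 0, "cyan")
  ct <- colocalize(near_c, far_r)
  expect_identical(nrow(ct), 1L)
  expect_gt(ct$n_contact_voxels, 0)

  # one cyan touching two reds -> two surface pairs
  two_r <- segment_surfaces(pmax(ball_volume(dims, c(10, 40, 9), 7),
                                 ball_volume(dims, c(10, 20, 9), 7)),
                            1, 1, 0, "red")
  mid_c <- segment_surfaces(ball_volume(dims, c(10, 30, 9), 4), 1, 1, 0, "cyan")
  ct2 <- colocalize(mid_c, two_r)
  expect_identical(nrow(ct2), 2L)
  expect_identical(sort(ct2$red_id), c(1L, 2L))

  # symmetry in channels
  ct_sw <- colocalize(two_r, mid_c)
  expect_identical(nrow(ct_sw), 2L)
  expect_equal(sort(ct_sw$n_contact_voxels), sort(ct2$n_contact_voxels))
})

test_that("an overlap of k voxels yields a contact set of at least k voxels", {
  dims <- c(30, 50, 17)
  a <- ball_volume(dims, c(15, 20, 9), 6)
  b <- ball_volume(dims, c(15, 30, 9), 6)  # centres 10 apart, radii 6: overlap
  sa <- segment_surfaces(a, 1, 1, 0, "cyan")
  sb <- segment_surfaces(b, 1, 1, 0, "red")
  shared <- length(intersect(sa$voxels[[1]], sb$voxels[[1]]))
  expect_gt(shared, 0)
  ct <- colocalize(sa, sb)
  expect_gte(ct$n_contact_voxels, shared)
})

test_that("contact tracking recovers a scripted movie exactly", {
  script <- tibble::tibble(cyan_cell = c(1, 2, 1, 3, 2, 3),
                           red_cell = c(1, 1, 2, 2, 1, 1),
                           first_frame = c(2, 5, 8, 10, 12, 16),
                           last_frame = c(4, 6, 9, 13, 14, 16))
  mv <- generate_contact_movie(script, n_frames = 17, n_cyan = 3, n_red = 2)
  tr <- track_contacts(mv$frames, 30)
  expect_identical(nrow(tr$events), 6L)
  got <- tr$events[order(tr$events$first_frame), ]
  want <- script[order(script$first_frame), ]
  expect_identical(got$first_frame, as.integer(want$first_frame))
  expect_identical(got$last_frame, as.integer(want$last_frame))
  expect_equal(got$duration_min,
               (want$last_frame - want$first_frame + 1) * 30)
  expect_equal(tr$summary$events_per_hour, 6 / 8)
  # bookkeeping identity
  expect_equal(tr$summary$events_per_hour * tr$summary$movie_hours,
               tr$summary$n_events)
})

test_that("a single pair in frames 2-4 of a 17-frame movie lasts 90 minutes", {
  script <- tibble::tibble(cyan_cell = 1, red_cell = 1,
                           first_frame = 2, last_frame = 4)
  mv <- generate_contact_movie(script, n_frames = 17)
  tr <- track_contacts(mv$frames, 30)
  expect_identical(nrow(tr$events), 1L)
  expect_equal(tr$events$duration_min, 90)
  expect_identical(tr$events$first_frame, 2L)
})

test_that("movies without any contact yield zero events", {
  mv <- generate_contact_movie(tibble::tibble(), n_frames = 4,
                               n_cyan = 2, n_red = 2)
  tr <- track_contacts(mv$frames, 30)
  expect_identical(nrow(tr$events), 0L)
  expect_identical(tr$summary$n_events, 0L)
  expect_true(all(tr$per_frame$n_cyan_surfaces == 2))
  expect_true(all(tr$per_frame$n_red_surfaces == 2))
})

test_that("tracking rejects non-uniform frame intervals", {
  mv <- generate_contact_movie(tibble::tibble(), n_frames = 3)
  mv$frames[[3]]$t_min <- 1000
  expect_error(track_contacts(mv$frames, 30), "uniform")
  expect_error(track_contacts(mv$frames[1], 30), "at least 2")
})

test_that("event recovery survives additive noise at SNR 5", {
  script <- tibble::tibble(cyan_cell = c(1, 2, 1, 3, 2, 3),
                           red_cell = c(1, 1, 2, 2, 1, 1),
                           first_frame = c(2, 5, 8, 10, 12, 16),
                           last_frame = c(4, 6, 9, 13, 14, 16))
  mv <- generate_contact_movie(script, n_frames = 17, n_cyan = 3, n_red = 2,
                               noise_sd = 40, seed = 2)  # fg 200 -> SNR 5
  tr <- track_contacts(mv$frames, 30)
  matched <- sum(mapply(function(f, l, r) {
    any(tr$events$first_frame <= l & tr$events$last_frame >= f)
  }, script$first_frame, script$last_frame, script$red_cell))
  expect_gte(matched / nrow(script), 0.9)
})

test_that("tidy/glance expose events and the summary row", {
  script <- tibble::tibble(cyan_cell = 1, red_cell = 1,
                           first_frame = 1, last_frame = 2)
  mv <- generate_contact_movie(script, n_frames = 3)
  tr <- track_contacts(mv$frames, 30)
  expect_identical(tidy(tr), tr$events)
  expect_identical(glance(tr), tr$summary)
  expect_s3_class(autoplot(tr), "ggplot")
})
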