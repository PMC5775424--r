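test_that("labeled pixel extraction counts each pixel once with a fixed overlap rule", {
  cy <- matrix(FALSE, 6, 6); cy[1, 1:3] <- TRUE
  rd <- matrix(FALSE, 6, 6); rd[3, 1:5] <- TRUE
  px <- extract_labeled_pixels(binary_mask(cy, "cyan"), binary_mask(rd, "red"))
  expect_identical(nrow(px), 8L)
  expect_identical(sum(px$color == "cyan"), 3L)
  expect_identical(sum(px$color == "red"), 5L)
  expect_identical(min(px$row), 0L)  # 0-based coordinates

  rd2 <- rd; rd2[1, 1] <- TRUE  # overlaps a cyan pixel
  both <- extract_labeled_pixels(binary_mask(cy, "cyan"),
                                 binary_mask(rd2, "red"))
  expect_identical(nrow(both), 8L)  # overlap counted once
  expect_identical(sum(both$color == "red"), 6L)  # ... and assigned red
  both_cy <- extract_labeled_pixels(binary_mask(cy, "cyan"),
                                    binary_mask(rd2, "red"), overlap = "cyan")
  expect_identical(nrow(both_cy), 8L)
  expect_identical(sum(both_cy$color == "cyan"), 3L)

  empty <- binary_mask(matrix(FALSE, 6, 6), "cyan")
  expect_error(extract_labeled_pixels(empty, binary_mask(matrix(FALSE, 6, 6), "red")),
               "no foreground")
})

test_that("the Ward tree merges nearest pairs first and has N - 1 merges", {
  px <- make_pixels(row = c(0, 0, 10, 10), col = c(0, 1, 10, 11),
                    color = c("cyan", "red", "cyan", "red"))
  tree <- build_cluster_tree(px)
  expect_identical(nrow(tree$merge), 3L)
  p2 <- partition_at(tree, px, 2)
  memb <- attr(p2, "membership")
  expect_identical(memb[1], memb[2])  # the close pairs stay together
  expect_identical(memb[3], memb[4])
  expect_false(memb[1] == memb[3])

  single <- make_pixels(0, 0, "cyan")
  expect_error(build_cluster_tree(single), "at least 2")
})

test_that("partition_at spans from one cluster to all singletons", {
  withr::with_seed(5, {
    px <- make_pixels(row = sample(0:29, 12), col = sample(0:29, 12),
                      color = sample(c("cyan", "red"), 12, replace = TRUE))
  })
  tree <- build_cluster_tree(px)
  p1 <- partition_at(tree, px, 1)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$y_count + p1$r_count, nrow(px))
  pn <- partition_at(tree, px, nrow(px))
  expect_identical(nrow(pn), nrow(px))
  expect_true(all(cluster_impurity(pn$y_count, pn$r_count) == 0))
  expect_error(partition_at(tree, px, 0), "integer in")
  expect_error(partition_at(tree, px, nrow(px) + 1), "integer in")
})

test_that("two separated single-colour blobs split into pure clusters at m = 2", {
  cy <- matrix(FALSE, 40, 40); cy[2:6, 2:6] <- TRUE
  rd <- matrix(FALSE, 40, 40); rd[30:34, 30:34] <- TRUE
  px <- extract_labeled_pixels(binary_mask(cy, "cyan"), binary_mask(rd, "red"))
  p2 <- partition_at(build_cluster_tree(px), px, 2)
  expect_identical(sort(p2$y_count), c(0L, 25L))
  expect_identical(sort(p2$r_count), c(0L, 25L))
  expect_equal(gli(p2), 0)
})

test_that("cluster impurity matches its closed form and bounds", {
  expect_equal(cluster_impurity(10, 10), 0.5)
  expect_equal(cluster_impurity(7, 0), 0)
  expect_equal(cluster_impurity(3, 1), 0.375)  # 1 - (9 + 1)/16
  expect_error(cluster_impurity(0, 0), "empty")
  withr::with_seed(2, {
    y <- sample(0:50, 100, replace = TRUE)
    r <- sample(0:50, 100, replace = TRUE)
    ok <- y + r > 0
    imp <- cluster_impurity(y[ok], r[ok])
    expect_true(all(imp >= 0 & imp <= 0.5))
    expect_equal(imp, cluster_impurity(r[ok], y[ok]))  # colour symmetry
  })
})

test_that("GLI is the size-weighted impurity average", {
  clusters <- tibble::tibble(y_count = c(3L, 0L), r_count = c(1L, 4L))
  expect_equal(gli(clusters), (4 / 8) * 0.375 + (4 / 8) * 0)
  pure <- tibble::tibble(y_count = c(5L, 0L, 2L), r_count = c(0L, 7L, 0L))
  expect_equal(gli(pure), 0)
  even <- tibble::tibble(y_count = c(4L, 1L), r_count = c(4L, 1L))
  expect_equal(gli(even), 0.5)
})

test_that("the GLI curve equals per-m recomputation and is monotone", {
  withr::with_seed(9, {
    px <- make_pixels(row = sample(0:40, 30), col = sample(0:40, 30),
                      color = sample(c("cyan", "red"), 30, replace = TRUE))
  })
  tree <- build_cluster_tree(px)
  curve <- gli_curve(tree, px, schedule = "full")
  recomputed <- vapply(seq_len(nrow(px)),
                       function(m) gli(partition_at(tree, px, m)), numeric(1))
  expect_equal(curve$gli, recomputed)
  expect_equal(curve$gli[nrow(px)], 0)
  expect_true(all(diff(curve$gli) <= 1e-12))
  expect_true(all(curve$gli >= 0 & curve$gli <= 0.5))

  pow <- gli_curve(tree, px, schedule = "powers_of_two")
  expect_identical(pow$m, as.integer(2^(0:4)))
  expect_equal(pow$gli, curve$gli[pow$m])
})

test_that("the GLI curve never increases across many random pixel sets", {
  withr::with_seed(100, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      px <- make_pixels(row = sample(0:60, n), col = sample(0:60, n),
                        color = sample(c("cyan", "red"), n, replace = TRUE))
      curve <- gli_curve(build_cluster_tree(px), px, schedule = "full")
      expect_true(all(diff(curve$gli) <= 1e-12))
      expect_true(all(curve$gli >= -1e-12 & curve$gli <= 0.5 + 1e-12))
      expect_equal(curve$gli[n], 0)
    }
  })
})

test_that("a single-colour field has an identically zero curve and CMI", {
  px <- make_pixels(row = c(0, 3, 7, 9), col = c(0, 2, 5, 8),
                    color = rep("cyan", 4))
  tree <- build_cluster_tree(px)
  curve <- gli_curve(tree, px, schedule = "full")
  expect_true(all(curve$gli == 0))
  expect_equal(cmi_exact(curve)$cmi, 0)
  expect_equal(cmi_approx(gli_curve(tree, px, "powers_of_two"))$cmi, 0)
})

test_that("a curve pinned at maximal impurity yields CMI = 1 (telescoping weights)", {
  for (n in c(7L, 64L, 1000L)) {
    curve <- make_gli_curve(1:n, rep(0.5, n), n)
    expect_equal(cmi_exact(curve)$cmi, 1, tolerance = 1e-12)
  }
  np <- 6L
  pcurve <- make_gli_curve(2^(0:np), rep(0.5, np + 1), 2^np, "powers_of_two")
  expect_equal(cmi_approx(pcurve)$cmi, 1, tolerance = 1e-12)
})

test_that("CMI validates its curve schedule", {
  curve <- make_gli_curve(1:9, rep(0.1, 9), 10)
  expect_error(cmi_exact(curve), "full GLI curve")
  gap <- make_gli_curve(c(1L, 2L, 8L), rep(0.1, 3), 8, "powers_of_two")
  expect_error(cmi_approx(gap), "m = 1, 2, 4, 8")
})

test_that("the full clustering-to-CMI chain matches an exhaustive oracle on tiny inputs", {
  withr::with_seed(21, {
    for (rep in 1:8) {
      n <- sample(4:8, 1)
      coords <- cbind(runif(n, 0, 20), runif(n, 0, 20))
      colors <- sample(c("cyan", "red"), n, replace = TRUE)
      cy <- matrix(FALSE, 25, 25); rd <- matrix(FALSE, 25, 25)
      ri <- round(coords[, 1]) + 1; ci <- round(coords[, 2]) + 1
      # ensure distinct integer pixel positions
      if (anyDuplicated(cbind(ri, ci))) next
      for (i in 1:n) {
        if (colors[i] == "cyan") cy[ri[i], ci[i]] <- TRUE else rd[ri[i], ci[i]] <- TRUE
      }
      px <- extract_labeled_pixels(binary_mask(cy, "cyan"),
                                   binary_mask(rd, "red"))
      tree <- build_cluster_tree(px)
      oracle_parts <- brute_ward_partitions(cbind(px$row, px$col))
      for (m in seq_len(nrow(px))) {
        ours <- attr(partition_at(tree, px, m), "membership")
        expect_true(same_partition(ours, oracle_parts[[m]]),
                    info = sprintf("rep %d, m = %d", rep, m))
      }
      oracle_gli <- vapply(seq_len(nrow(px)), function(m) {
        gli_direct(oracle_parts[[m]], px$color)
      }, numeric(1))
      curve <- gli_curve(tree, px, "full")
      expect_equal(curve$gli, oracle_gli)
      expect_equal(cmi_exact(curve)$cmi, cmi_exact_direct(oracle_gli))
      expect_equal(cmi_approx(curve)$cmi, cmi_approx_direct(oracle_gli))
    }
  })
})

test_that("GLI and CMI are symmetric under swapping the two colours", {
  withr::with_seed(14, {
    n <- 24
    row <- sample(0:30, n); col <- sample(0:30, n)
    color <- sample(c("cyan", "red"), n, replace = TRUE)
  })
  px <- make_pixels(row, col, color)
  swapped <- make_pixels(row, col, ifelse(color == "cyan", "red", "cyan"))
  c1 <- gli_curve(build_cluster_tree(px), px, "full")
  c2 <- gli_curve(build_cluster_tree(swapped), swapped, "full")
  expect_equal(c1$gli, c2$gli)
  expect_equal(cmi_exact(c1)$cmi, cmi_exact(c2)$cmi)
})

test_that("compute_cmi ranks colonies below interleaved fields and is deterministic", {
  colony <- generate_distribution_image(scene_spec(theta = 0, seed = 31))
  mixed <- generate_distribution_image(scene_spec(theta = 1, seed = 31))
  r_colony <- compute_cmi(colony$cyan, colony$red)
  r_mixed <- compute_cmi(mixed$cyan, mixed$red)
  expect_lt(r_colony$cmi, r_mixed$cmi)
  expect_true(r_colony$cmi >= 0 && r_colony$cmi <= 1)
  expect_gt(r_colony$areas$cyan, 0)
  expect_false(is.na(r_colony$thresholds$red))

  again <- compute_cmi(generate_distribution_image(scene_spec(theta = 0, seed = 31))$cyan,
                       generate_distribution_image(scene_spec(theta = 0, seed = 31))$red)
  expect_identical(r_colony$cmi, again$cmi)
  expect_identical(r_colony$N, again$N)
})

test_that("compute_cmi is insensitive to the downscale factor", {
  scene <- generate_distribution_image(scene_spec(size_px = 512, n_cyan = 40,
                                                  n_red = 40, theta = 0.6,
                                                  seed = 8))
  r4 <- compute_cmi(scene$cyan, scene$red, scale = 1 / 4)
  r8 <- compute_cmi(scene$cyan, scene$red, scale = 1 / 8)
  expect_lt(abs(r4$cmi - r8$cmi), 0.1)
})

test_that("compute_cmi reports which channel lost all foreground", {
  blank <- channel_image(matrix(c(rep(0, 99), 1), 10, 10), "cyan")
  scene <- generate_distribution_image(scene_spec(size_px = 10, n_cyan = 1,
                                                  n_red = 1,
                                                  radius_mean_um = 3,
                                                  radius_sd_um = 0, theta = 1,
                                                  seed = 2))
  expect_error(compute_cmi(blank, scene$red, scale = 1), "cyan")
})

test_that("tidy and glance expose the curve and the headline statistics", {
  scene <- generate_distribution_image(scene_spec(size_px = 96, n_cyan = 6,
                                                  n_red = 6, theta = 1,
                                                  seed = 4))
  res <- compute_cmi(scene$cyan, scene$red, scale = 1 / 2)
  td <- tidy(res)
  expect_named(td, c("m", "gli"))
  gl <- glance(res)
  expect_identical(gl$cmi, res$cmi)
  expect_identical(gl$n_pixels, res$N)
  expect_s3_class(autoplot(res), "ggplot")
})
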