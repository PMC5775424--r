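#' Labeled foreground pixels of a two-channel field
#'
#' Collects the foreground pixels of the cyan (osteoblast) and red
#' (osteoclast) masks into one tidy table, the substrate for the cell
#' mixture analysis. Coordinates are 0-based `(row, col)` with rows growing
#' downward. A pixel that is foreground in both channels is counted once and
#' assigned to the channel named by `overlap` (red by default; overlap is
#' rare after independent Otsu cuts but the rule must be fixed for
#' determinism).
#'
#' @param cyan,red [binary_mask]s of identical shape and pixel size.
#' @param overlap `"red"` or `"cyan"`: the label given to pixels foreground
#'   in both channels.
#' @return A tibble of class `"labeled_pixels"` with columns `row`, `col`
#'   (0-based) and `color` (`"cyan"`/`"red"`), carrying the pixel size as an
#'   attribute.
#' @export
extract_labeled_pixels <- function(cyan, red, overlap = c("red", "cyan")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(cyan, "binary_mask"), inherits(red, "binary_mask"))
  if (!identical(dim(cyan$bits), dim(red$bits))) {
    abort("cyan and red masks must have identical shape")
  }
  if (cyan$pixel_size_um != red$pixel_size_um) {
    abort("cyan and red masks must share one pixel size")
  }
  both <- cyan$bits & red$bits
  cy <- cyan$bits & !(both & (overlap == "red"))
  rd <- red$bits & !(both & (overlap == "cyan"))
  if (!any(cy) && !any(rd)) {
    abort("no foreground pixel in either channel: cell mixture is undefined")
  }
  coord_tbl <- function(bits, color) {
    idx <- which(bits, arr.ind = TRUE)
    tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L, color = color)
  }
  out <- dplyr::bind_rows(coord_tbl(cy, "cyan"), coord_tbl(rd, "red"))
  out <- dplyr::arrange(out, .data$row, .data$col)
  attr(out, "pixel_size_um") <- cyan$pixel_size_um
  class(out) <- c("labeled_pixels", class(out))
  out
}

#' @export
print.labeled_pixels <- function(x, ...) {
  cat(sprintf("<labeled_pixels> N = %d (cyan %d, red %d)\n",
              nrow(x), sum(x$color == "cyan"), sum(x$color == "red")))
  NextMethod()
}

#' Ward hierarchical clustering of labeled pixels
#'
#' Agglomerates the foreground pixels by Ward's minimum-variance method on
#' Euclidean distances between pixel coordinates. Pixel colour plays no role
#' in the clustering: the tree expresses spatial connectivity only, and the
#' colour composition of its clusters is measured afterwards by the
#' Gini-like impurity. The tree is the standard [stats::hclust] object
#' (method `"ward.D2"`), deterministic for a given pixel order.
#'
#' @param pixels A `"labeled_pixels"` table with at least two pixels.
#' @return An [stats::hclust] tree over the pixel rows.
#' @export
build_cluster_tree <- function(pixels) {
  stopifnot(inherits(pixels, "labeled_pixels"))
  if (nrow(pixels) < 2L) {
    abort("hierarchical clustering needs at least 2 foreground pixels")
  }
  hclust(dist(cbind(pixels$row, pixels$col)), method = "ward.D2")
}

#' Cut a cluster tree into m clusters
#'
#' Undoes the last `m - 1` merges of the Ward tree (equivalently, cuts the
#' dendrogram at the height yielding `m` clusters) and tallies the cyan and
#' red pixel counts of each cluster.
#'
#' @param tree An [stats::hclust] tree from [build_cluster_tree()].
#' @param pixels The `"labeled_pixels"` table the tree was built from.
#' @param m Number of clusters, `1 <= m <= N`.
#' @return A tibble with one row per cluster: `cluster`, `y_count` (cyan),
#'   `r_count` (red), plus a `membership` attribute mapping pixels to
#'   clusters.
#' @export
partition_at <- function(tree, pixels, m) {
  n <- nrow(pixels)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m > n || m != round(m)) {
    abort(sprintf("`m` must be an integer in [1, %d]", n))
  }
  membership <- cutree(tree, k = m)
  out <- cluster_counts(membership, pixels$color)
  attr(out, "membership") <- membership
  out
}

cluster_counts <- function(membership, colors) {
  k <- max(membership)
  tibble(
    cluster = seq_len(k),
    y_count = tabulate(membership[colors == "cyan"], nbins = k),
    r_count = tabulate(membership[colors == "red"], nbins = k)
  )
}

#' Gini-like impurity of a two-colour cluster
#'
#' For a cluster holding `y` cyan and `r` red pixels the impurity is
#' \deqn{I = 1 - \frac{y^2 + r^2}{(y + r)^2},}
#' the two-class Gini impurity: 0 for a single-colour cluster and 0.5 when
#' both colours are equally represented. Vectorized over clusters.
#'
#' @param y_count,r_count Non-negative pixel counts; each cluster must be
#'   non-empty.
#' @return Impurity values in `[0, 0.5]`.
#' @export
cluster_impurity <- function(y_count, r_count) {
  if (any(y_count < 0) || any(r_count < 0)) abort("counts must be >= 0")
  tot <- y_count + r_count
  if (any(tot < 1)) abort("impurity of an empty cluster is undefined")
  1 - (y_count^2 + r_count^2) / tot^2
}

#' Weighted Gini-like impurity of a partition (GLI)
#'
#' The GLI of a partition is the average of per-cluster impurities weighted
#' by cluster size:
#' \deqn{\mathrm{GLI}(C_m) = \sum_{i=1}^{m} \frac{Y_{c_i}+R_{c_i}}{N}\, I_{c_i}.}
#' It is 0 when every cluster is single-coloured and attains its maximum 0.5
#' when every cluster splits evenly between cyan and red.
#'
#' @param clusters A tibble with `y_count` and `r_count` columns, e.g. from
#'   [partition_at()].
#' @return The GLI, a number in `[0, 0.5]`.
#' @export
gli <- function(clusters) {
  y <- clusters$y_count
  r <- clusters$r_count
  n <- sum(y) + sum(r)
  if (n < 1) abort("GLI of an empty pixel set is undefined")
  sum(((y + r) / n) * cluster_impurity(y, r))
}

#' GLI as a function of cluster count
#'
#' Evaluates the weighted impurity along the Ward tree, from the root (one
#' cluster holding every pixel) down to singletons (impurity 0). The curve
#' is non-increasing in the number of clusters; how quickly it decays is
#' what distinguishes segregated colonies (fast decay) from interleaved
#' cells (slow decay). The full schedule evaluates every `m = 1..N`; the
#' `powers_of_two` schedule evaluates only `m = 1, 2, 4, ..., 2^N'` with
#' `N'` the largest integer with `2^N' <= N`, which is all the approximate
#' CMI needs.
#'
#' The curve is computed in one pass over the merge sequence (each merge
#' changes a single cluster's impurity contribution), which is algebraically
#' identical to cutting the tree at every `m` and re-evaluating the GLI.
#'
#' @inheritParams partition_at
#' @param schedule `"full"` or `"powers_of_two"`.
#' @return A tibble of class `"gli_curve"` with columns `m` and `gli`,
#'   carrying `N` and the schedule as attributes.
#' @export
gli_curve <- function(tree, pixels, schedule = c("powers_of_two", "full")) {
  schedule <- match.arg(schedule)
  n <- nrow(pixels)
  is_cyan <- pixels$color == "cyan"
  merges <- tree$merge
  # colour tallies and impurity contribution of every merged cluster
  ys <- rs <- numeric(n - 1L)
  contrib <- numeric(n - 1L) # ((Y+R)/N) * I for merge-node clusters
  gli_at_m <- numeric(n)     # indexed by m
  gli_at_m[n] <- 0           # all singletons: every impurity 0
  acc <- 0
  for (j in seq_len(n - 1L)) {
    ab <- merges[j, ]
    child <- function(id) {
      if (id < 0) {
        c(as.numeric(is_cyan[-id]), as.numeric(!is_cyan[-id]), 0)
      } else {
        c(ys[id], rs[id], contrib[id])
      }
    }
    a <- child(ab[1]); b <- child(ab[2])
    y <- a[1] + b[1]; r <- a[2] + b[2]
    ys[j] <- y; rs[j] <- r
    contrib[j] <- ((y + r) / n) * (1 - (y^2 + r^2) / (y + r)^2)
    acc <- acc - a[3] - b[3] + contrib[j]
    gli_at_m[n - j] <- acc
  }
  ms <- if (schedule == "full") seq_len(n) else 2^(0:floor(log2(n)))
  out <- tibble(m = as.integer(ms), gli = gli_at_m[ms])
  attr(out, "N") <- n
  attr(out, "schedule") <- schedule
  class(out) <- c("gli_curve", class(out))
  out
}

#' Cell Mixture Index from a GLI curve
#'
#' The CMI is the normalized, log2-weighted area under the GLI curve. The
#' exact form integrates the full curve,
#' \deqn{\mathrm{CMI} = \frac{2}{\log_2(N+1)} \sum_{m=1}^{N}
#'   \log_2\!\frac{m+1}{m}\,\mathrm{GLI}(C_m),}
#' with base-2 weights because the clustering is a binary tree; the weights
#' telescope to \eqn{\log_2(N+1)}, so a curve pinned at the maximal impurity
#' 0.5 yields exactly 1 and the CMI always lies in `[0, 1]`. The approximate
#' form evaluates the curve only at the powers of two
#' `m = 1, 2, 4, ..., 2^{N'}` (with `2^{N'} <= N`) and averages,
#' \deqn{\mathrm{CMI} \approx \frac{2}{N'+1} \sum_{m \in \{2^0..2^{N'}\}}
#'   \mathrm{GLI}(C_m),}
#' which shrinks the cost drastically while changing the value only
#' slightly.
#'
#' @param curve A `"gli_curve"`; full schedule for `cmi_exact()`, the
#'   powers-of-two schedule (a full curve is also accepted and subset) for
#'   `cmi_approx()`.
#' @param N Total foreground pixel count; defaults to the curve's own `N`.
#' @return A `"cmi_result"` list: `cmi`, `method`, `N`, `n_prime` (approx
#'   only), and the curve used.
#' @export
cmi_exact <- function(curve, N = attr(curve, "N")) {
  stopifnot(inherits(curve, "gli_curve"))
  if (!identical(curve$m, seq_len(N))) {
    abort("exact CMI needs the full GLI curve (every m = 1..N)")
  }
  check_gli_range(curve$gli)
  w <- log2((curve$m + 1) / curve$m)
  cmi <- 2 / log2(N + 1) * sum(w * curve$gli)
  new_cmi_result(cmi, "exact", N, NA_integer_, curve)
}

#' @rdname cmi_exact
#' @export
cmi_approx <- function(curve, N = attr(curve, "N")) {
  stopifnot(inherits(curve, "gli_curve"))
  n_prime <- floor(log2(N))
  wanted <- as.integer(2^(0:n_prime))
  idx <- match(wanted, curve$m)
  if (anyNA(idx)) {
    abort(sprintf("approximate CMI needs GLI entries at m = %s",
                  paste(wanted, collapse = ", ")))
  }
  check_gli_range(curve$gli[idx])
  cmi <- 2 / (n_prime + 1) * sum(curve$gli[idx])
  new_cmi_result(cmi, "approx", N, as.integer(n_prime), curve)
}

check_gli_range <- function(g) {
  if (any(g < -1e-12 | g > 0.5 + 1e-12)) {
    abort("GLI values outside [0, 0.5]: corrupt curve")
  }
}

new_cmi_result <- function(cmi, method, N, n_prime, curve, extra = list()) {
  structure(
    c(list(cmi = cmi, method = method, N = as.integer(N),
           n_prime = n_prime, curve = curve), extra),
    class = "cmi_result"
  )
}

#' @export
print.cmi_result <- function(x, ...) {
  cat(sprintf("<cmi_result> CMI = %.4f (%s, N = %d%s)\n", x$cmi, x$method,
              x$N,
              if (!is.na(x$n_prime)) sprintf(", N' = %d", x$n_prime) else ""))
  if (!is.null(x$areas)) {
    cat(sprintf("  areas: cyan %.4g um^2, red %.4g um^2\n",
                x$areas$cyan, x$areas$red))
  }
  invisible(x)
}

#' Cell Mixture Index of a two-channel field
#'
#' End-to-end cell mixture analysis. Step 1 binarizes each channel with an
#' independent Otsu threshold (skipped when masks are supplied), removes
#' debris-sized components (cyan `<= 5` um^2, red `<= 10` um^2 by default)
#' and downscales both masks by block majority (default factor 1/4). Step 2
#' clusters the labelled foreground pixels with Ward's method on spatial
#' coordinates. Step 3 traces the GLI curve along the tree, and Step 4
#' integrates it into the CMI. Per-channel foreground areas are measured as
#' a by-product at native resolution, after size filtering.
#'
#' @param cyan,red [channel_image]s (raw intensities) or [binary_mask]s of
#'   equal shape and pixel size.
#' @param scale Downscale factor `1/k`, in `[1/16, 1]`; 1/4 by default.
#' @param method `"approx"` (default; powers-of-two schedule) or `"exact"`
#'   (full curve; practical up to a few thousand foreground pixels).
#' @param min_area_cyan_um2,min_area_red_um2 Inclusive component-exclusion
#'   gates in um^2.
#' @param overlap Channel assigned to pixels foreground in both masks.
#' @return A `"cmi_result"` with, additionally, `areas` (native-resolution
#'   foreground per channel, um^2) and the Otsu `thresholds` used (NA when
#'   masks were supplied).
#' @examples
#' set.seed(1)
#' scene <- generate_distribution_image(scene_spec(size_px = 96, theta = 1,
#'                                                 n_cyan = 6, n_red = 6,
#'                                                 seed = 7))
#' compute_cmi(scene$cyan, scene$red, scale = 1 / 2)
#' @export
compute_cmi <- function(cyan, red, scale = 1 / 4,
                        method = c("approx", "exact"),
                        min_area_cyan_um2 = 5, min_area_red_um2 = 10,
                        overlap = c("red", "cyan")) {
  method <- match.arg(method)
  overlap <- match.arg(overlap)
  prep <- function(x, channel, min_area) {
    thr <- NA_real_
    if (inherits(x, "channel_image")) {
      thr <- otsu_threshold(x)
      x <- binarize(x, thr)
    } else if (!inherits(x, "binary_mask")) {
      abort("inputs must be channel_image or binary_mask objects")
    }
    x <- remove_small_components(x, min_area)
    if (!any(x$bits)) {
      abort(sprintf(
        "channel '%s' has no foreground after thresholding and size filtering",
        channel))
    }
    list(mask = x, threshold = thr)
  }
  pc <- prep(cyan, "cyan", min_area_cyan_um2)
  pr <- prep(red, "red", min_area_red_um2)
  areas <- list(cyan = mask_area_um2(pc$mask), red = mask_area_um2(pr$mask))
  cyan_small <- downscale_mask(pc$mask, scale)
  red_small <- downscale_mask(pr$mask, scale)
  pixels <- extract_labeled_pixels(cyan_small, red_small, overlap = overlap)
  if (nrow(pixels) < 2L) {
    abort("fewer than 2 foreground pixels after downscaling; use a larger scale")
  }
  tree <- build_cluster_tree(pixels)
  curve <- gli_curve(tree, pixels,
                     schedule = if (method == "exact") "full" else "powers_of_two")
  res <- if (method == "exact") cmi_exact(curve) else cmi_approx(curve)
  res$areas <- areas
  res$thresholds <- list(cyan = pc$threshold, red = pr$threshold)
  res$scale <- scale
  res
}

#' @export
tidy.cmi_result <- function(x, ...) {
  tibble(m = x$curve$m, gli = x$curve$gli)
}

#' @export
glance.cmi_result <- function(x, ...) {
  tibble(
    cmi = x$cmi, method = x$method, n_pixels = x$N,
    n_prime = x$n_prime,
    area_cyan_um2 = if (is.null(x$areas)) NA_real_ else x$areas$cyan,
    area_red_um2 = if (is.null(x$areas)) NA_real_ else x$areas$red
  )
}

#' @export
autoplot.gli_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$gli)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "number of clusters (log2 scale)",
                  y = "Gini-like impurity (GLI)") +
    ggplot2::ylim(0, 0.5) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cmi_result <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::ggtitle(sprintf("CMI = %.3f (%s, N = %d)",
                             object$cmi, object$method, object$N))
}
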