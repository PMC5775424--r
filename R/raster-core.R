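#' Otsu's automatic intensity threshold
#'
#' Computes the threshold that maximizes the between-class variance of the
#' intensity histogram, the standard automatic binarization for fluorescence
#' channels. Intensities are binned at integer values `0 .. levels - 1`
#' (256 levels for 8-bit data, 65536 for 16-bit). Foreground is defined as
#' strictly above the returned threshold; when several cut points attain the
#' maximal between-class variance the lowest is returned, which makes the
#' result deterministic.
#'
#' @param image A [channel_image] (or a bare numeric matrix/array).
#' @param levels Number of integer intensity bins; defaults to one more than
#'   the maximal observed intensity, rounded up to 256 or 65536.
#' @return A single numeric threshold `t`; pixels with intensity `> t` are
#'   foreground.
#' @seealso [binarize()]
#' @export
otsu_threshold <- function(image, levels = NULL) {
  px <- if (inherits(image, "channel_image")) image$pixels else image
  ch <- if (inherits(image, "channel_image")) image$channel else "image"
  v <- floor(as.numeric(px))
  if (is.null(levels)) levels <- if (max(v) <= 255) 256L else 65536L
  v <- pmin(pmax(v, 0), levels - 1L)
  if (length(unique(v)) < 2L) {
    abort(sprintf(
      "channel '%s': constant intensity histogram, Otsu threshold undefined", ch))
  }
  counts <- tabulate(v + 1L, nbins = levels)
  vals <- 0:(levels - 1L)
  n <- sum(counts)
  # cumulative moments for the class {intensity <= t}
  w0 <- cumsum(counts) / n
  mu0_num <- cumsum(counts * vals)
  mu_tot <- mu0_num[levels] / n
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, levels)
  mu0 <- mu0_num[ok] / (w0[ok] * n)
  mu1 <- (mu0_num[levels] - mu0_num[ok]) / (w1[ok] * n)
  sigma_b[ok] <- w0[ok] * w1[ok] * (mu0 - mu1)^2
  vals[which.max(sigma_b)]
}

#' Binarize a channel image at a fixed threshold
#'
#' @param image A [channel_image].
#' @param threshold Intensity cut; pixels strictly above it become foreground.
#' @return A [binary_mask] with the channel and pixel size propagated.
#' @export
binarize <- function(image, threshold) {
  stopifnot(inherits(image, "channel_image"))
  binary_mask(image$pixels > threshold, image$channel,
              image$pixel_size_um, image$voxel_depth_um)
}

#' Label connected foreground components
#'
#' Labels connected components of a logical grid under the package-wide
#' connectivity convention: 8-connectivity in 2D, 26-connectivity in 3D
#' (i.e. pixels/voxels touching by edge or corner belong to one component).
#' Implemented as a neighbourhood graph over foreground positions whose
#' connected components are extracted with \pkg{igraph}.
#'
#' @param bits Logical matrix or 3D array.
#' @return Integer grid of the same shape: 0 for background, `1..k` for the
#'   `k` components (labelled in order of first raster occurrence).
#' @export
label_components <- function(bits) {
  stopifnot(is.logical(bits), !is.null(dim(bits)))
  dm <- dim(bits)
  lab <- array(0L, dm)
  fg <- which(bits)
  if (length(fg) == 0L) return(lab)
  id_at <- array(0L, dm)
  id_at[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dm)
  offs <- neighbour_offsets(length(dm))
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[k, ], `+`)
    inside <- rep(TRUE, nrow(nb))
    for (d in seq_along(dm)) {
      inside <- inside & nb[, d] >= 1L & nb[, d] <= dm[d]
    }
    if (!any(inside)) next
    lin <- linear_index(nb[inside, , drop = FALSE], dm)
    nb_id <- id_at[lin]
    hit <- nb_id > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(which(inside)[hit], nb_id[hit])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # relabel by first occurrence in raster order so labels are reproducible
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[fg] <- relab[comp]
  lab
}

# half-neighbourhood offsets (each undirected adjacency counted once):
# 4 offsets in 2D (8-connectivity), 13 in 3D (26-connectivity)
neighbour_offsets <- function(ndim) {
  grid <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  keep <- apply(grid, 1L, function(o) {
    nz <- o[o != 0]
    nz[length(nz)] > 0  # keep one of each +/- pair
  })
  grid[keep, , drop = FALSE]
}

linear_index <- function(coords, dm) {
  idx <- coords[, 1L]
  mult <- 1L
  for (d in seq_along(dm)[-1L]) {
    mult <- mult * dm[d - 1L]
    idx <- idx + (coords[, d] - 1L) * mult
  }
  idx
}

#' Remove small foreground components
#'
#' Deletes every 8-connected component whose area is less than or equal to
#' `max_excluded_area_um2` (the exclusion is inclusive), leaving larger
#' components untouched. The default gates follow the debris-rejection rule
#' for two-photon bone imaging: 5 um^2 for the cyan osteoblast channel and
#' 10 um^2 for the red osteoclast channel. Areas are converted to pixel
#' counts through the mask's pixel size, so this step is intended to run at
#' native resolution, before any downscaling.
#'
#' @param mask A 2D [binary_mask].
#' @param max_excluded_area_um2 Components with area (um^2) `<=` this value
#'   are removed. Must be positive.
#' @return The filtered [binary_mask].
#' @export
remove_small_components <- function(mask, max_excluded_area_um2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(dim(mask$bits)) != 2L) abort("size filtering expects a 2D mask")
  if (!is.numeric(max_excluded_area_um2) || max_excluded_area_um2 <= 0) {
    abort("`max_excluded_area_um2` must be a positive area in um^2")
  }
  lab <- label_components(mask$bits)
  if (max(lab) == 0L) return(mask)
  px_area <- mask$pixel_size_um^2
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes * px_area <= max_excluded_area_um2)
  bits <- mask$bits
  bits[lab %in% drop] <- FALSE
  binary_mask(bits, mask$channel, mask$pixel_size_um, mask$voxel_depth_um)
}

#' Downscale a binary mask by block majority
#'
#' Reduces a 2D mask by an integer factor `k` (`factor = 1/k`): each
#' `k x k` block collapses to a single pixel that is foreground when at
#' least half of the block is foreground (ties count as foreground). The
#' physical pixel size is multiplied by `k`, so foreground area in um^2 is
#' approximately preserved. Valid factors span 1 (identity) down to 1/16,
#' the range over which the cell mixture index is insensitive to scale;
#' 1/4 (512 x 512 to 128 x 128) is the working default of the CMI pipeline.
#' Masks whose dimensions are not multiples of `k` are padded with
#' background on the bottom/right edge first.
#'
#' @param mask A 2D [binary_mask].
#' @param factor Scale factor of the form `1/k` with integer `k`, in
#'   `[1/16, 1]`.
#' @return The downscaled [binary_mask] with `pixel_size_um` scaled by `k`.
#' @export
downscale_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(dim(mask$bits)) != 2L) abort("downscaling expects a 2D mask")
  if (!is.numeric(factor) || length(factor) != 1L ||
      factor < 1 / 16 - 1e-9 || factor > 1 + 1e-9) {
    abort("`factor` must lie in [1/16, 1]")
  }
  k <- round(1 / factor)
  if (abs(1 / factor - k) > 1e-6) abort("`factor` must be 1/k for integer k")
  if (k == 1L) return(mask)
  bits <- mask$bits
  nr <- ceiling(nrow(bits) / k) * k
  nc <- ceiling(ncol(bits) / k) * k
  if (nr != nrow(bits) || nc != ncol(bits)) {
    padded <- matrix(FALSE, nr, nc)
    padded[seq_len(nrow(bits)), seq_len(ncol(bits))] <- bits
    bits <- padded
  }
  # block sums: collapse row blocks, then column blocks
  s1 <- colSums(array(bits, c(k, nr / k, nc)))        # (nr/k) x nc
  s2 <- t(colSums(array(t(s1), c(k, nc / k, nr / k)))) # (nr/k) x (nc/k)
  out <- s2 / k^2 >= 0.5
  binary_mask(out, mask$channel, mask$pixel_size_um * k, mask$voxel_depth_um)
}
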