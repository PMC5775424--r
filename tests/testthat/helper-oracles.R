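# Independent reference implementations used as oracles. These deliberately
# recompute everything from first principles (exhaustive scans, greedy
# objective re-evaluation) and share no code with the package internals.

# Otsu by exhaustive scan: for every candidate cut t, split into {v <= t}
# and {v > t} and compute the between-class variance directly.
brute_otsu <- function(values, levels = 256L) {
  v <- floor(values)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:(levels - 2L)) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Greedy Ward agglomeration, recomputing the increase in total
# within-cluster sum of squares for every candidate pair at every step.
# Returns the membership vector at every cluster count m = n .. 1.
brute_ward_partitions <- function(coords) {
  n <- nrow(coords)
  clusters <- as.list(seq_len(n))
  partitions <- vector("list", n)
  membership <- function(cl) {
    memb <- integer(n)
    for (i in seq_along(cl)) memb[cl[[i]]] <- i
    memb
  }
  partitions[[n]] <- membership(clusters)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- c(NA, NA)
    best_cost <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        a <- coords[clusters[[i]], , drop = FALSE]
        b <- coords[clusters[[j]], , drop = FALSE]
        na <- nrow(a); nb <- nrow(b)
        d2 <- sum((colMeans(a) - colMeans(b))^2)
        cost <- na * nb / (na + nb) * d2
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    partitions[[k - 1L]] <- membership(clusters)
  }
  partitions
}

# Direct evaluation of the weighted Gini-like impurity for a membership
# vector and colour labels.
gli_direct <- function(membership, colors) {
  n <- length(membership)
  total <- 0
  for (cl in unique(membership)) {
    y <- sum(membership == cl & colors == "cyan")
    r <- sum(membership == cl & colors == "red")
    total <- total + ((y + r) / n) * (1 - (y^2 + r^2) / (y + r)^2)
  }
  total
}

cmi_exact_direct <- function(gli_by_m) {
  n <- length(gli_by_m)
  m <- seq_len(n)
  2 / log2(n + 1) * sum((log2(m + 1) - log2(m)) * gli_by_m)
}

cmi_approx_direct <- function(gli_by_m) {
  n <- length(gli_by_m)
  np <- floor(log2(n))
  2 / (np + 1) * sum(gli_by_m[2^(0:np)])
}

# do two membership vectors induce the same set partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# quick pixel-set builder for small hand-made examples
make_pixels <- function(row, col, color, pixel_size_um = 1) {
  n <- max(row + 2, col + 2)
  cy <- matrix(FALSE, n, n)
  rd <- matrix(FALSE, n, n)
  for (i in seq_along(row)) {
    if (color[i] == "cyan") cy[row[i] + 1, col[i] + 1] <- TRUE
    else rd[row[i] + 1, col[i] + 1] <- TRUE
  }
  extract_labeled_pixels(binary_mask(cy, "cyan", pixel_size_um),
                         binary_mask(rd, "red", pixel_size_um))
}

# construct a gli_curve object directly (for analytic curve tests)
make_gli_curve <- function(m, gli, N, schedule = "full") {
  out <- tibble::tibble(m = as.integer(m), gli = gli)
  attr(out, "N") <- N
  attr(out, "schedule") <- schedule
  class(out) <- c("gli_curve", class(out))
  out
}
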