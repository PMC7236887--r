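# Independent brute-force oracles used to validate the implementation paths.

# 8-connected labelling by queue-based flood fill
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of foreground pixels?
same_partition <- function(a, b) {
  fa <- a > 0L; fb <- b > 0L
  if (!identical(fa, fb)) return(FALSE)
  key_a <- a[fa]; key_b <- b[fb]
  all(tapply(key_b, key_a, function(v) length(unique(v)) == 1L)) &&
    all(tapply(key_a, key_b, function(v) length(unique(v)) == 1L))
}

# sort-based linear-interpolation percentile (closest-ranks, independent of
# stats::quantile)
oracle_percentile <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Andrew monotone-chain convex hull area with shoelace formula
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  hull <- c(build(1:n), build(n:1))
  hull <- hull[!duplicated(hull)]
  v <- pts[hull, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  xx <- v[, 1]; zz <- v[, 2]
  abs(sum(xx * c(zz[-1], zz[1]) - c(xx[-1], xx[1]) * zz)) / 2
}

# exhaustive coverage fractions: triple loop over grid point, track, slice
oracle_coverage <- function(tracks, grid, spacing, radii) {
  ids <- unique(tracks$track_id)
  cls <- tracks$element_class[match(ids, tracks$track_id)]
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    dmin <- sapply(ids, function(id) {
      tt <- tracks[tracks$track_id == id, ]
      min(sqrt((tt$x_um - grid$x_um[gi])^2 +
               ((tt$slice_index - 1) * spacing - grid$y_um[gi])^2))
    })
    for (cc in c(sort(unique(cls)), "all")) {
      sel <- if (cc == "all") rep(TRUE, length(ids)) else cls == cc
      for (r in radii)
        out[[length(out) + 1L]] <- data.frame(
          grid_x_um = grid$x_um[gi], grid_y_um = grid$y_um[gi],
          element_class = cc, radius_um = r,
          fraction = mean(dmin[sel] <= r))
    }
  }
  do.call(rbind, out)
}

random_mask <- function(nr, nc, p = 0.35) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
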