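#' Label 8-connected components in a binary mask
#'
#' Wraps `EBImage::bwlabel()` (4-connected) and then merges labels that touch
#' diagonally, so that the resulting components are 8-connected. Profile
#' extraction treats diagonal pixel contact as membership in the same vessel or
#' nerve cross-section.
#'
#' @param mask Logical or 0/1 numeric matrix (rows = z, cols = x).
#' @return Integer matrix of the same dimension; background 0, components
#'   labelled 1..k in first-pixel order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  storage.mode(m) <- "double"
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal adjacencies between distinct 4-connected labels
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]      # down-right neighbours
  c2 <- lab[-1L, -nc]; d <- lab[-nr, -1L]     # up-right neighbours
  sel1 <- a > 0L & b > 0L & a != b
  sel2 <- c2 > 0L & d > 0L & c2 != d
  pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c2[sel2], d[sel2]))
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  # renumber roots consecutively, preserving first-appearance order
  remap <- integer(k)
  remap[sort(unique(root))] <- seq_along(unique(sort(root)))
  lut <- c(0L, remap[root])
  matrix(lut[lab + 1L], nrow = nr)
}
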