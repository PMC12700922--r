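# Minimal binary-mask morphology on (y, x) slice matrices. Connectivity is
# fixed at 4-neighborhood throughout, matching the measurement conventions:
# raw network masks may contain specks or holes, so chords are taken on the
# largest 4-connected component after hole filling.

# Label 4-connected components with a run-based union-find.
# Returns an integer matrix; components numbered 1..K in order of first
# appearance in raster scan (lowest y, then lowest x), 0 = background.
label_components4 <- function(mask) {
  ny <- nrow(mask)
  out <- matrix(0L, ny, ncol(mask))
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nrun <- 0L
  prev <- NULL
  runs <- vector("list", ny)
  for (y in seq_len(ny)) {
    row <- mask[y, ]
    if (!any(row)) { prev <- NULL; next }
    r <- rle(as.logical(row))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    xs <- starts[r$values]; xe <- ends[r$values]
    ids <- nrun + seq_along(xs)
    nrun <- nrun + length(xs)
    parent <- c(parent, ids)
    if (!is.null(prev)) {
      for (i in seq_along(xs)) {
        for (j in which(prev$xe >= xs[i] & prev$xs <= xe[i])) {
          ri <- find(ids[i]); rj <- find(prev$ids[j])
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    prev <- list(ids = ids, xs = xs, xe = xe)
    runs[[y]] <- prev
  }
  if (nrun == 0L) return(out)
  roots <- vapply(seq_len(nrun), find, integer(1))
  labels <- match(roots, sort(unique(roots)))
  for (y in seq_len(ny)) {
    rr <- runs[[y]]
    if (is.null(rr)) next
    for (i in seq_along(rr$ids))
      out[y, rr$xs[i]:rr$xe[i]] <- labels[rr$ids[i]]
  }
  out
}

# Largest 4-connected component (ties -> component whose first pixel comes
# earliest in raster order).
largest_component4 <- function(mask) {
  lab <- label_components4(mask)
  k <- max(lab)
  if (k == 0L) return(mask & FALSE)
  sizes <- tabulate(lab, nbins = k)
  lab == which.max(sizes)
}

# Fill interior holes: background 4-components not touching the matrix border
# become foreground.
fill_holes4 <- function(mask) {
  lab <- label_components4(!mask)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  mask | (lab != 0L & !(lab %in% border))
}

# Largest component, holes filled: the mask actually measured.
clean_mask <- function(mask) {
  if (!any(mask)) return(mask)
  fill_holes4(largest_component4(mask))
}

# Foreground pixels with at least one 4-neighbor outside the mask (matrix
# edges count as outside). Returns an n x 2 matrix of (y, x) indices.
boundary_pixels4 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- mask
  core <- pad[2:(ny + 1L), 2:(nx + 1L)]
  nb <- pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
        pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  which(core & !nb, arr.ind = TRUE)
}
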