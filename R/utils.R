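# Internal geometry helpers shared by the density filter, cluster selection
# and fiducial identification. All distances in nm.

# Index pairs (i < j) of points closer than r, found with a cell list so that
# dense local neighbourhoods do not force an O(n^2) scan of the whole field.
neighbor_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  cx <- floor(x / r)
  cy <- floor(y / r)
  key <- paste(cx, cy, sep = ",")
  cells <- split(seq_len(n), key)
  out_i <- vector("list", 0L)
  out_j <- vector("list", 0L)
  r2 <- r * r
  for (cell in names(cells)) {
    idx <- cells[[cell]]
    cc <- as.integer(strsplit(cell, ",", fixed = TRUE)[[1L]])
    # same cell: all pairs
    if (length(idx) > 1L) {
      prs <- utils::combn(idx, 2L)
      d2 <- (x[prs[1L, ]] - x[prs[2L, ]])^2 + (y[prs[1L, ]] - y[prs[2L, ]])^2
      keep <- d2 <= r2
      out_i[[length(out_i) + 1L]] <- prs[1L, keep]
      out_j[[length(out_j) + 1L]] <- prs[2L, keep]
    }
    # half the neighbouring cells, so each cell pair is visited once
    for (off in list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))) {
      nb <- paste(cc[1L] + off[1L], cc[2L] + off[2L], sep = ",")
      jdx <- cells[[nb]]
      if (is.null(jdx)) next
      g <- expand.grid(i = idx, j = jdx)
      d2 <- (x[g$i] - x[g$j])^2 + (y[g$i] - y[g$j])^2
      keep <- d2 <= r2
      if (any(keep)) {
        ii <- pmin(g$i[keep], g$j[keep])
        jj <- pmax(g$i[keep], g$j[keep])
        out_i[[length(out_i) + 1L]] <- ii
        out_j[[length(out_j) + 1L]] <- jj
      }
    }
  }
  ii <- unlist(out_i, use.names = FALSE)
  jj <- unlist(out_j, use.names = FALSE)
  if (is.null(ii)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  cbind(i = ii, j = jj)
}

# Number of neighbours within r for every point (point itself excluded).
neighbor_counts <- function(x, y, r) {
  n <- length(x)
  cnt <- integer(n)
  prs <- neighbor_pairs(x, y, r)
  if (nrow(prs) > 0L) {
    t1 <- tabulate(prs[, 1L], nbins = n)
    t2 <- tabulate(prs[, 2L], nbins = n)
    cnt <- t1 + t2
  }
  cnt
}

# Connected components under the relation "closer than r" (single linkage).
# Returns an integer membership vector.
link_components <- function(x, y, r) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  prs <- neighbor_pairs(x, y, r)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(prs) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(prs)))
  }
  igraph::components(g)$membership
}

# Centered running mean with shrinking windows at the edges.
running_mean <- function(v, window) {
  if (window <= 1L) return(v)
  half <- window %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Two-pass connected-component labelling of a logical matrix (4-connectivity).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # edges between vertically / horizontally adjacent foreground pixels
  m <- matrix(NA_integer_, nrow(mask), ncol(mask))
  m[idx] <- seq_along(idx)
  e <- list()
  down <- idx[rr < nr]
  down <- down[mask[down + 1L]]
  if (length(down)) e[[1L]] <- cbind(m[down], m[down + 1L])
  right <- idx[cc < ncol(mask)]
  right <- right[mask[right + nr]]
  if (length(right)) e[[2L]] <- cbind(m[right], m[right + nr])
  edges <- do.call(rbind, e)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  memb <- igraph::components(g)$membership
  lab[idx] <- memb
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
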