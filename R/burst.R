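#' Render detections as a pointillist density image
#'
#' Each detection is drawn as a unit-integral 2D Gaussian (sigma = 10 nm by
#' convention) on a fine pixel grid, so the image integrates to the number
#' of detections and its values are local detection densities.
#'
#' @param detections data.frame with `x_nm`, `y_nm`.
#' @param sigma_nm Rendering kernel SD.
#' @param pixel_nm Rendering pixel size; must not exceed `sigma_nm` so the
#'   kernel is resolved.
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)` in nm; defaults to
#'   the detection bounding box padded by `4 sigma`.
#' @return Numeric matrix (row = y, column = x) with attributes
#'   `pixel_nm` and `origin_nm`; `sum(img) * pixel_nm^2` equals the number
#'   of detections inside the bounds (up to kernel tail truncation).
#' @export
render_pointillist <- function(detections, sigma_nm = 10, pixel_nm = 5,
                               bounds = NULL) {
  stopifnot(pixel_nm <= sigma_nm, pixel_nm > 0)
  n <- nrow(detections)
  if (is.null(bounds)) {
    # pad by the discrete kernel support so no mass is clipped at the edges
    pad <- (ceiling(4 * sigma_nm / pixel_nm) + 1L) * pixel_nm
    if (n == 0L) bounds <- c(0, 100, 0, 100)
    else bounds <- c(min(detections$x_nm) - pad, max(detections$x_nm) + pad,
                     min(detections$y_nm) - pad, max(detections$y_nm) + pad)
  }
  nx <- max(1L, ceiling((bounds[2L] - bounds[1L]) / pixel_nm))
  ny <- max(1L, ceiling((bounds[4L] - bounds[3L]) / pixel_nm))
  img <- matrix(0, ny, nx)
  if (n > 0L) {
    # bin detections, then blur with a separable unit-sum Gaussian kernel
    ix <- pmin(pmax(floor((detections$x_nm - bounds[1L]) / pixel_nm), 0L), nx - 1L)
    iy <- pmin(pmax(floor((detections$y_nm - bounds[3L]) / pixel_nm), 0L), ny - 1L)
    counts <- table(factor(iy * nx + ix, levels = 0:(nx * ny - 1L)))
    img <- matrix(as.numeric(counts), ny, nx, byrow = TRUE)
    half <- ceiling(4 * sigma_nm / pixel_nm)
    k <- exp(-((-half:half) * pixel_nm)^2 / (2 * sigma_nm^2))
    k <- k / sum(k)
    img <- convolve_rows(convolve_rows(img, k), k, transpose = TRUE)
    img <- img / pixel_nm^2 # density: detections per nm^2
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "origin_nm") <- c(bounds[1L], bounds[3L])
  img
}

# 1D convolution of each row with kernel k (zero padding); transpose = TRUE
# convolves columns instead.
convolve_rows <- function(img, k, transpose = FALSE) {
  if (transpose) return(t(convolve_rows(t(img), k)))
  half <- (length(k) - 1L) %/% 2L
  nc <- ncol(img)
  out <- matrix(0, nrow(img), nc)
  for (o in -half:half) {
    w <- k[o + half + 1L]
    src <- seq_len(nc) - o
    ok <- src >= 1L & src <= nc
    out[, ok] <- out[, ok] + w * img[, src[ok]]
  }
  out
}

#' Density filter: remove isolated single detections
#'
#' Keeps detections that have at least `min_neighbors` other detections
#' within `radius_nm`, pooling all frames. This removes the background of
#' spurious single localizations before cluster selection. Order
#' preserving.
#'
#' @param detections data.frame with `x_nm`, `y_nm`.
#' @param radius_nm Neighbourhood radius.
#' @param min_neighbors Minimum number of neighbours (excluding self).
#' @return The filtered data.frame (attribute `n_removed`).
#' @export
density_filter <- function(detections, radius_nm = 50, min_neighbors = 3L) {
  stopifnot(radius_nm > 0)
  if (nrow(detections) == 0L) return(detections)
  cnt <- neighbor_counts(detections$x_nm, detections$y_nm, radius_nm)
  keep <- cnt >= min_neighbors
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Select detection clusters for burst counting
#'
#' Single-linkage connected components (linking distance
#' `max_diameter_nm / 2`) of the density-filtered detections become
#' candidate clusters if their spatial extent (maximal pairwise distance)
#' is at most `max_diameter_nm` and they hold at least `min_detections`
#' detections. A circular mask of `mask_diameter_nm` centered on the
#' component centroid then collects *all* detections inside it from the
#' original table (including ones removed by the density filter) as
#' cluster members. Pairs of clusters with overlapping masks are ambiguous
#' and both are discarded (counted in the QC report).
#'
#' @param filtered Density-filtered detections (drives cluster discovery).
#' @param detections Full detection table (mask membership); defaults to
#'   `filtered`.
#' @param max_diameter_nm Maximal cluster extent (100 nm).
#' @param min_detections Minimal detections per candidate cluster (9).
#' @param mask_diameter_nm Mask diameter: 120 nm for a Dendra2-like tag,
#'   150 nm for mEos2. Must be >= `max_diameter_nm`.
#' @return list of class `cluster_set`: `clusters` (list of data.frames of
#'   member detections), `centroids` (data.frame `cluster_id`, `x_nm`,
#'   `y_nm`, `n_detections`), and `qc` (list with `n_candidates`,
#'   `n_discarded_overlap`, `n_oversize`, `n_undersize`).
#' @export
select_clusters <- function(filtered, detections = filtered,
                            max_diameter_nm = 100, min_detections = 9L,
                            mask_diameter_nm = 120) {
  stopifnot(mask_diameter_nm >= max_diameter_nm)
  qc <- list(n_candidates = 0L, n_discarded_overlap = 0L,
             n_oversize = 0L, n_undersize = 0L)
  empty <- structure(list(clusters = list(),
                          centroids = data.frame(cluster_id = integer(0),
                                                 x_nm = numeric(0), y_nm = numeric(0),
                                                 n_detections = integer(0)),
                          qc = qc), class = "cluster_set")
  if (nrow(filtered) == 0L) return(empty)
  memb <- link_components(filtered$x_nm, filtered$y_nm, max_diameter_nm / 2)
  cent <- NULL
  for (m in sort(unique(memb))) {
    idx <- which(memb == m)
    if (length(idx) < min_detections) {
      qc$n_undersize <- qc$n_undersize + 1L
      next
    }
    xs <- filtered$x_nm[idx]; ys <- filtered$y_nm[idx]
    # maximal pairwise distance; components are small, so this is cheap
    ext2 <- max(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
    if (ext2 > max_diameter_nm^2) {
      qc$n_oversize <- qc$n_oversize + 1L
      next
    }
    cent <- rbind(cent, c(mean(xs), mean(ys)))
  }
  if (is.null(cent)) return(empty)
  qc$n_candidates <- nrow(cent)
  # discard pairs of clusters whose masks overlap (ambiguous assignment)
  keep <- rep(TRUE, nrow(cent))
  if (nrow(cent) > 1L) {
    prs <- neighbor_pairs(cent[, 1L], cent[, 2L], mask_diameter_nm)
    if (nrow(prs) > 0L) keep[unique(as.vector(prs))] <- FALSE
  }
  qc$n_discarded_overlap <- sum(!keep)
  cent <- cent[keep, , drop = FALSE]
  clusters <- vector("list", nrow(cent))
  r2 <- (mask_diameter_nm / 2)^2
  for (i in seq_len(nrow(cent))) {
    inmask <- (detections$x_nm - cent[i, 1L])^2 +
      (detections$y_nm - cent[i, 2L])^2 <= r2
    mem <- detections[inmask, , drop = FALSE]
    mem <- mem[order(mem$frame), , drop = FALSE]
    rownames(mem) <- NULL
    clusters[[i]] <- mem
  }
  centroids <- data.frame(cluster_id = seq_len(nrow(cent)),
                          x_nm = cent[, 1L], y_nm = cent[, 2L],
                          n_detections = vapply(clusters, nrow, integer(1)))
  structure(list(clusters = clusters, centroids = centroids, qc = qc),
            class = "cluster_set")
}

#' Segment a detection time trace into bursts
#'
#' Scans the detection frames in order; a gap longer than
#' `tau_bleach_frames` between successive detections starts a new burst
#' (a new photoconversion event), while shorter gaps stay within the
#' current burst.
#'
#' @param frames Integer vector of detection frames (any order).
#' @param tau_bleach_frames The bleaching window.
#' @return list with `bursts` (data.frame `start_frame`, `end_frame`,
#'   `n_detections`) and `k` (burst count; 0 for an empty trace).
#' @examples
#' segment_bursts(c(10:20, 300:310), 250)$k # 2
#' @export
segment_bursts <- function(frames, tau_bleach_frames) {
  stopifnot(tau_bleach_frames >= 1)
  if (length(frames) == 0L) {
    return(list(bursts = data.frame(start_frame = integer(0),
                                    end_frame = integer(0),
                                    n_detections = integer(0)),
                k = 0L))
  }
  fr <- sort(as.integer(frames))
  newburst <- c(TRUE, diff(fr) > tau_bleach_frames)
  bid <- cumsum(newburst)
  bursts <- data.frame(
    start_frame = tapply(fr, bid, min),
    end_frame = tapply(fr, bid, max),
    n_detections = as.integer(tapply(fr, bid, length))
  )
  rownames(bursts) <- NULL
  list(bursts = bursts, k = max(bid))
}

#' Build a burst-count histogram from selected clusters
#'
#' Applies [segment_bursts()] to every cluster's time trace and tallies
#' the burst counts k. Also computes the recording-wide mean number of
#' detections per burst (total detections in all bursts divided by the
#' total number of bursts), the `n` of the counting equation `N = x/(n p)`.
#'
#' @param cluster_set A `cluster_set` from [select_clusters()], or a plain
#'   list of data.frames with a `frame` column.
#' @param tau_bleach_frames Bleaching window used for segmentation.
#' @return Object of class `burst_histogram`: list with `counts` (named
#'   integer vector, `counts[k]` = number of clusters showing k bursts,
#'   k = 1..k_max), `n_clusters`, `mean_detections_per_burst`,
#'   `tau_bleach_frames`, and `k` (per-cluster burst counts).
#' @export
build_histogram <- function(cluster_set, tau_bleach_frames) {
  clusters <- if (inherits(cluster_set, "cluster_set")) cluster_set$clusters
              else cluster_set
  stopifnot(length(clusters) >= 1L)
  ks <- integer(length(clusters))
  tot_det <- 0L
  tot_bursts <- 0L
  for (i in seq_along(clusters)) {
    seg <- segment_bursts(clusters[[i]]$frame, tau_bleach_frames)
    ks[i] <- seg$k
    tot_det <- tot_det + sum(seg$bursts$n_detections)
    tot_bursts <- tot_bursts + seg$k
  }
  ks <- ks[ks > 0L]
  counts <- tabulate(ks, nbins = max(ks))
  names(counts) <- seq_along(counts)
  structure(list(counts = counts,
                 n_clusters = length(ks),
                 mean_detections_per_burst = tot_det / tot_bursts,
                 tau_bleach_frames = as.integer(tau_bleach_frames),
                 k = ks),
            class = "burst_histogram")
}

#' Burst histogram from observed frequencies
#'
#' Wraps a plain vector of frequencies (x_k for k = 1..k_max) as a
#' `burst_histogram`, e.g. when transcribing a published table.
#'
#' @param counts Numeric vector; `counts[k]` is the number of clusters
#'   with k bursts.
#' @param tau_bleach_frames Bleaching window the counts were obtained with.
#' @param mean_detections_per_burst Optional recording mean.
#' @export
burst_histogram <- function(counts, tau_bleach_frames = NA_integer_,
                            mean_detections_per_burst = NA_real_) {
  stopifnot(all(counts >= 0), length(counts) >= 1L)
  counts <- as.numeric(counts)
  names(counts) <- seq_along(counts)
  structure(list(counts = counts, n_clusters = sum(counts),
                 mean_detections_per_burst = mean_detections_per_burst,
                 tau_bleach_frames = tau_bleach_frames,
                 k = rep(seq_along(counts), times = round(counts))),
            class = "burst_histogram")
}

#' @export
print.burst_histogram <- function(x, ...) {
  cat(sprintf("<burst_histogram> %d clusters, tau = %s frames, n per burst = %.1f\n",
              x$n_clusters, format(x$tau_bleach_frames),
              x$mean_detections_per_burst))
  print(x$counts)
  invisible(x)
}

#' Full burst-counting stage: localization table to burst histogram
#'
#' The counting front end applied to a drift-corrected localization table:
#' density filtering, cluster selection, mask superposition, burst
#' segmentation, histogram. Fiducial detections (logical column
#' `is_fiducial`, if present) are excluded first.
#'
#' @param detections Localization data.frame (`frame`, `x_nm`, `y_nm`).
#' @param tau_bleach_frames Bleaching window (frames).
#' @param mask_diameter_nm Cluster mask diameter (120 or 150 nm).
#' @param max_diameter_nm,min_detections Cluster selection thresholds.
#' @param filter_radius_nm,filter_min_neighbors Density filter parameters.
#' @return list with `histogram` (`burst_histogram`), `clusters`
#'   (`cluster_set`) and `qc`.
#' @export
count_bursts <- function(detections, tau_bleach_frames = 250L,
                         mask_diameter_nm = 120,
                         max_diameter_nm = 100, min_detections = 9L,
                         filter_radius_nm = 50, filter_min_neighbors = 3L) {
  if (!is.null(detections$is_fiducial)) {
    detections <- detections[!detections$is_fiducial, , drop = FALSE]
  }
  if (!is.null(detections$kind)) {
    detections <- detections[detections$kind != "fiducial", , drop = FALSE]
  }
  filtered <- density_filter(detections, filter_radius_nm, filter_min_neighbors)
  cs <- select_clusters(filtered, detections, max_diameter_nm,
                        min_detections, mask_diameter_nm)
  if (length(cs$clusters) == 0L) {
    stop("no clusters selected; nothing to count")
  }
  hist <- build_histogram(cs, tau_bleach_frames)
  list(histogram = hist, clusters = cs,
       qc = c(cs$qc, n_filtered_out = attr(filtered, "n_removed")))
}

#' Burst histogram from simulator ground truth
#'
#' Groups detections by their ground-truth complex, bypassing spatial
#' cluster selection. Useful for validating the statistical stages in
#' isolation from the spatial ones.
#'
#' @param sim A `photophysics_sim`.
#' @param tau_bleach_frames Bleaching window; defaults to the simulated
#'   one.
#' @return A `burst_histogram`.
#' @export
histogram_from_truth <- function(sim, tau_bleach_frames = sim$cfg$tau_bleach_frames) {
  det <- sim$detections
  det <- det[det$kind == "complex", , drop = FALSE]
  traces <- split(det[, c("frame", "x_nm", "y_nm")], det$complex_id)
  build_histogram(traces, tau_bleach_frames)
}
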