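#' Detect candidate spots in a single frame
#'
#' Local maxima above `background mean + threshold_sd * background SD`
#' (robust background statistics: median and MAD over the frame), followed
#' by non-maximum suppression within one PSF width.
#'
#' @param frame_image Numeric matrix (row = y, column = x) of camera counts.
#' @param threshold_sd Detection threshold in background SDs.
#' @param psf_sigma_px PSF width in pixels, used as the suppression radius.
#' @return data.frame with columns `x_px`, `y_px` (pixel-center
#'   coordinates, so pixel (r, c) is at x = c - 0.5, y = r - 0.5) and
#'   `value`.
#' @export
detect_spots <- function(frame_image, threshold_sd = 5, psf_sigma_px = 1.5) {
  stopifnot(is.matrix(frame_image), threshold_sd > 0)
  if (any(frame_image >= 65535)) {
    warning("saturated pixels in frame; candidates may be inaccurate")
  }
  bg_mean <- median(frame_image)
  bg_sd <- mad(frame_image)
  if (bg_sd == 0) bg_sd <- sd(frame_image)
  if (is.na(bg_sd) || bg_sd == 0) bg_sd <- 1
  thr <- bg_mean + threshold_sd * bg_sd
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  cand <- which(frame_image > thr)
  if (length(cand) == 0L) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0), value = numeric(0)))
  }
  rr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  # strict local maximum over the 8-neighbourhood (edge pixels excluded)
  is_max <- vapply(seq_along(cand), function(k) {
    r <- rr[k]; c <- cc[k]
    if (r <= 1L || r >= nr || c <= 1L || c >= nc) return(FALSE)
    v <- frame_image[r, c]
    nb <- frame_image[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
    v >= max(nb) && sum(nb == v) <= 1L
  }, logical(1))
  rr <- rr[is_max]; cc <- cc[is_max]
  vals <- frame_image[cbind(rr, cc)]
  if (length(vals) == 0L) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0), value = numeric(0)))
  }
  # greedy non-maximum suppression within one PSF width
  o <- order(vals, decreasing = TRUE)
  keep <- logical(length(o))
  for (k in o) {
    if (any(keep & (cc - cc[k])^2 + (rr - rr[k])^2 < psf_sigma_px^2)) next
    keep[k] <- TRUE
  }
  data.frame(x_px = cc[keep] - 0.5, y_px = rr[keep] - 0.5,
             value = vals[keep])
}

#' Fit a symmetric 2D Gaussian to a candidate spot
#'
#' Least-squares fit of `A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2)) + b`
#' over a square window centered on the candidate. Failures (window outside
#' the frame, vanishing amplitude, non-convergence) are flagged, not
#' dropped.
#'
#' @param frame_image Numeric matrix of camera counts.
#' @param candidate One row of [detect_spots()] output (needs `x_px`,
#'   `y_px`).
#' @param window_px Half-width of the fitting window in pixels.
#' @return One-row data.frame: `x_px`, `y_px`, `sigma_px`, `amplitude`,
#'   `offset`, `ok` (logical), `reason`.
#' @export
fit_gaussian2d <- function(frame_image, candidate, window_px = 3L) {
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  c0 <- round(candidate$x_px + 0.5)
  r0 <- round(candidate$y_px + 0.5)
  reject <- function(reason) data.frame(
    x_px = NA_real_, y_px = NA_real_, sigma_px = NA_real_,
    amplitude = NA_real_, offset = NA_real_, ok = FALSE, reason = reason)
  if (length(c0) != 1L || length(r0) != 1L || is.na(c0) || is.na(r0)) {
    return(reject("no candidate"))
  }
  if (r0 - window_px < 1L || r0 + window_px > nr ||
      c0 - window_px < 1L || c0 + window_px > nc) {
    return(reject("window outside frame"))
  }
  win <- frame_image[(r0 - window_px):(r0 + window_px),
                     (c0 - window_px):(c0 + window_px)]
  xs <- (c0 - window_px):(c0 + window_px) - 0.5
  ys <- (r0 - window_px):(r0 + window_px) - 0.5
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  b0 <- min(win)
  a0 <- max(win) - b0
  if (a0 <= 0 || sd(as.vector(win)) < 1e-12) {
    return(reject("flat window"))
  }
  obj <- function(p) {
    mu <- p[4L] + p[3L] * exp(-((gx - p[1L])^2 + (gy - p[2L])^2) / (2 * p[5L]^2))
    sum((win - mu)^2)
  }
  start <- c(candidate$x_px, candidate$y_px, a0, b0, 1.3)
  fit <- tryCatch(
    optim(start, obj, method = "L-BFGS-B",
          lower = c(min(xs), min(ys), 0, -Inf, 0.3),
          upper = c(max(xs), max(ys), Inf, Inf, 2 * window_px)),
    error = function(e) NULL)
  if (is.null(fit)) return(reject("non-convergence"))
  p <- fit$par
  noise <- sd(as.vector(win - (p[4L] + p[3L] *
    exp(-((gx - p[1L])^2 + (gy - p[2L])^2) / (2 * p[5L]^2)))))
  if (p[3L] < 3 * noise) return(reject("low amplitude"))
  data.frame(x_px = p[1L], y_px = p[2L], sigma_px = p[5L],
             amplitude = p[3L], offset = p[4L], ok = TRUE, reason = "")
}

#' Localize every frame of an image stack
#'
#' Runs [detect_spots()] and [fit_gaussian2d()] over all frames and returns
#' a localization table in nm.
#'
#' @param stack `image_stack` array (`h x w x f`).
#' @param threshold_sd Spot detection threshold in background SDs.
#' @param pixel_nm Camera pixel size; defaults to the stack attribute.
#' @param psf_sigma_nm PSF width used for suppression and fit windows.
#' @param window_px Half-width of the Gaussian fit window.
#' @return data.frame `id`, `frame` (0-based), `x_nm`, `y_nm`, `sigma_nm`,
#'   `intensity`; rejected candidates are counted in
#'   `attr(, "n_rejected")`.
#' @export
localize_stack <- function(stack, threshold_sd = 5,
                           pixel_nm = attr(stack, "pixel_nm") %||% 107,
                           psf_sigma_nm = 160, window_px = 3L) {
  nf <- dim(stack)[3L]
  rows <- list()
  n_rejected <- 0L
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    cands <- detect_spots(img, threshold_sd, psf_sigma_nm / pixel_nm)
    for (k in seq_len(nrow(cands))) {
      fit <- fit_gaussian2d(img, cands[k, ], window_px)
      if (!fit$ok) {
        n_rejected <- n_rejected + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f - 1L,
        x_nm = fit$x_px * pixel_nm,
        y_nm = fit$y_px * pixel_nm,
        sigma_nm = fit$sigma_px * pixel_nm,
        intensity = fit$amplitude * 2 * pi * fit$sigma_px^2
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               sigma_nm = numeric(0), intensity = numeric(0))
  out <- cbind(id = seq_len(nrow(out)), out)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Identify fiducial bead tracks in a localization table
#'
#' Emitters present in at least `min_fraction` of all frames within a
#' small radius are fiducials (photoconvertible fluorophores bleach within
#' seconds and cannot persist). Detections are grouped by single linkage at
#' `radius_nm`; groups spanning enough distinct frames become tracks.
#'
#' @param detections Localization data.frame (`frame`, `x_nm`, `y_nm`).
#' @param radius_nm Linking radius (2 camera pixels by default).
#' @param min_fraction Minimum fraction of frames a bead must appear in.
#' @param n_frames Total frames in the recording; defaults to
#'   `max(frame) + 1`.
#' @return list of data.frames (one per bead) with `frame`, `x_nm`,
#'   `y_nm`, plus attribute `member_ids` with the detection row indices
#'   belonging to fiducials. Empty list if no persistent emitter exists.
#' @export
identify_fiducials <- function(detections, radius_nm = 214, min_fraction = 0.9,
                               n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections) > 0L) max(detections$frame) + 1L else 0L
  }
  if (nrow(detections) == 0L || n_frames == 0L) return(list())
  # The movie is cut into chunks short enough that stage drift within a
  # chunk is small against the gating radius. Per chunk, candidate bead
  # positions are seeded from grid cells holding close to one detection per
  # frame (transient fluorophores contribute only tens of detections);
  # candidates are then linked across chunks by proximity, so a bead may
  # drift arbitrarily far over the whole movie yet still be followed.
  chunk_len <- max(50L, min(500L, ceiling(n_frames / 10)))
  n_chunks <- ceiling(n_frames / chunk_len)
  chunk_of <- pmin(detections$frame %/% chunk_len + 1L, n_chunks)
  per_chunk_centers <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    idx <- which(chunk_of == ch)
    if (!length(idx)) next
    this_len <- min(chunk_len, n_frames - (ch - 1L) * chunk_len)
    key <- paste(floor(detections$x_nm[idx] / radius_nm),
                 floor(detections$y_nm[idx] / radius_nm), sep = ",")
    tab <- table(key)
    seeds <- names(tab)[tab >= min_fraction * this_len / 4]
    if (!length(seeds)) next
    centers <- t(vapply(seeds, function(s) {
      ii <- idx[key == s]
      c(median(detections$x_nm[ii]), median(detections$y_nm[ii]))
    }, numeric(2)))
    # merge seeds of the same bead (adjacent cells)
    keep <- rep(TRUE, nrow(centers))
    if (nrow(centers) > 1L) {
      for (i in 2:nrow(centers)) for (j in 1:(i - 1L)) {
        if (keep[j] && sum((centers[i, ] - centers[j, ])^2) < radius_nm^2) {
          keep[i] <- FALSE
          break
        }
      }
    }
    per_chunk_centers[[ch]] <- centers[keep, , drop = FALSE]
  }
  # link chunk candidates into bead tracks by nearest neighbour
  beads <- list() # each: list(last = c(x, y), chunks = int, path = matrix)
  for (ch in seq_len(n_chunks)) {
    cen <- per_chunk_centers[[ch]]
    if (is.null(cen) || nrow(cen) == 0L) next
    for (i in seq_len(nrow(cen))) {
      attached <- FALSE
      for (b in seq_along(beads)) {
        if (sum((beads[[b]]$last - cen[i, ])^2) <= radius_nm^2) {
          beads[[b]]$last <- cen[i, ]
          beads[[b]]$chunks <- c(beads[[b]]$chunks, ch)
          beads[[b]]$path <- rbind(beads[[b]]$path, c(ch, cen[i, ]))
          attached <- TRUE
          break
        }
      }
      if (!attached) {
        beads[[length(beads) + 1L]] <-
          list(last = cen[i, ], chunks = ch, path = cbind(ch, cen[i, 1L], cen[i, 2L]))
      }
    }
  }
  tracks <- list()
  member_ids <- integer(0)
  for (b in beads) {
    if (length(b$chunks) < min_fraction * n_chunks) next
    # collect member detections: within radius of the bead's center in
    # their own chunk
    if (nrow(b$path) > 1L) {
      cx <- approx(b$path[, 1L], b$path[, 2L], xout = chunk_of, rule = 2)$y
      cy <- approx(b$path[, 1L], b$path[, 3L], xout = chunk_of, rule = 2)$y
    } else {
      cx <- rep(b$path[1L, 2L], length(chunk_of))
      cy <- rep(b$path[1L, 3L], length(chunk_of))
    }
    idx <- which((detections$x_nm - cx)^2 + (detections$y_nm - cy)^2 <= radius_nm^2)
    nfr <- length(unique(detections$frame[idx]))
    if (nfr < min_fraction * n_frames) next
    tr <- detections[idx, c("frame", "x_nm", "y_nm")]
    tr <- tr[order(tr$frame), ]
    rownames(tr) <- NULL
    tracks[[length(tracks) + 1L]] <- tr
    member_ids <- c(member_ids, idx)
  }
  attr(tracks, "member_ids") <- member_ids
  tracks
}

#' Correct stage drift using fiducial tracks
#'
#' The per-frame offset is the mean fiducial displacement from the
#' reference (first) frame, linearly interpolated over frame gaps and
#' smoothed with a centered running mean. The offset is subtracted from
#' every detection. Fiducial detections themselves are flagged so that
#' downstream counting can exclude them.
#'
#' @param detections Localization data.frame.
#' @param fiducial_tracks Output of [identify_fiducials()].
#' @param smooth_window Running-mean window in frames (drift is slow
#'   compared to the 20 Hz acquisition; 50 frames = 2.5 s).
#' @param n_frames Total frames; defaults to `max(frame) + 1`.
#' @return list with `detections` (drift-corrected, with logical column
#'   `is_fiducial`) and `drift` (data.frame `frame`, `dx_nm`, `dy_nm`,
#'   zero at the reference frame). With zero fiducials the input is
#'   returned unchanged and a message is emitted.
#' @export
correct_drift <- function(detections, fiducial_tracks, smooth_window = 50L,
                          n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections) > 0L) max(detections$frame) + 1L else 0L
  }
  det <- detections
  det$is_fiducial <- FALSE
  ids <- attr(fiducial_tracks, "member_ids")
  if (!is.null(ids) && length(ids)) det$is_fiducial[ids] <- TRUE
  if (length(fiducial_tracks) == 0L) {
    message("no fiducials found; drift correction disabled")
    drift <- data.frame(frame = seq_len(n_frames) - 1L, dx_nm = 0, dy_nm = 0)
    return(list(detections = det, drift = drift))
  }
  frames <- 0:(n_frames - 1L)
  offs <- lapply(fiducial_tracks, function(tr) {
    dx <- tr$x_nm - tr$x_nm[1L]
    dy <- tr$y_nm - tr$y_nm[1L]
    gap <- length(tr$frame) < n_frames
    dxi <- approx(tr$frame, dx, xout = frames, rule = 2)$y
    dyi <- approx(tr$frame, dy, xout = frames, rule = 2)$y
    if (gap) message("fiducial track has frame gaps; drift linearly interpolated")
    cbind(dxi, dyi)
  })
  dx <- rowMeans(do.call(cbind, lapply(offs, function(o) o[, 1L])))
  dy <- rowMeans(do.call(cbind, lapply(offs, function(o) o[, 2L])))
  dx <- running_mean(dx, smooth_window)
  dy <- running_mean(dy, smooth_window)
  dx <- dx - dx[1L]
  dy <- dy - dy[1L]
  det$x_nm <- det$x_nm - dx[det$frame + 1L]
  det$y_nm <- det$y_nm - dy[det$frame + 1L]
  list(detections = det,
       drift = data.frame(frame = frames, dx_nm = dx, dy_nm = dy))
}
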