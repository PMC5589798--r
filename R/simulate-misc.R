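#' Simulate 2D Brownian trajectories
#'
#' Generates quantum-dot-style single-particle tracks: pure 2D Brownian
#' motion with per-step displacement variance `4 D dt` split equally over x
#' and y, plus independent Gaussian localization noise on every position.
#'
#' @param n_traj Number of trajectories.
#' @param D_um2_per_s Diffusion coefficient (um^2/s), `>= 0`.
#' @param n_frames Positions per trajectory (500 in a typical recording).
#' @param frame_rate_hz Acquisition rate (13 Hz for QD tracking).
#' @param loc_error_nm Localization noise added independently to each
#'   position.
#' @param movie_id Label stored in the `movie_id` column.
#' @param seed Optional integer seed.
#'
#' @return data.frame with columns `movie_id`, `particle_id`, `frame`
#'   (0-based), `x_nm`, `y_nm` and attribute `frame_rate_hz`.
#' @examples
#' tr <- simulate_trajectories(5, 0.023, 500, 13, 20, seed = 1)
#' @export
simulate_trajectories <- function(n_traj, D_um2_per_s, n_frames = 500L,
                                  frame_rate_hz = 13, loc_error_nm = 20,
                                  movie_id = "movie1", seed = NULL) {
  stopifnot(n_traj >= 1, D_um2_per_s >= 0, n_frames >= 2, frame_rate_hz > 0,
            loc_error_nm >= 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / frame_rate_hz
  step_sd_nm <- sqrt(2 * D_um2_per_s * dt) * 1000 # per axis
  n <- n_traj * n_frames
  pid <- rep(seq_len(n_traj), each = n_frames)
  dx <- rnorm(n, 0, step_sd_nm)
  dy <- rnorm(n, 0, step_sd_nm)
  # first position of each track at the origin
  first <- !duplicated(pid)
  dx[first] <- 0
  dy[first] <- 0
  x <- stats::ave(dx, pid, FUN = cumsum)
  y <- stats::ave(dy, pid, FUN = cumsum)
  out <- data.frame(
    movie_id = movie_id,
    particle_id = pid,
    frame = rep(0:(n_frames - 1L), n_traj),
    x_nm = x + rnorm(n, 0, loc_error_nm),
    y_nm = y + rnorm(n, 0, loc_error_nm)
  )
  attr(out, "frame_rate_hz") <- frame_rate_hz
  out
}

#' Simulate a two-channel colocalization fixture
#'
#' Channel B is a `coloc_fraction`-weighted copy of channel A mixed with an
#' independent random image, plus Gaussian noise, evaluated within a central
#' mask. Used to validate the intensity correlation quotient.
#'
#' @param size Image side length in pixels.
#' @param coloc_fraction Mixing weight in `[0, 1]`: 1 makes B a copy of A,
#'   0 makes B independent of A.
#' @param noise_sd Gaussian noise added to both channels.
#' @param n_puncta Number of Gaussian puncta composing each channel.
#' @param seed Optional integer seed.
#' @return list with matrices `a`, `b` and logical matrix `mask`.
#' @export
simulate_two_channel <- function(size = 64L, coloc_fraction = 0.5,
                                 noise_sd = 0.05, n_puncta = 12L,
                                 seed = NULL) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, size >= 8)
  if (!is.null(seed)) set.seed(seed)
  puncta_image <- function() {
    img <- matrix(0, size, size)
    xs <- runif(n_puncta, 5, size - 4)
    ys <- runif(n_puncta, 5, size - 4)
    amp <- runif(n_puncta, 0.5, 1.5)
    gx <- row(img); gy <- col(img)
    for (i in seq_len(n_puncta)) {
      img <- img + amp[i] * exp(-((gx - xs[i])^2 + (gy - ys[i])^2) / (2 * 2^2))
    }
    img
  }
  a <- puncta_image()
  indep <- puncta_image()
  b <- coloc_fraction * a + (1 - coloc_fraction) * indep
  if (noise_sd > 0) {
    a <- a + rnorm(length(a), 0, noise_sd)
    b <- b + rnorm(length(b), 0, noise_sd)
  }
  mask <- matrix(TRUE, size, size)
  list(a = a, b = b, mask = mask)
}

#' Render a localization table into a synthetic camera movie
#'
#' The inverse of spot localization: each detection becomes a 2D Gaussian
#' photon spot on its frame, on top of a Poisson background, with optional
#' Gaussian camera read noise, quantized to 16-bit counts. Intended to give
#' the localization stage realistic input with known ground truth.
#'
#' @param detections data.frame with `frame` (0-based), `x_nm`, `y_nm`.
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_nm Camera pixel size (107 nm on a typical EMCCD setup).
#' @param psf_sigma_nm PSF standard deviation.
#' @param photons_per_detection Expected photons per localized spot.
#' @param background Expected background photons per pixel per frame.
#' @param camera_noise_sd Gaussian read noise (counts).
#' @param poisson_noise Apply Poisson shot noise; disable for noiseless
#'   oracle images.
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @param seed Optional integer seed.
#' @return A numeric array `height_px x width_px x n_frames` of class
#'   `image_stack` (photon counts). Detections outside the field of view
#'   are clipped; their number is reported in `attr(, "n_clipped")` with a
#'   warning.
#' @export
render_frames <- function(detections, width_px = 32L, height_px = 32L,
                          pixel_nm = 107, psf_sigma_nm = 160,
                          photons_per_detection = 1000, background = 10,
                          camera_noise_sd = 0, poisson_noise = TRUE,
                          n_frames = NULL, seed = NULL) {
  stopifnot(pixel_nm > 0, psf_sigma_nm > 0, photons_per_detection > 0,
            background >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections) > 0L) max(detections$frame) + 1L else 1L
  }
  stack <- array(0, dim = c(height_px, width_px, n_frames))
  sig_px <- psf_sigma_nm / pixel_nm
  n_clipped <- 0L
  if (nrow(detections) > 0L) {
    # pixel-center coordinates: pixel (r, c) covers [(c-1), c) x [(r-1), r) px
    px <- detections$x_nm / pixel_nm
    py <- detections$y_nm / pixel_nm
    inside <- px >= 0 & px < width_px & py >= 0 & py < height_px &
      detections$frame >= 0 & detections$frame < n_frames
    n_clipped <- sum(!inside)
    if (n_clipped > 0L) {
      warning(sprintf("%d detections outside the field of view were clipped", n_clipped))
    }
    xs <- (seq_len(width_px)) - 0.5
    ys <- (seq_len(height_px)) - 0.5
    for (i in which(inside)) {
      f <- detections$frame[i] + 1L
      gx <- exp(-(xs - px[i])^2 / (2 * sig_px^2))
      gy <- exp(-(ys - py[i])^2 / (2 * sig_px^2))
      spot <- outer(gy, gx) / (2 * pi * sig_px^2)
      stack[, , f] <- stack[, , f] + photons_per_detection * spot
    }
  }
  stack <- stack + background
  dim_save <- dim(stack)
  if (poisson_noise) {
    stack <- array(rpois(length(stack), stack), dim = dim_save)
  }
  if (camera_noise_sd > 0) {
    stack <- stack + array(rnorm(length(stack), 0, camera_noise_sd), dim = dim_save)
  }
  if (poisson_noise || camera_noise_sd > 0) stack <- round(stack)
  stack <- pmin(pmax(stack, 0), 65535)
  dim(stack) <- dim_save
  attr(stack, "pixel_nm") <- pixel_nm
  attr(stack, "n_clipped") <- n_clipped
  class(stack) <- c("image_stack", class(stack))
  stack
}

#' Write / read a 16-bit multi-page TIFF image stack
#'
#' @param stack Array `h x w x f` of photon counts (0--65535).
#' @param path Output file.
#' @export
write_stack <- function(stack, path) {
  f <- dim(stack)[3L]
  pages <- lapply(seq_len(f), function(i) stack[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_nm Pixel size to attach to the stack on read.
#' @export
read_stack <- function(path, pixel_nm = 107) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- round(pages[[i]] * 65535)
  attr(stack, "pixel_nm") <- pixel_nm
  class(stack) <- c("image_stack", class(stack))
  stack
}
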