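#' Mean square displacement of a trajectory
#'
#' `rho_j` is the mean squared displacement over all (overlapping) pairs
#' of positions separated by j frames; pairs spanning frame gaps use the
#' true frame difference. Lag times are `j / frame_rate`.
#'
#' @param traj data.frame with `frame`, `x_nm`, `y_nm` for one particle.
#' @param frame_rate_hz Acquisition rate (13 Hz for QD tracking).
#' @param max_lag Largest lag (frames) to evaluate.
#' @return Object of class `msd_curve`: data.frame `lag_frames`, `tau_s`,
#'   `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(traj, frame_rate_hz = attr(traj, "frame_rate_hz") %||% 13,
                        max_lag = 10L) {
  stopifnot(nrow(traj) >= 2L, frame_rate_hz > 0)
  o <- order(traj$frame)
  fr <- traj$frame[o]
  if (any(diff(fr) <= 0)) stop("frames must be strictly increasing")
  x <- traj$x_nm[o] / 1000 # um
  y <- traj$y_nm[o] / 1000
  n <- length(fr)
  msd <- numeric(max_lag)
  cnt <- integer(max_lag)
  # accumulate by position offset, splitting by true frame difference
  for (off in seq_len(n - 1L)) {
    i <- seq_len(n - off)
    dj <- fr[i + off] - fr[i]
    ok <- dj <= max_lag
    if (!any(ok)) next
    d2 <- (x[i + off] - x[i])^2 + (y[i + off] - y[i])^2
    for (j in unique(dj[ok])) {
      sel <- ok & dj == j
      msd[j] <- msd[j] + sum(d2[sel])
      cnt[j] <- cnt[j] + sum(sel)
    }
    if (min(dj) > max_lag) break
  }
  lag <- which(cnt > 0L)
  structure(data.frame(lag_frames = lag, tau_s = lag / frame_rate_hz,
                       msd_um2 = msd[lag] / cnt[lag], n_pairs = cnt[lag]),
            class = c("msd_curve", "data.frame"),
            frame_rate_hz = frame_rate_hz)
}

#' Diffusion coefficient from the initial MSD slope
#'
#' Ordinary least squares line through the first `n_points` MSD points
#' against lag time, with a free intercept that absorbs the (static)
#' localization noise `4 sigma_loc^2`; `D = slope / 4` for 2D diffusion.
#' A negative slope is reported as `D = 0` with attribute
#' `negative_slope = TRUE`.
#'
#' @param msd An `msd_curve`.
#' @param n_points Number of initial points to fit (5 by convention).
#' @return D in um^2/s (attributes `intercept_um2`, `negative_slope`).
#' @export
fit_diffusion <- function(msd, n_points = 5L) {
  if (nrow(msd) < n_points) {
    stop(sprintf("MSD curve has %d lags; %d required", nrow(msd), n_points))
  }
  d <- msd[seq_len(n_points), ]
  fit <- lm(msd_um2 ~ tau_s, data = d)
  slope <- coef(fit)[["tau_s"]]
  D <- slope / 4
  neg <- D < 0
  if (neg) D <- 0
  attr(D, "intercept_um2") <- coef(fit)[["(Intercept)"]]
  attr(D, "negative_slope") <- neg
  D
}

#' Per-trajectory diffusion coefficients for a trajectory table
#'
#' @param trajectories data.frame `movie_id`, `particle_id`, `frame`,
#'   `x_nm`, `y_nm`.
#' @param frame_rate_hz Acquisition rate.
#' @param n_points MSD points fitted per trajectory.
#' @return data.frame `movie_id`, `particle_id`, `D_um2_per_s`.
#' @export
fit_diffusion_table <- function(trajectories,
                                frame_rate_hz = attr(trajectories, "frame_rate_hz") %||% 13,
                                n_points = 5L) {
  key <- interaction(trajectories$movie_id, trajectories$particle_id, drop = TRUE)
  parts <- split(trajectories, key)
  rows <- lapply(parts, function(tr) {
    D <- tryCatch(
      fit_diffusion(compute_msd(tr, frame_rate_hz, max_lag = n_points), n_points),
      error = function(e) NA_real_)
    data.frame(movie_id = tr$movie_id[1L], particle_id = tr$particle_id[1L],
               D_um2_per_s = as.numeric(D))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[complete.cases(out), , drop = FALSE]
}

#' Summarize diffusion per movie
#'
#' Statistical comparisons between conditions use the median D of each
#' movie as the experimental unit; the pooled empirical CDF over all
#' trajectories serves for plotting.
#'
#' @param d_table Output of [fit_diffusion_table()].
#' @return list of class `spt_summary`: `per_movie` (data.frame
#'   `movie_id`, `median_D`, `n_traj`), `pooled_D` (all trajectory Ds),
#'   `cdf` (function).
#' @export
summarize_movies <- function(d_table) {
  stopifnot(nrow(d_table) >= 1L)
  sp <- split(d_table$D_um2_per_s, d_table$movie_id)
  per_movie <- data.frame(
    movie_id = names(sp),
    median_D = vapply(sp, median, numeric(1)),
    n_traj = vapply(sp, length, integer(1))
  )
  rownames(per_movie) <- NULL
  structure(list(per_movie = per_movie, pooled_D = d_table$D_um2_per_s,
                 cdf = ecdf(d_table$D_um2_per_s)),
            class = "spt_summary")
}

#' @export
print.spt_summary <- function(x, ...) {
  cat(sprintf("<spt_summary> %d movies, %d trajectories, pooled median D = %.4f um^2/s\n",
              nrow(x$per_movie), length(x$pooled_D), median(x$pooled_D)))
  invisible(x)
}
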