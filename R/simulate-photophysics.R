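#' Photophysics configuration for the burst simulator
#'
#' Bundles and validates the parameters of the single-fluorophore burst
#' model. Defaults describe a Dendra2-like photoconvertible tag imaged at
#' 20 Hz over a 20000-frame movie: each tagged subunit is
#' fluorescent-and-detectable with probability `p_det` (a single compound
#' Bernoulli covering fluorophore misfolding and replacement by untagged
#' endogenous subunits), converts once at a random frame drawn from a
#' cumulative conversion schedule that completes before the end of the
#' movie, and then emits a burst of detections whose total count is
#' 1 + Poisson(`mean_detections_per_burst` - 1).
#'
#' Within a burst, successive detections are separated by short geometric
#' frame gaps (mean `gap_mean_frames`); in addition a fluorophore enters a
#' long-lived dark state at most once per burst, inserting a geometric dark
#' gap with mean `tau_bleach_frames`. The probability of the long dark
#' state is calibrated (see [calibrate_long_dark()]) so that 95% of bursts
#' span at most `tau_bleach_frames` -- the operational definition of the
#' bleaching window used to segment bursts. The remaining 5% reproduce the
#' occasional fluorophore whose burst is split by the cutoff (overcounting),
#' which in real recordings partially offsets the merging of two
#' fluorophores converting within the same window (undercounting).
#'
#' @param p_det Per-subunit detection probability in (0, 1].
#' @param mean_detections_per_burst Mean detections emitted per fluorophore
#'   (13--19 in typical recordings).
#' @param tau_bleach_frames Bleaching window in frames: 250 for a
#'   Dendra2-like tag at 20 Hz (12.5 s), 1200 for an mEos2-like tag (60 s).
#' @param frame_rate_hz Acquisition rate.
#' @param n_frames Movie length in frames.
#' @param loc_error_nm Isotropic Gaussian localization error.
#' @param drift_nm_per_frame Length-2 numeric, linear stage drift per frame.
#' @param conversion_end_fraction Fraction of the movie by which the
#'   cumulative conversion probability reaches 1 (photoconversion ramps up
#'   so that all fluorophores are converted before the last bleaching
#'   window).
#' @param gap_mean_frames Mean short (within-burst) frame gap.
#' @param span_quantile Probability with which a burst must complete within
#'   `tau_bleach_frames`; fixed at 0.95 by the operational definition of the
#'   bleaching window but exposed for sensitivity checks.
#' @param n_fiducials Number of always-on fiducial beads in the field.
#' @param fiducial_error_nm Localization error of the (bright) beads.
#' @param noise_detections Expected number of spurious isolated single
#'   detections over the whole movie (removed downstream by the density
#'   filter).
#'
#' @return A list of class `photophysics_config`.
#' @export
photophysics_config <- function(p_det = 0.44,
                                mean_detections_per_burst = 16,
                                tau_bleach_frames = 250L,
                                frame_rate_hz = 20,
                                n_frames = 20000L,
                                loc_error_nm = 15,
                                drift_nm_per_frame = c(0, 0),
                                conversion_end_fraction = 0.9,
                                gap_mean_frames = 3,
                                span_quantile = 0.95,
                                n_fiducials = 0L,
                                fiducial_error_nm = 2,
                                noise_detections = 0) {
  stopifnot(p_det > 0, p_det <= 1,
            mean_detections_per_burst >= 1,
            tau_bleach_frames >= 1, n_frames > tau_bleach_frames,
            frame_rate_hz > 0, loc_error_nm >= 0,
            length(drift_nm_per_frame) == 2L,
            conversion_end_fraction > 0, conversion_end_fraction <= 1,
            gap_mean_frames >= 1, span_quantile > 0, span_quantile < 1,
            n_fiducials >= 0, noise_detections >= 0)
  # conversion must be complete before the last bleaching window so the
  # final burst can still be observed in full
  if (conversion_end_fraction * n_frames > n_frames - tau_bleach_frames) {
    conversion_end_fraction <- (n_frames - tau_bleach_frames) / n_frames
  }
  structure(list(
    p_det = p_det,
    mean_detections_per_burst = mean_detections_per_burst,
    tau_bleach_frames = as.integer(tau_bleach_frames),
    frame_rate_hz = frame_rate_hz,
    n_frames = as.integer(n_frames),
    loc_error_nm = loc_error_nm,
    drift_nm_per_frame = as.numeric(drift_nm_per_frame),
    conversion_end_fraction = conversion_end_fraction,
    gap_mean_frames = gap_mean_frames,
    span_quantile = span_quantile,
    n_fiducials = as.integer(n_fiducials),
    fiducial_error_nm = fiducial_error_nm,
    noise_detections = noise_detections
  ), class = "photophysics_config")
}

#' Calibrate the long-dark-state probability of the burst model
#'
#' Computes, without simulation, the probability `p_long` with which a burst
#' must contain one long geometric dark gap (mean `tau_bleach_frames`) so
#' that the burst span (first to last detection) stays within
#' `tau_bleach_frames` with probability `span_quantile`. The short-gap span
#' is a Poisson mixture of shifted negative binomials, so both terms of the
#' calibration equation have closed forms.
#'
#' @param mean_detections Mean detections per burst.
#' @param gap_mean_frames Mean short frame gap.
#' @param tau_bleach_frames Bleaching window (frames).
#' @param span_quantile Required P(span <= tau), default 0.95.
#' @return `p_long` in `[0, 1]`.
#' @export
calibrate_long_dark <- function(mean_detections, gap_mean_frames,
                                tau_bleach_frames, span_quantile = 0.95) {
  tau <- as.integer(tau_bleach_frames)
  g <- gap_mean_frames
  mu <- mean_detections - 1
  dmax <- max(20L, ceiling(mu + 10 * sqrt(max(mu, 1))))
  wd <- dpois(0:dmax, mu) # P(ndet = d + 1)
  # cdf of the short span S at integer t: S = d + NB(d, 1/g) given d gaps
  span_cdf <- function(t) {
    if (t < 0) return(0)
    d <- 0:dmax
    p <- ifelse(d == 0, 1, pnbinom(pmax(t - d, -1), size = pmax(d, 1), prob = 1 / g))
    p[d > t] <- 0
    p[1L] <- 1 # zero gaps: span 0
    sum(wd * p)
  }
  A <- span_cdf(tau)
  if (A <= span_quantile) {
    warning("short-gap spans alone exceed the bleaching window; p_long = 0")
    return(0)
  }
  # with one long gap L ~ Geom(prob = 1/tau): P(S + L <= tau)
  l <- 0:tau
  wl <- dgeom(l, prob = 1 / tau)
  Fs <- vapply(tau - l, span_cdf, numeric(1))
  B <- sum(wl * Fs)
  p_long <- (A - span_quantile) / (A - B)
  min(max(p_long, 0), 1)
}

#' Simulate single-fluorophore detection bursts over a complex field
#'
#' The core generative model behind the counting pipeline. Every tagged
#' subunit of every complex is independently fluorescent with probability
#' `p_det`; each fluorescent fluorophore photoconverts once, at a frame
#' drawn from a linear cumulative conversion schedule, and then emits a
#' burst of localized detections (see [photophysics_config()] for the burst
#' model). Detections carry isotropic Gaussian localization error and
#' cumulative linear stage drift. Optional fiducial beads emit in every
#' frame; optional spurious single detections model background noise.
#'
#' @param field A `complex_field` from [simulate_complex_field()].
#' @param cfg A `photophysics_config`.
#' @param seed Optional integer seed; output is deterministic given it.
#'
#' @return A list of class `photophysics_sim` with elements
#'   `detections` (data.frame: `id`, `frame` (0-based), `x_nm`, `y_nm`,
#'   `sigma_nm`, `intensity`, `fluor_id`, `complex_id`, `kind`),
#'   `truth` (list: `complexes` with per-complex fluorophore counts,
#'   `fluors` with per-fluorophore conversion frame and detection count,
#'   `p_long`), and the `cfg` used.
#' @export
simulate_photophysics <- function(field, cfg = photophysics_config(), seed = NULL) {
  stopifnot(inherits(field, "complex_field"), inherits(cfg, "photophysics_config"))
  if (!is.null(seed)) set.seed(seed)

  cx <- field$complexes
  n_complex <- nrow(cx)
  tagged <- rep.int(cx$complex_id, cx$n_tagged)
  n_tag <- length(tagged)
  fluorescent <- runif(n_tag) < cfg$p_det
  fluors <- data.frame(
    fluor_id = seq_len(n_tag),
    complex_id = tagged,
    fluorescent = fluorescent,
    conv_frame = NA_integer_,
    n_detections = 0L
  )

  conv_end <- floor(cfg$conversion_end_fraction * cfg$n_frames)
  idx_f <- which(fluorescent)
  nf <- length(idx_f)
  p_long <- calibrate_long_dark(cfg$mean_detections_per_burst,
                                cfg$gap_mean_frames,
                                cfg$tau_bleach_frames,
                                cfg$span_quantile)

  det_list <- NULL
  if (nf > 0L) {
    conv <- floor(runif(nf, 0, conv_end))
    ndet <- 1L + rpois(nf, cfg$mean_detections_per_burst - 1)
    has_long <- runif(nf) < p_long
    total_gaps <- sum(ndet - 1L)
    all_gaps <- 1L + rgeom(total_gaps, prob = 1 / cfg$gap_mean_frames)
    gidx <- rep.int(seq_len(nf), ndet - 1L)
    gaps <- split(all_gaps, factor(gidx, levels = seq_len(nf)))
    frames <- vector("list", nf)
    for (i in seq_len(nf)) {
      gi <- gaps[[i]]
      if (has_long[i] && length(gi) > 0L) {
        at <- sample.int(length(gi), 1L)
        gi[at] <- gi[at] + rgeom(1L, prob = 1 / cfg$tau_bleach_frames)
      }
      fr <- conv[i] + cumsum(c(0L, gi))
      frames[[i]] <- fr[fr < cfg$n_frames]
    }
    nkept <- lengths(frames)
    fluors$conv_frame[idx_f] <- conv
    fluors$n_detections[idx_f] <- nkept
    fid <- rep.int(idx_f, nkept)
    comp <- fluors$complex_id[fid]
    n_det <- length(fid)
    det_list <- data.frame(
      frame = unlist(frames, use.names = FALSE),
      x_nm = cx$x_nm[comp] + rnorm(n_det, 0, cfg$loc_error_nm),
      y_nm = cx$y_nm[comp] + rnorm(n_det, 0, cfg$loc_error_nm),
      sigma_nm = pmax(rnorm(n_det, 160, 15), 50),
      intensity = rpois(n_det, 500),
      fluor_id = fid,
      complex_id = comp,
      kind = rep("complex", n_det)
    )
  }

  # fiducial beads: one localization per frame, small error, full drift
  if (cfg$n_fiducials > 0L) {
    fx <- runif(cfg$n_fiducials, 0.05, 0.95) * field$field_nm["width"]
    fy <- runif(cfg$n_fiducials, 0.05, 0.95) * field$field_nm["height"]
    for (b in seq_len(cfg$n_fiducials)) {
      fr <- 0:(cfg$n_frames - 1L)
      det_list <- rbind(det_list, data.frame(
        frame = fr,
        x_nm = fx[b] + rnorm(cfg$n_frames, 0, cfg$fiducial_error_nm),
        y_nm = fy[b] + rnorm(cfg$n_frames, 0, cfg$fiducial_error_nm),
        sigma_nm = pmax(rnorm(cfg$n_frames, 160, 5), 50),
        intensity = rpois(cfg$n_frames, 5000),
        fluor_id = NA_integer_,
        complex_id = NA_integer_,
        kind = "fiducial"
      ))
    }
  }

  if (cfg$noise_detections > 0) {
    nn <- rpois(1L, cfg$noise_detections)
    if (nn > 0L) {
      det_list <- rbind(det_list, data.frame(
        frame = sample.int(cfg$n_frames, nn, replace = TRUE) - 1L,
        x_nm = runif(nn, 0, field$field_nm["width"]),
        y_nm = runif(nn, 0, field$field_nm["height"]),
        sigma_nm = pmax(rnorm(nn, 160, 30), 50),
        intensity = rpois(nn, 300),
        fluor_id = NA_integer_,
        complex_id = NA_integer_,
        kind = "noise"
      ))
    }
  }

  if (is.null(det_list)) {
    det_list <- data.frame(frame = integer(0), x_nm = numeric(0),
                           y_nm = numeric(0), sigma_nm = numeric(0),
                           intensity = numeric(0), fluor_id = integer(0),
                           complex_id = integer(0), kind = character(0))
  }

  # cumulative linear drift
  if (any(cfg$drift_nm_per_frame != 0) && nrow(det_list) > 0L) {
    det_list$x_nm <- det_list$x_nm + det_list$frame * cfg$drift_nm_per_frame[1L]
    det_list$y_nm <- det_list$y_nm + det_list$frame * cfg$drift_nm_per_frame[2L]
  }

  det_list <- det_list[order(det_list$frame, det_list$x_nm), , drop = FALSE]
  rownames(det_list) <- NULL
  det_list$id <- seq_len(nrow(det_list))
  det_list <- det_list[, c("id", "frame", "x_nm", "y_nm", "sigma_nm",
                           "intensity", "fluor_id", "complex_id", "kind")]

  n_fluor_per_complex <- tabulate(fluors$complex_id[fluors$fluorescent],
                                  nbins = n_complex)
  truth <- list(
    complexes = cbind(cx, n_fluorescent = n_fluor_per_complex),
    fluors = fluors,
    p_long = p_long
  )
  structure(list(detections = det_list, truth = truth, cfg = cfg),
            class = "photophysics_sim")
}

#' @export
print.photophysics_sim <- function(x, ...) {
  cat(sprintf("<photophysics_sim> %d detections from %d fluorophores (%d complexes), %d frames\n",
              nrow(x$detections), sum(x$truth$fluors$fluorescent),
              nrow(x$truth$complexes), x$cfg$n_frames))
  invisible(x)
}
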