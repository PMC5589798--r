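#' Simulate a field of membrane protein complexes
#'
#' Places multimeric complexes in a rectangular membrane patch, mimicking the
#' two spatial regimes seen in localization-microscopy counting experiments:
#' a sparse extrasynaptic pool placed uniformly at a target 2D density
#' (a few complexes per square micron) and, optionally, dense synaptic
#' regions of interest, each a disc of given area holding a fixed number of
#' complexes (tens of complexes packed into 0.01--0.15 um^2).
#'
#' @param width_um,height_um Field dimensions in microns.
#' @param density_um2 Extrasynaptic complex density, complexes per um^2.
#' @param subunits_per_complex Total subunits per complex (5 for a
#'   pentameric receptor, 3 for a trimeric scaffold).
#' @param tagged_per_complex Number of subunits per complex carrying a
#'   photoconvertible tag; at most `subunits_per_complex`. Defaults to all.
#' @param synapse_areas_um2 Numeric vector of synaptic ROI areas (um^2);
#'   one circular ROI per element. Empty for a purely extrasynaptic field.
#' @param complexes_per_synapse Integer (recycled): complexes placed in each
#'   synaptic ROI.
#' @param min_separation_nm Minimum center-to-center distance between
#'   complexes inside a synaptic ROI. The default 8 nm is roughly one
#'   receptor footprint.
#' @param seed Optional integer seed; the field is deterministic given it.
#'
#' @return An object of class `complex_field`: a list with `complexes`
#'   (data.frame: `complex_id`, `x_nm`, `y_nm`, `n_tagged`, `region`,
#'   `roi`), `synapses` (data.frame: `roi`, `x_nm`, `y_nm`, `area_um2`,
#'   `radius_nm`) and `field_nm = c(width, height)`.
#'
#' @examples
#' fld <- simulate_complex_field(10, 10, density_um2 = 3, seed = 1)
#' nrow(fld$complexes) # about 300
#' @export
simulate_complex_field <- function(width_um = 10, height_um = 10,
                                   density_um2 = 3,
                                   subunits_per_complex = 5L,
                                   tagged_per_complex = subunits_per_complex,
                                   synapse_areas_um2 = numeric(0),
                                   complexes_per_synapse = integer(0),
                                   min_separation_nm = 8,
                                   seed = NULL) {
  stopifnot(width_um > 0, height_um > 0, density_um2 >= 0,
            subunits_per_complex >= 1, tagged_per_complex >= 0,
            tagged_per_complex <= subunits_per_complex)
  if (length(synapse_areas_um2) > 0 && any(synapse_areas_um2 <= 0)) {
    stop("synaptic ROI areas must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  w_nm <- width_um * 1000
  h_nm <- height_um * 1000

  n_extra <- rpois(1L, density_um2 * width_um * height_um)
  xs <- runif(n_extra, 0, w_nm)
  ys <- runif(n_extra, 0, h_nm)
  region <- rep("extrasynaptic", n_extra)
  roi <- rep(NA_integer_, n_extra)

  n_syn <- length(synapse_areas_um2)
  syn <- data.frame(roi = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                    area_um2 = numeric(0), radius_nm = numeric(0))
  if (n_syn > 0L) {
    counts <- rep_len(as.integer(complexes_per_synapse), n_syn)
    radius_nm <- sqrt(synapse_areas_um2 / pi) * 1000
    # synapses are distinct membrane specializations: place ROI centers so
    # that discs never overlap (200 nm clearance)
    cx <- numeric(n_syn); cy <- numeric(n_syn)
    for (s in seq_len(n_syn)) {
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        px <- runif(1L, radius_nm[s], w_nm - radius_nm[s])
        py <- runif(1L, radius_nm[s], h_nm - radius_nm[s])
        if (s == 1L) { ok <- TRUE }
        else {
          prev <- seq_len(s - 1L)
          ok <- all(sqrt((cx[prev] - px)^2 + (cy[prev] - py)^2) >=
                      radius_nm[prev] + radius_nm[s] + 200)
        }
        if (ok) { cx[s] <- px; cy[s] <- py; break }
      }
      if (!ok) stop(sprintf("could not place synaptic ROI %d without overlap", s))
    }
    syn <- data.frame(roi = seq_len(n_syn), x_nm = cx, y_nm = cy,
                      area_um2 = synapse_areas_um2, radius_nm = radius_nm)
    for (s in seq_len(n_syn)) {
      pos <- place_in_disc(counts[s], radius_nm[s], min_separation_nm, s)
      xs <- c(xs, cx[s] + pos[, 1L])
      ys <- c(ys, cy[s] + pos[, 2L])
      region <- c(region, rep("synaptic", counts[s]))
      roi <- c(roi, rep(s, counts[s]))
    }
  }

  complexes <- data.frame(
    complex_id = seq_along(xs),
    x_nm = xs, y_nm = ys,
    n_tagged = rep.int(as.integer(tagged_per_complex), length(xs)),
    region = region, roi = roi
  )
  structure(
    list(complexes = complexes, synapses = syn,
         field_nm = c(width = w_nm, height = h_nm),
         subunits_per_complex = as.integer(subunits_per_complex)),
    class = "complex_field"
  )
}

# Dart-throwing placement of n points in a disc with a minimum separation.
place_in_disc <- function(n, radius_nm, min_sep_nm, roi_id) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  # hexagonal packing bound: fail early if the request cannot fit
  packing_limit <- floor(0.9069 * (pi * radius_nm^2) / (pi * (min_sep_nm / 2)^2))
  if (n > packing_limit) {
    stop(sprintf(
      "ROI %d: %d complexes at %.0f nm separation exceed the packing limit (%d) of a %.0f nm radius disc",
      roi_id, n, min_sep_nm, packing_limit, radius_nm))
  }
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("ROI %d: failed to place %d complexes at %.0f nm separation",
                   roi_id, n, min_sep_nm))
    }
    r <- radius_nm * sqrt(runif(1L))
    th <- runif(1L, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    if (placed == 0L ||
        min((px[seq_len(placed)] - x)^2 + (py[seq_len(placed)] - y)^2) >= min_sep_nm^2) {
      placed <- placed + 1L
      px[placed] <- x; py[placed] <- y
    }
  }
  cbind(px, py)
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %.1f x %.1f um, %d complexes (%d synaptic in %d ROIs)\n",
              x$field_nm["width"] / 1000, x$field_nm["height"] / 1000,
              nrow(x$complexes), sum(x$complexes$region == "synaptic"),
              nrow(x$synapses)))
  invisible(x)
}
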