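#' Absolute molecule number from detection counts
#'
#' The counting equation `N = x / (n p)`: the total number of detections
#' in a cluster, divided by the mean number of detections per fluorophore
#' burst and by the detection probability, estimates the number of
#' molecules (subunits) present, including the non-fluorescent fraction.
#'
#' @param x_total Total detections in the cluster (vectorized).
#' @param n_per_burst Mean detections per burst for the recording
#'   (13--19 for a Dendra2-like tag, ~19 for mEos2).
#' @param p_det Detection probability (0.44 Dendra2, 0.48 mEos2).
#' @return Estimated molecule number (exact quotient, no rounding).
#' @examples
#' count_molecules(1100, 16, 0.44) # 156.25
#' @export
count_molecules <- function(x_total, n_per_burst, p_det) {
  stopifnot(n_per_burst > 0, p_det > 0, p_det <= 1)
  x_total / (n_per_burst * p_det)
}

#' Complexes from subunit copies
#'
#' Divides the molecule (subunit) number by the copies of the tagged
#' subunit per complex: 3 for the alpha subunit of an alpha3:beta2
#' heteropentamer, 2 for beta, 1 when molecules are themselves the unit
#' (e.g. a scaffold protein counted per molecule).
#'
#' @param N_molecules Molecule count(s).
#' @param copies_per_complex Tagged copies per complex (integer >= 1).
#' @param round_result Round to the nearest integer (as reported in
#'   summaries); internally quantities stay exact.
#' @examples
#' complexes_from_subunits(250, 3) # 83.33..
#' complexes_from_subunits(250, 3, round_result = TRUE) # 83
#' @export
complexes_from_subunits <- function(N_molecules, copies_per_complex,
                                    round_result = FALSE) {
  stopifnot(copies_per_complex >= 1,
            copies_per_complex == round(copies_per_complex))
  out <- N_molecules / copies_per_complex
  if (round_result) round(out) else out
}

#' Area of a density-thresholded detection cluster
#'
#' Renders the detections as a pointillist density image
#' ([render_pointillist()]), thresholds it at `threshold_per_um2`
#' detections per square micron, and measures the area of the
#' super-threshold region in um^2. If the region fragments, the largest
#' connected component is used and the fragmentation is reported via the
#' `n_fragments` attribute.
#'
#' @param detections data.frame with `x_nm`, `y_nm`.
#' @param sigma_nm Rendering kernel SD (10 nm).
#' @param pixel_nm Rendering pixel (5 nm).
#' @param threshold_per_um2 Density threshold. The default 500 um^-2 sits
#'   an order of magnitude above a sparse extrasynaptic background
#'   (~100 detections/um^2) and two below a synaptic peak (~20000/um^2).
#' @return Area in um^2 (attribute `n_fragments`).
#' @export
cluster_area <- function(detections, sigma_nm = 10, pixel_nm = 5,
                         threshold_per_um2 = 500) {
  stopifnot(nrow(detections) >= 1L)
  img <- render_pointillist(detections, sigma_nm, pixel_nm)
  thr_per_nm2 <- threshold_per_um2 / 1e6
  mask <- img > thr_per_nm2
  if (!any(mask)) {
    out <- 0
    attr(out, "n_fragments") <- 0L
    return(out)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  area_px <- max(sizes)
  out <- area_px * (pixel_nm / 1000)^2
  attr(out, "n_fragments") <- length(sizes)
  out
}

#' Two-dimensional cluster density
#'
#' @param N_complexes Complex count(s).
#' @param area_um2 Cluster area(s), um^2.
#' @return Complexes per um^2 (per cluster; summarize with mean +/- SEM
#'   across clusters).
#' @export
density2d <- function(N_complexes, area_um2) {
  stopifnot(all(area_um2 > 0))
  N_complexes / area_um2
}

#' Intensity correlation quotient between two channels
#'
#' For every mask pixel the product `(A_i - mean(A)) (B_i - mean(B))` is
#' formed (means over the mask); the ICQ is the fraction of pixels with a
#' positive product, minus 0.5. Values in (0, 0.5] indicate correlated
#' (colocalized) staining, values near 0 independence, negative values
#' exclusion.
#'
#' @param a,b Numeric matrices of identical dimension.
#' @param mask Logical matrix; pixels to evaluate. Defaults to all.
#' @return list of class `coloc_result`: `icq`, `n_pixels`, `mean_a`,
#'   `mean_b`.
#' @export
icq <- function(a, b, mask = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  stopifnot(identical(dim(mask), dim(a)), any(mask))
  av <- a[mask]; bv <- b[mask]
  if (sd(av) == 0 || sd(bv) == 0) {
    stop("ICQ undefined for a constant channel within the mask")
  }
  prod <- (av - mean(av)) * (bv - mean(bv))
  structure(list(icq = mean(prod > 0) - 0.5, n_pixels = length(av),
                 mean_a = mean(av), mean_b = mean(bv)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> ICQ = %.3f over %d pixels\n", x$icq, x$n_pixels))
  invisible(x)
}

#' Background-corrected integrated intensity
#'
#' Sum over the cluster mask of `pixel - median(background)`, with the
#' background statistic taken over a disjoint background region. The sum
#' is not floored: a cluster dimmer than the background median yields a
#' negative value, which is informative rather than an error. The median
#' makes the background estimate robust to stray puncta.
#'
#' @param image Numeric matrix.
#' @param cluster_mask,background_region Disjoint logical matrices.
#' @return The corrected integrated intensity (scalar).
#' @export
integrated_intensity <- function(image, cluster_mask, background_region) {
  stopifnot(identical(dim(image), dim(cluster_mask)),
            identical(dim(image), dim(background_region)))
  if (!any(background_region)) stop("empty background region")
  if (any(cluster_mask & background_region)) {
    stop("cluster mask and background region must be disjoint")
  }
  bg <- median(image[background_region])
  sum(image[cluster_mask] - bg)
}

#' Fraction of scaffold binding sites occupied by receptor complexes
#'
#' Each receptor complex engages the scaffold through its beta subunits
#' (`beta_per_complex = 2` for an alpha3:beta2 receptor); each scaffold
#' molecule carries one receptor binding site. The occupancy is
#' `N_complexes * beta_per_complex / N_scaffold`.
#'
#' @param N_complexes Receptor complexes at the synapse.
#' @param beta_per_complex Scaffold-binding subunits per complex.
#' @param N_scaffold Scaffold molecules at the synapse.
#' @examples
#' occupancy(83, 2, 304) # ~0.55, "up to half" of the sites
#' @export
occupancy <- function(N_complexes, beta_per_complex = 2, N_scaffold) {
  stopifnot(N_scaffold > 0)
  (N_complexes * beta_per_complex) / N_scaffold
}

#' Per-synapse quantification of detection clusters
#'
#' Converts synaptic detection clusters into absolute molecule and complex
#' numbers, areas and densities. A cluster enters the summary only when
#' its centroid falls inside a reference region (the punctum observed in
#' the conventional fluorescence channel; in synthetic runs, the
#' ground-truth ROI).
#'
#' @param clusters List of data.frames of member detections (e.g.
#'   `cluster_set$clusters`).
#' @param n_per_burst Mean detections per burst for the recording.
#' @param p_det Detection probability.
#' @param copies_per_complex Tagged subunit copies per complex.
#' @param reference_rois Optional data.frame `x_nm`, `y_nm`, `radius_nm` of
#'   reference puncta; clusters without a matching punctum are dropped.
#' @param area_threshold_per_um2 Density threshold for the area
#'   measurement.
#' @return data.frame: `cluster_id`, `x_total`, `area_um2`,
#'   `N_molecules`, `N_complexes`, `density_per_um2`, `matched`.
#' @export
quantify_synapses <- function(clusters, n_per_burst, p_det,
                              copies_per_complex = 3L,
                              reference_rois = NULL,
                              area_threshold_per_um2 = 500) {
  rows <- lapply(seq_along(clusters), function(i) {
    det <- clusters[[i]]
    cxm <- mean(det$x_nm); cym <- mean(det$y_nm)
    matched <- TRUE
    if (!is.null(reference_rois)) {
      d2 <- (reference_rois$x_nm - cxm)^2 + (reference_rois$y_nm - cym)^2
      matched <- any(d2 <= reference_rois$radius_nm^2)
    }
    x_total <- nrow(det)
    area <- cluster_area(det, threshold_per_um2 = area_threshold_per_um2)
    Nmol <- count_molecules(x_total, n_per_burst, p_det)
    Ncx <- complexes_from_subunits(Nmol, copies_per_complex)
    data.frame(cluster_id = i, x_total = x_total, area_um2 = as.numeric(area),
               N_molecules = Nmol, N_complexes = Ncx,
               density_per_um2 = if (area > 0) Ncx / as.numeric(area) else NA_real_,
               matched = matched)
  })
  out <- do.call(rbind, rows)
  out[out$matched, , drop = FALSE]
}
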