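#' Read a localization table from CSV
#'
#' Native columns are `id, frame, x_nm, y_nm, sigma_nm, intensity` with
#' optional `fluor_id`. Common ThunderSTORM-style aliases are accepted:
#' `x [nm]`, `y [nm]`, `sigma [nm]`, `intensity [photon]`, `frame`.
#'
#' @param path CSV file.
#' @return data.frame in native column naming.
#' @export
read_locs <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  alias <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm", "sigma [nm]" = "sigma_nm",
             "intensity [photon]" = "intensity", "uncertainty [nm]" = "uncertainty_nm",
             "x" = "x_nm", "y" = "y_nm", "sigma" = "sigma_nm")
  nm <- names(df)
  hit <- nm %in% names(alias) & !(alias[nm] %in% nm)
  nm[hit] <- alias[nm[hit]]
  names(df) <- nm
  need <- c("frame", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("localization CSV must provide columns frame, x_nm, y_nm (or aliases)")
  }
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  df
}

#' Write a localization table to CSV
#' @param detections Localization data.frame.
#' @param path Output file.
#' @export
write_locs <- function(detections, path) {
  keep <- intersect(c("id", "frame", "x_nm", "y_nm", "sigma_nm",
                      "intensity", "fluor_id"), names(detections))
  write.csv(detections[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a burst-count histogram as CSV (columns k, x_k)
#' @param path CSV file.
#' @param tau_bleach_frames,mean_detections_per_burst Metadata to attach
#'   on read.
#' @export
read_histogram <- function(path, tau_bleach_frames = NA_integer_,
                           mean_detections_per_burst = NA_real_) {
  df <- read.csv(path)
  stopifnot(all(c("k", "x_k") %in% names(df)))
  df <- df[order(df$k), ]
  counts <- numeric(max(df$k))
  counts[df$k] <- df$x_k
  burst_histogram(counts, tau_bleach_frames, mean_detections_per_burst)
}

#' @rdname read_histogram
#' @param histogram A `burst_histogram`.
#' @export
write_histogram <- function(histogram, path) {
  write.csv(data.frame(k = seq_along(histogram$counts),
                       x_k = as.numeric(histogram$counts)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write per-cluster results as CSV
#' @param cluster_set A `cluster_set`.
#' @param histogram The matching `burst_histogram`.
#' @param path Output file.
#' @export
write_clusters <- function(cluster_set, histogram, path) {
  df <- cluster_set$centroids
  df$k <- histogram$k[seq_len(nrow(df))]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table (movie_id, particle_id, frame, x_nm, y_nm)
#' @param path CSV file.
#' @param frame_rate_hz Acquisition rate attached as attribute.
#' @export
read_trajectories <- function(path, frame_rate_hz = 13) {
  df <- read.csv(path)
  need <- c("particle_id", "frame", "x_nm", "y_nm")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$movie_id)) df$movie_id <- "movie1"
  attr(df, "frame_rate_hz") <- frame_rate_hz
  df
}
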