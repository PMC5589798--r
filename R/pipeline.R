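#' Default configuration for a counting scenario
#'
#' A scenario bundles the field, photophysics and analysis parameters of
#' one simulated counting experiment. Shipped scenario files
#' (`system.file("scenarios", package = "palmcount")`) mirror the standard
#' study conditions: homopentamer calibration in fibroblast-like cells,
#' heteromer model comparison, scaffold trimer counting, synaptic
#' copy-number quantification and a cytokine-challenge reduction.
#'
#' @param name Scenario name.
#' @param ... Overrides of the default fields (see the returned list).
#' @return list of class `run_config`.
#' @export
scenario_config <- function(name = "pentamer_cal", ...) {
  base <- list(
    name = name,
    seed = 1L,
    field = list(width_um = 18, height_um = 18, density_um2 = 3,
                 subunits_per_complex = 5L, tagged_per_complex = 5L,
                 synapse_areas_um2 = numeric(0),
                 complexes_per_synapse = integer(0)),
    photophysics = list(p_det = 0.44, mean_detections_per_burst = 16,
                        tau_bleach_frames = 250L, frame_rate_hz = 20,
                        n_frames = 20000L, loc_error_nm = 15,
                        noise_detections = 50),
    counting = list(mask_diameter_nm = 120, max_diameter_nm = 100,
                    min_detections = 9L, filter_radius_nm = 50,
                    filter_min_neighbors = 3L),
    stoichiometry = list(fit_n = 5L, fixed_p = NULL, candidate_ns = NULL),
    quantification = list(copies_per_complex = 3L,
                          area_threshold_per_um2 = 500)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(base[[nm]])) {
      base[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      base[[nm]] <- dots[[nm]]
    }
  }
  structure(base, class = "run_config")
}

#' Load a scenario configuration from a YAML file
#' @param path YAML file with the [scenario_config()] fields.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scenario_config, cfg)
}

#' Run a counting scenario end to end
#'
#' Simulate the complex field and its photophysics, apply the counting
#' front end (density filter, cluster selection, burst segmentation),
#' fit the binomial stoichiometry model and, when the scenario has
#' synaptic ROIs, quantify per-synapse molecule numbers, areas and
#' densities. All intermediates can be written to `out_dir`; re-running
#' with the same config reproduces every number exactly.
#'
#' @param config A `run_config` from [scenario_config()] /
#'   [read_scenario()].
#' @param out_dir Optional directory for intermediates (localization CSV,
#'   histogram CSV, cluster CSV, report JSON).
#' @return list of class `run_report`: `scenario`, `seed`, `histogram`,
#'   `fit` (or `comparison` for fixed-p scenarios), `synapses`
#'   (per-synapse quantification, possibly NULL), `qc`, `headline`
#'   (named numeric vector of the run's key numbers).
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  field <- do.call(simulate_complex_field, config$field)
  pcfg <- do.call(photophysics_config, config$photophysics)
  sim <- simulate_photophysics(field, pcfg)

  cb <- count_bursts(sim$detections,
                     tau_bleach_frames = pcfg$tau_bleach_frames,
                     mask_diameter_nm = config$counting$mask_diameter_nm,
                     max_diameter_nm = config$counting$max_diameter_nm,
                     min_detections = config$counting$min_detections,
                     filter_radius_nm = config$counting$filter_radius_nm,
                     filter_min_neighbors = config$counting$filter_min_neighbors)

  fit <- NULL; comparison <- NULL
  if (!is.null(config$stoichiometry$fixed_p)) {
    comparison <- fit_binomial_fixed_p(cb$histogram,
                                       config$stoichiometry$fixed_p,
                                       config$stoichiometry$candidate_ns)
  }
  if (!is.null(config$stoichiometry$fit_n)) {
    fit <- fit_binomial_free(cb$histogram, config$stoichiometry$fit_n)
  }

  synapses <- NULL
  if (length(config$field$synapse_areas_um2) > 0) {
    rois <- data.frame(x_nm = field$synapses$x_nm, y_nm = field$synapses$y_nm,
                       radius_nm = field$synapses$radius_nm + 100)
    syn_det <- sim$detections[!is.na(sim$detections$complex_id), , drop = FALSE]
    syn_clusters <- lapply(seq_len(nrow(field$synapses)), function(s) {
      r <- rois[s, ]
      inroi <- (syn_det$x_nm - r$x_nm)^2 + (syn_det$y_nm - r$y_nm)^2 <= r$radius_nm^2
      syn_det[inroi, , drop = FALSE]
    })
    syn_clusters <- syn_clusters[vapply(syn_clusters, nrow, integer(1)) > 0L]
    p_use <- config$stoichiometry$fixed_p %||% pcfg$p_det
    synapses <- quantify_synapses(
      syn_clusters,
      n_per_burst = cb$histogram$mean_detections_per_burst,
      p_det = p_use,
      copies_per_complex = config$quantification$copies_per_complex,
      reference_rois = rois,
      area_threshold_per_um2 = config$quantification$area_threshold_per_um2)
  }

  headline <- c(
    n_clusters = cb$histogram$n_clusters,
    mean_detections_per_burst = cb$histogram$mean_detections_per_burst,
    p_det_fit = if (!is.null(fit)) fit$p_det else NA_real_,
    best_n = if (!is.null(comparison)) comparison$ranking$n[1L] else NA_real_,
    mean_complexes_per_synapse =
      if (!is.null(synapses)) mean(synapses$N_complexes) else NA_real_,
    mean_area_um2 = if (!is.null(synapses)) mean(synapses$area_um2) else NA_real_,
    mean_density_per_um2 =
      if (!is.null(synapses)) mean(synapses$density_per_um2, na.rm = TRUE) else NA_real_
  )

  report <- structure(list(
    scenario = config$name, seed = config$seed,
    histogram = cb$histogram, fit = fit, comparison = comparison,
    synapses = synapses, qc = cb$qc, headline = headline
  ), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_locs(sim$detections, file.path(out_dir, "locs.csv"))
    write_histogram(cb$histogram, file.path(out_dir, "histogram.csv"))
    write_clusters(cb$clusters, cb$histogram, file.path(out_dir, "clusters.csv"))
    if (!is.null(synapses)) {
      write.csv(synapses, file.path(out_dir, "synapses.csv"), row.names = FALSE)
    }
    jsonlite::write_json(
      list(scenario = config$name, seed = config$seed,
           headline = as.list(headline[!is.na(headline)]),
           qc = cb$qc),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario '%s' (seed %d)\n", x$scenario, x$seed))
  h <- x$headline[!is.na(x$headline)]
  for (nm in names(h)) cat(sprintf("  %s: %.4g\n", nm, h[[nm]]))
  invisible(x)
}

#' Compare a metric between two runs or conditions
#'
#' Nonparametric comparison (Mann-Whitney U via [stats::wilcox.test()]) of
#' a per-cluster metric between two run reports or two numeric vectors.
#'
#' @param a,b `run_report`s (their per-synapse tables are used) or
#'   numeric vectors.
#' @param metric Column compared when reports are given.
#' @return list: `metric`, `mean_a`, `mean_b`, `delta` (b - a),
#'   `direction`, `p_value`.
#' @export
compare_conditions <- function(a, b, metric = "N_complexes") {
  pull <- function(r) {
    if (inherits(r, "run_report")) {
      if (is.null(r$synapses) || !metric %in% names(r$synapses)) {
        stop(sprintf("report has no per-synapse metric '%s'", metric))
      }
      r$synapses[[metric]]
    } else as.numeric(r)
  }
  va <- pull(a); vb <- pull(b)
  wt <- suppressWarnings(wilcox.test(va, vb))
  delta <- mean(vb) - mean(va)
  list(metric = metric, mean_a = mean(va), mean_b = mean(vb), delta = delta,
       direction = if (delta > 0) "increase" else if (delta < 0) "decrease" else "none",
       p_value = wt$p.value)
}
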