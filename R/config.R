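#' Pipeline configuration
#'
#' Bundles the thresholds and numerical settings shared by the filtering,
#' weight-matrix, density-map and field stages. Defaults follow common
#' EM-connectome practice: synaptic contacts are kept when their automatic
#' cleft-detection confidence score is at least 50, partners and posts with
#' fewer than five regional synapses are dropped, and synapse density maps
#' are binned at 40 nm and smoothed with a Gaussian of 10 bins.
#'
#' @param cleft_threshold minimum cleft score for a contact to be kept.
#' @param min_partner_synapses minimum synapse count for a partner edge in
#'   graph traversals.
#' @param min_regional_connections posts with fewer total regional synapses
#'   than this are dropped from weight matrices.
#' @param density_bin_nm bin size of synapse-density maps, nm.
#' @param density_sigma_bins Gaussian smoothing sigma, in bins (10 for
#'   quantitative maps, 4 for demonstrative maps).
#' @param annulus_area_um2 area of the equal-area annuli used for radial
#'   synapse-density profiles, in square micrometres.
#' @param contour_levels iso-contour levels (fractions of the maximum) used
#'   for receptive-field outlines.
#' @param seed integer seed for the stochastic stages.
#' @param coordinate_units `"nm"` when synapse tables are already in
#'   nanometres, or a numeric length-3 voxel size (nm per voxel) applied
#'   once at read time.
#' @param denominator_side `"input"` (default) normalizes weight-matrix
#'   columns by the post neuron's regional *input* synapses;
#'   `"input_output"` uses input plus output synapses.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(cleft_threshold = 50,
                            min_partner_synapses = 5,
                            min_regional_connections = 5,
                            density_bin_nm = 40,
                            density_sigma_bins = 10,
                            annulus_area_um2 = 314.15,
                            contour_levels = c(0.2, 0.5),
                            seed = 1L,
                            coordinate_units = "nm",
                            denominator_side = c("input", "input_output")) {
  denominator_side <- match.arg(denominator_side)
  cfg <- list(
    cleft_threshold = cleft_threshold,
    min_partner_synapses = min_partner_synapses,
    min_regional_connections = min_regional_connections,
    density_bin_nm = density_bin_nm,
    density_sigma_bins = density_sigma_bins,
    annulus_area_um2 = annulus_area_um2,
    contour_levels = contour_levels,
    seed = as.integer(seed),
    coordinate_units = coordinate_units,
    denominator_side = denominator_side
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  num_ge0 <- c("cleft_threshold", "min_partner_synapses",
               "min_regional_connections", "density_bin_nm",
               "density_sigma_bins", "annulus_area_um2")
  for (f in num_ge0) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("pipeline_config: `", f, "` must be a single number >= 0")
  }
  lv <- cfg$contour_levels
  if (!is.numeric(lv) || any(is.na(lv)) || any(lv <= 0) || any(lv >= 1))
    stop("pipeline_config: contour levels must lie strictly in (0, 1)")
  cu <- cfg$coordinate_units
  if (!(identical(cu, "nm") || (is.numeric(cu) && length(cu) == 3L && all(cu > 0))))
    stop("pipeline_config: coordinate_units must be \"nm\" or a length-3 voxel size")
  cfg
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path file path.
#' @param config a [pipeline_config()] object.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[intersect(names(x), names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (n in names(x)) cat(" ", n, ": ", paste(format(x[[n]]), collapse = ","), "\n", sep = "")
  invisible(x)
}
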