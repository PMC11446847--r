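# One-call analysis pipeline: from a connectome bundle (synapse table,
# annotations, hulls, columns) to weight matrices, subtype clusters,
# column geometry, eye map, occupancies and back-traced ER fields.
# This is the reference composition of the package's stages; each stage
# remains independently callable.

#' Run the full AVP analysis pipeline
#'
#' Composes the package's stages on a connectome bundle (as produced by
#' [generate_connectome()] or assembled from [read_synapse_table()] and
#' friends): synapse filtering; region-restricted weight matrices
#' (medulla inputs -> MeTu, MeTu -> AOTU targets, TuBu/TuTu -> ER);
#' connectivity feature vectors and subtype clustering; column-axis
#' fits from the columnar anchor neurons; equator detection and hex
#' alignment into an eye map; MeTu column occupancies; and per-ER
#' direct/indirect back-traced fields.
#'
#' @param connectome list with `synapses`, `annotations`, `hulls`,
#'   `columns` (lattice with q, r, pr_count) and `ommatidia`.
#' @param config a [pipeline_config()].
#' @param k number of subtype clusters.
#' @param cluster_args extra arguments passed to [cluster_subtypes()].
#' @param occupancy_sites `"presynaptic"` counts sites where the MeTu is
#'   presynaptic in the medulla; `"dendritic"` (default here, matching a
#'   dendritic-footprint reading) counts sites where it is postsynaptic.
#' @return a list with the filtered table, the weight matrices,
#'   `features`, `clustering`, `column_fits`, `eyemap`, `occupancies`
#'   and `fields` (per-ER `column_field`s), plus the id vectors used.
#' @export
analyze_connectome <- function(connectome, config = pipeline_config(),
                               k = 10,
                               cluster_args = list(merge_within = "in:"),
                               occupancy_sites = c("dendritic",
                                                   "presynaptic")) {
  occupancy_sites <- match.arg(occupancy_sites)
  ann <- connectome$annotations
  hulls <- connectome$hulls
  syn <- filter_synapses(connectome$synapses, config)
  ids <- list(
    metu = ann$neuron_id[grepl("^MeTu", ann$cell_class)],
    tubu = ann$neuron_id[grepl("^TuBu", ann$cell_class)],
    er = ann$neuron_id[grepl("^ER|^ExR", ann$cell_class)],
    tutu = ann$neuron_id[grepl("^TuTu", ann$cell_class)],
    aotu046 = ann$neuron_id[ann$cell_class == "AOTU046"],
    mi1 = ann$neuron_id[ann$cell_class == "Mi1"])
  ids$inputs <- setdiff(
    ann$neuron_id[!grepl("^(MeTu|TuBu|ER|ExR|TuTu|AOTU046|Mi1|L1)",
                         ann$cell_class) & ann$cell_class != "other"],
    unlist(ids))
  type_map <- stats::setNames(ann$cell_class, ann$neuron_id)

  ## weight matrices
  wm_me <- neuron_weight_matrix(syn, ids$inputs, ids$metu,
                                hulls$ME_R, config)
  wm_ao <- neuron_weight_matrix(syn, ids$metu,
                                c(ids$tubu, ids$tutu, ids$aotu046),
                                hulls$AOTU_R, config)
  wm_bu <- neuron_weight_matrix(syn, c(ids$tubu, ids$aotu046), ids$er,
                                hulls$BU_R, config)
  wm_mt <- neuron_weight_matrix(syn, ids$metu, ids$tutu,
                                hulls$AOTU_R, config)
  wm_tt <- neuron_weight_matrix(syn, ids$tutu, ids$tubu,
                                hulls$AOTU_R, config)

  ## classification
  metu_in <- intersect(ids$metu, wm_me$post_ids)
  features <- build_feature_vectors(wm_me, wm_ao, type_map, metu_in)
  clustering <- do.call(cluster_subtypes,
                        c(list(features = features, mode = "dendrogram",
                               k = k, seed = config$seed), cluster_args))

  ## column geometry and eye map
  me_syn <- restrict_to_region(syn, hulls$ME_R)
  prox_ref <- c(mean(me_syn$x_nm), mean(me_syn$y_nm),
                max(me_syn$z_nm) + 1)
  col_in <- connectome$columns
  fits <- vector("list", nrow(col_in))
  for (i in seq_len(nrow(col_in))) {
    id <- col_in$column_id[i]
    P <- as.matrix(me_syn[me_syn$post_id == paste0("Mi1_", id),
                          c("x_nm", "y_nm", "z_nm")])
    fits[[i]] <- fit_column_axis(P, prox_ref, column_id = id,
                                 q = col_in$q[i], r = col_in$r[i])
  }
  column_fits <- do.call(rbind, fits)
  eq <- detect_equator(stats::setNames(col_in$pr_count, col_in$column_id))
  column_fits$is_equator <- unname(eq[column_fits$column_id])
  eyemap <- align_hex_grids(
    column_fits[, c("column_id", "q", "r", "is_equator")],
    connectome$ommatidia)

  ## occupancies and ER fields
  side <- if (occupancy_sites == "dendritic") "post_id" else "pre_id"
  occ_syn <- me_syn[me_syn[[side]] %in% ids$metu, , drop = FALSE]
  occ_split <- split(seq_len(nrow(occ_syn)), occ_syn[[side]])
  occupancies <- lapply(ids$metu, function(m) {
    rows <- occ_split[[m]]
    S <- as.matrix(occ_syn[rows, c("x_nm", "y_nm", "z_nm")])
    column_occupancy(S, column_fits, metu_id = m)
  })
  names(occupancies) <- ids$metu
  er_in <- intersect(ids$er, wm_bu$post_ids)
  fields <- lapply(er_in, function(er)
    backtrace_field(er, wm_bu, wm_ao, occupancies,
                    metu_tutu = wm_mt, tutu_tubu = wm_tt,
                    pathway = "both", exclude = ids$aotu046))
  names(fields) <- er_in

  list(synapses = syn, ids = ids, type_map = type_map,
       wm_medulla = wm_me, wm_aotu = wm_ao, wm_bulb = wm_bu,
       wm_metu_tutu = wm_mt, wm_tutu_tubu = wm_tt,
       features = features, clustering = clustering,
       column_fits = column_fits, eyemap = eyemap,
       occupancies = occupancies, fields = fields)
}

#' Fit an eye-coordinate ellipse to a back-traced field
#'
#' Weighted Gaussian fit of a `column_field`'s direct values over the
#' eye-map coordinates of its columns; the standard summary used to
#' compare channel geometries (e.g. vertically elongated versus 2-D
#' tiled fields).
#'
#' @param field a `column_field`.
#' @param eyemap an `eye_map`.
#' @param k_sigma contour level in sigmas.
#' @return an `ellipse_fit`, or `NULL` when fewer than 10 mapped
#'   columns carry weight.
#' @export
field_ellipse <- function(field, eyemap, k_sigma = 1) {
  m <- match(names(field$direct), eyemap$column_id)
  ok <- !is.na(m) & field$direct > 0
  if (sum(ok) < 10) return(NULL)
  fit_span_ellipse(cbind(eyemap$azimuth_deg[m[ok]],
                         eyemap$elevation_deg[m[ok]]),
                   weights = field$direct[ok], k_sigma = k_sigma)
}
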