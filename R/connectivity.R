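# Synapse filtering, region-restricted synaptic weight matrices
# (individual and type level), matrix row ordering by retinotopic TuBu
# position, upstream graph traversal, neurotransmitter profile averaging
# and projected synapse-density maps.

new_weight_matrix <- function(region, pre_ids, post_ids, values, counts,
                              denominators, level = c("individual", "type"),
                              normalize = "post") {
  level <- match.arg(level)
  structure(list(region = region, pre_ids = pre_ids, post_ids = post_ids,
                 values = values, counts = counts,
                 denominators = denominators, level = level,
                 normalize = normalize),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("<weight_matrix> region:", x$region, " level:", x$level,
      " [", length(x$pre_ids), "pre x", length(x$post_ids), "post ]\n")
  invisible(x)
}

#' Filter a synapse table
#'
#' Keeps contacts whose cleft score reaches the configured threshold
#' (default >= 50) and removes autapses (pre id equal to post id) and
#' contacts with the background segmentation (partner id `"0"`). Row
#' order of the survivors is preserved, and the operation is idempotent.
#'
#' @param synapses a synapse `data.frame` ([read_synapse_table()]).
#' @param config a [pipeline_config()].
#' @return the filtered `data.frame`.
#' @export
filter_synapses <- function(synapses, config = pipeline_config()) {
  keep <- synapses$cleft_score >= config$cleft_threshold &
    synapses$pre_id != synapses$post_id &
    synapses$pre_id != BACKGROUND_ID &
    synapses$post_id != BACKGROUND_ID
  synapses[keep, , drop = FALSE]
}

# Restrict synapses to a hull (NULL hull keeps everything).
restrict_to_region <- function(synapses, hull, subtract_hull = NULL) {
  if (is.null(hull)) return(synapses)
  pos <- as.matrix(synapses[, c("x_nm", "y_nm", "z_nm")])
  synapses[point_in_region(pos, hull, subtract_hull), , drop = FALSE]
}

#' Individual-neuron synaptic weight matrix
#'
#' Counts synapses from each pre neuron to each post neuron inside a
#' region and normalizes each count by the post neuron's total number of
#' synapses in the region (its regional input synapses by default; a
#' config switch adds its outputs). Posts with fewer than
#' `min_regional_connections` total regional synapses are dropped, and an
#' explicit exclusion list removes dataset-specific outliers.
#'
#' @param synapses a *filtered* synapse table ([filter_synapses()]).
#' @param pre_ids,post_ids character vectors fixing the row/column order.
#' @param hull optional [region_hull()] restricting the counts;
#'   `subtract_hull` as in [point_in_region()].
#' @param config a [pipeline_config()].
#' @param exclude character vector of neuron ids dropped from both axes.
#' @param subtract_hull see [point_in_region()].
#' @return a `weight_matrix` (level `"individual"`) with `values`
#'   (weights), `counts` (raw synapse counts) and per-post
#'   `denominators`.
#' @export
neuron_weight_matrix <- function(synapses, pre_ids, post_ids, hull = NULL,
                                 config = pipeline_config(),
                                 exclude = character(),
                                 subtract_hull = NULL) {
  syn <- restrict_to_region(synapses, hull, subtract_hull)
  pre_ids <- setdiff(pre_ids, exclude)
  post_ids <- setdiff(post_ids, exclude)
  # denominator: the post's total regional synapses
  denom_in <- tapply(rep(1L, nrow(syn)), syn$post_id, sum)
  denom <- as.numeric(denom_in[post_ids])
  denom[is.na(denom)] <- 0
  if (identical(config$denominator_side, "input_output")) {
    denom_out <- tapply(rep(1L, nrow(syn)), syn$pre_id, sum)
    extra <- as.numeric(denom_out[post_ids])
    extra[is.na(extra)] <- 0
    denom <- denom + extra
  }
  keep <- denom >= config$min_regional_connections
  if (!any(keep))
    warning("neuron_weight_matrix: no post neuron reaches ",
            config$min_regional_connections, " regional connections")
  post_kept <- post_ids[keep]
  denom <- denom[keep]
  counts <- matrix(0, length(pre_ids), length(post_kept),
                   dimnames = list(pre_ids, post_kept))
  sub <- syn[syn$pre_id %in% pre_ids & syn$post_id %in% post_kept, ,
             drop = FALSE]
  if (nrow(sub)) {
    tab <- table(factor(sub$pre_id, levels = pre_ids),
                 factor(sub$post_id, levels = post_kept))
    counts[] <- as.numeric(tab)
  }
  values <- if (length(post_kept))
    sweep(counts, 2, denom, "/") else counts
  names(denom) <- post_kept
  new_weight_matrix(region = if (is.null(hull)) NA_character_ else hull$name,
                    pre_ids = pre_ids, post_ids = post_kept,
                    values = values, counts = counts, denominators = denom,
                    level = "individual", normalize = config$denominator_side)
}

#' Type-level synaptic weight matrix
#'
#' Aggregates synapses over cell types: the cell for (pre type, post type)
#' is the total number of synapses from all neurons of the pre type onto
#' all neurons of the post type in the region, divided by the total
#' regional synapses of all post-type neurons. A post type with zero
#' regional synapses gets weight 0 with a warning.
#'
#' @inheritParams neuron_weight_matrix
#' @param type_map named character vector mapping neuron_id -> type label;
#'   every neuron appearing in the region must be typed.
#' @param pre_types,post_types optional type orderings (default: sorted
#'   types observed on each side).
#' @return a `weight_matrix` with level `"type"`.
#' @export
type_weight_matrix <- function(synapses, type_map, hull = NULL,
                               config = pipeline_config(),
                               pre_types = NULL, post_types = NULL,
                               subtract_hull = NULL) {
  syn <- restrict_to_region(synapses, hull, subtract_hull)
  untyped <- setdiff(unique(c(syn$pre_id, syn$post_id)), names(type_map))
  if (length(untyped))
    stop("type_weight_matrix: untyped neuron(s): ",
         paste(utils::head(untyped, 5), collapse = ", "))
  pre_t <- unname(type_map[syn$pre_id])
  post_t <- unname(type_map[syn$post_id])
  if (is.null(pre_types)) pre_types <- sort(unique(pre_t))
  if (is.null(post_types)) post_types <- sort(unique(post_t))
  counts <- matrix(0, length(pre_types), length(post_types),
                   dimnames = list(pre_types, post_types))
  tab <- table(factor(pre_t, levels = pre_types),
               factor(post_t, levels = post_types))
  counts[] <- as.numeric(tab)
  denom <- as.numeric(table(factor(post_t, levels = post_types)))
  if (identical(config$denominator_side, "input_output"))
    denom <- denom + as.numeric(table(factor(pre_t, levels = post_types)))
  zero <- denom == 0
  if (any(zero))
    warning("type_weight_matrix: post type(s) with zero regional synapses ",
            "reported as 0: ", paste(post_types[zero], collapse = ", "))
  values <- sweep(counts, 2, ifelse(zero, 1, denom), "/")
  names(denom) <- post_types
  new_weight_matrix(region = if (is.null(hull)) NA_character_ else hull$name,
                    pre_ids = pre_types, post_ids = post_types,
                    values = values, counts = counts, denominators = denom,
                    level = "type", normalize = config$denominator_side)
}

#' Order weight-matrix rows by retinotopic TuBu position
#'
#' Groups the pre-side neurons (MeTu or ER) by the TuBu partner they share
#' the most synapses with, orders the groups by that TuBu's dorsal-ventral
#' position, and orders neurons within a group by descending synapse count
#' with that TuBu (ties by neuron id). Neurons without any TuBu partner go
#' to a trailing group with a warning.
#'
#' @param matrix a `weight_matrix` whose posts are TuBu neurons (counts
#'   present).
#' @param tubu_dv named numeric vector: dorsal-ventral scalar per TuBu id.
#' @return the reordered `weight_matrix`.
#' @export
order_matrix_rows <- function(matrix, tubu_dv) {
  stopifnot(inherits(matrix, "weight_matrix"), !is.null(matrix$counts))
  cts <- matrix$counts
  n <- length(matrix$pre_ids)
  strongest <- character(n); strength <- numeric(n)
  for (i in seq_len(n)) {
    row <- cts[i, ]
    if (!length(row) || all(row == 0)) {
      strongest[i] <- NA_character_; strength[i] <- 0
    } else {
      j <- which.max(row)  # first max: stable for ties
      strongest[i] <- matrix$post_ids[j]; strength[i] <- row[j]
    }
  }
  if (anyNA(strongest))
    warning("order_matrix_rows: neuron(s) with no TuBu partner placed last: ",
            paste(matrix$pre_ids[is.na(strongest)], collapse = ", "))
  dv <- tubu_dv[strongest]
  dv[is.na(dv)] <- Inf
  ord <- order(dv, -strength, matrix$pre_ids)
  matrix$pre_ids <- matrix$pre_ids[ord]
  matrix$values <- matrix$values[ord, , drop = FALSE]
  matrix$counts <- matrix$counts[ord, , drop = FALSE]
  matrix
}

#' Traverse upstream of seed neurons
#'
#' Breadth-first expansion up to `max_hops` hops upstream of the seed
#' neurons on the filtered synapse graph. An edge exists when the partner
#' supplies at least `min_syn` synapses to its downstream neuron.
#' Central-complex-intrinsic neurons are never expanded. For each visited
#' partner the summed relative input weight contributed by optic-lobe
#' resident neurons is reported, plus a report flag marking partners that
#' contribute at least `report_fraction` of their target's total
#' non-central-complex input weight.
#'
#' @param seeds character vector of seed neuron ids.
#' @param synapses a *filtered* synapse table.
#' @param max_hops maximum number of upstream hops (default 2).
#' @param min_syn minimum synapses for an edge (default 5).
#' @param cx_ids ids of central-complex-intrinsic neurons (excluded from
#'   expansion).
#' @param ol_ids ids of optic-lobe-resident neurons.
#' @param report_fraction report-flag threshold on the fraction of
#'   non-central-complex input weight (default 0.01).
#' @return a `data.frame` with neuron_id, hop (1 or 2), target (the
#'   downstream neuron through which it was reached), n_syn,
#'   weight_to_target (fraction of the target's total input),
#'   optic_lobe_weight (the partner's own summed relative input weight
#'   from optic-lobe neurons) and report flag.
#' @export
upstream_traversal <- function(seeds, synapses, max_hops = 2L, min_syn = 5L,
                               cx_ids = character(), ol_ids = character(),
                               report_fraction = 0.01) {
  unknown <- setdiff(seeds, c(synapses$pre_id, synapses$post_id))
  if (length(unknown))
    stop("upstream_traversal: unknown seed id(s): ",
         paste(unknown, collapse = ", "))
  edges <- stats::aggregate(list(n_syn = rep(1L, nrow(synapses))),
                            by = list(pre_id = synapses$pre_id,
                                      post_id = synapses$post_id), FUN = sum)
  edges <- edges[edges$n_syn >= min_syn, , drop = FALSE]
  tot_in <- tapply(edges$n_syn, edges$post_id, sum)
  frontier <- setdiff(seeds, cx_ids)
  visited <- character()
  rows <- list()
  for (hop in seq_len(max_hops)) {
    up <- edges[edges$post_id %in% frontier, , drop = FALSE]
    up <- up[!up$pre_id %in% c(seeds, visited), , drop = FALSE]
    if (!nrow(up)) break
    up$hop <- hop
    rows[[hop]] <- up
    visited <- union(visited, up$pre_id)
    frontier <- setdiff(unique(up$pre_id), cx_ids)
  }
  if (!length(rows))
    return(data.frame(neuron_id = character(), hop = integer(),
                      target = character(), n_syn = integer(),
                      weight_to_target = numeric(),
                      optic_lobe_weight = numeric(), report = logical()))
  out <- do.call(rbind, rows)
  out$weight_to_target <- out$n_syn / as.numeric(tot_in[out$post_id])
  # the partner's own input weight from optic-lobe residents
  ol_w <- vapply(out$pre_id, function(id) {
    inc <- edges[edges$post_id == id, , drop = FALSE]
    if (!nrow(inc)) return(0)
    sum(inc$n_syn[inc$pre_id %in% ol_ids]) / sum(inc$n_syn)
  }, numeric(1))
  # fraction of the target's non-central-complex input weight
  noncx <- vapply(seq_len(nrow(out)), function(k) {
    inc <- edges[edges$post_id == out$post_id[k], , drop = FALSE]
    tot <- sum(inc$n_syn[!inc$pre_id %in% cx_ids])
    if (tot == 0) 0 else out$n_syn[k] / tot
  }, numeric(1))
  data.frame(neuron_id = out$pre_id, hop = out$hop, target = out$post_id,
             n_syn = out$n_syn, weight_to_target = out$weight_to_target,
             optic_lobe_weight = unname(ol_w),
             report = noncx >= report_fraction,
             stringsAsFactors = FALSE)
}

#' Average neurotransmitter profile of one neuron
#'
#' Arithmetic mean of the per-presynaptic-site transmitter probability
#' vectors; renormalized to sum 1 when the inputs deviate by more than
#' 1e-6.
#'
#' @param site_probs numeric matrix, one presynaptic site per row, one
#'   transmitter class per column.
#' @param neuron_id optional id attached to the result.
#' @return a list (class `nt_profile`) with `neuron_id`, `probs` (named
#'   mean vector) and `n_sites`.
#' @export
mean_nt_profile <- function(site_probs, neuron_id = NA_character_) {
  P <- as.matrix(site_probs)
  if (!nrow(P)) stop("mean_nt_profile: neuron has no presynaptic sites")
  if (any(P < 0)) stop("mean_nt_profile: negative probabilities")
  m <- colMeans(P)
  if (abs(sum(m) - 1) > 1e-6) m <- m / sum(m)
  structure(list(neuron_id = neuron_id, probs = m, n_sites = nrow(P)),
            class = "nt_profile")
}

# Truncated (4 sigma), renormalized 1-D Gaussian kernel.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- ceiling(4 * sigma)
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with zero padding.
smooth2d <- function(M, sigma) {
  k <- gaussian_kernel(sigma)
  h <- (length(k) - 1L) / 2L
  if (h == 0L) return(M)
  pad_rc <- function(X) rbind(matrix(0, h, ncol(X)), X, matrix(0, h, ncol(X)))
  conv_cols <- function(X) {
    Xp <- pad_rc(X)
    out <- matrix(0, nrow(X), ncol(X))
    for (d in -h:h)
      out <- out + k[d + h + 1L] * Xp[(1 + h + d):(nrow(X) + h + d), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(M))))
}

#' Projected synapse-density map
#'
#' Projects synapse positions onto a 2-D viewing plane, bins them on a
#' square grid (40 nm by 40 nm by default, each bin spanning the full
#' depth of the region along the viewing axis) and applies a truncated,
#' renormalized Gaussian blur (sigma 10 bins for quantitative maps, 4 for
#' demonstrative maps). The grid is padded by 4 sigma so smoothing
#' conserves total mass.
#'
#' The `view` presets follow the three standard viewing directions of the
#' AOTUsu (dorsal, anterior, lateral), each rotated 30 degrees about the
#' anterior-posterior (x) axis; a custom orthonormal pair of in-plane
#' axes may be supplied instead.
#'
#' @param synapses a synapse table (typically already restricted to a
#'   region hull with [filter_synapses()] plus a hull).
#' @param view `"dorsal"`, `"anterior"`, `"lateral"`, or a 2 x 3 matrix
#'   whose rows are the two in-plane unit axes.
#' @param hull optional [region_hull()] applied before binning.
#' @param config a [pipeline_config()]; uses `density_bin_nm` and
#'   `density_sigma_bins`.
#' @param sigma_bins overrides `config$density_sigma_bins` (e.g. 4).
#' @return a list (class `density_map`) with `grid` (the smoothed count
#'   matrix), `x_breaks`, `y_breaks` (bin edges, nm) and `n_synapses`.
#' @export
synapse_density_map <- function(synapses, view = "dorsal", hull = NULL,
                                config = pipeline_config(),
                                sigma_bins = NULL) {
  syn <- restrict_to_region(synapses, hull)
  sigma <- if (is.null(sigma_bins)) config$density_sigma_bins else sigma_bins
  axes <- if (is.matrix(view)) view else density_view_axes(view)
  bin <- config$density_bin_nm
  if (!nrow(syn)) {
    warning("synapse_density_map: empty synapse set; all-zero grid")
    return(structure(list(grid = matrix(0, 1, 1), x_breaks = c(0, bin),
                          y_breaks = c(0, bin), n_synapses = 0L),
                     class = "density_map"))
  }
  P <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")]) %*% t(axes)
  pad <- ceiling(4 * sigma)
  xb <- seq(floor(min(P[, 1]) / bin) - pad, ceiling(max(P[, 1]) / bin) + pad) * bin
  yb <- seq(floor(min(P[, 2]) / bin) - pad, ceiling(max(P[, 2]) / bin) + pad) * bin
  ix <- findInterval(P[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  G <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  structure(list(grid = smooth2d(G, sigma), x_breaks = xb, y_breaks = yb,
                 n_synapses = nrow(P)),
            class = "density_map")
}

# Named viewing-frame presets: in-plane axes after a 30 degree rotation
# about the anterior-posterior (x) axis.
density_view_axes <- function(view = c("dorsal", "anterior", "lateral")) {
  view <- match.arg(view)
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  base <- switch(view,
    dorsal = rbind(c(1, 0, 0), c(0, 1, 0)),    # looking down z
    anterior = rbind(c(1, 0, 0), c(0, 0, 1)),  # looking along y
    lateral = rbind(c(0, 1, 0), c(0, 0, 1)))   # looking along x
  base %*% t(R)
}
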