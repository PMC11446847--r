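# Neuropil geometry: convex region hulls with half-space membership,
# medulla column axes from PCA of columnar anchor neurons, the layer
# coordinate table, equator detection, and hexagonal grid alignment
# between medulla columns and ommatidia.

#' Construct a region hull
#'
#' A neuropil region is represented by the convex hull of a vertex cloud
#' (in nm). Membership is the half-space test against the hull facets,
#' which are enumerated once at construction by brute force over all
#' vertex triplets: a triplet spans a facet plane when every other vertex
#' lies on one side of it.
#'
#' @param name region label (e.g. `"ME_R"`, `"AOTU_R"`).
#' @param vertices numeric matrix, one 3-D vertex (nm) per row; at least 4
#'   non-coplanar vertices.
#' @param subtract optional name of a hull whose interior is excluded
#'   from membership (e.g. the ipsilateral lobula subtracted from the
#'   medulla).
#' @return an object of class `region_hull` with precomputed facet
#'   inequalities `A x <= b`.
#' @export
region_hull <- function(name, vertices, subtract = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("region_hull: vertices must be n x 3")
  if (nrow(vertices) < 4L) stop("region_hull: need at least 4 vertices")
  f <- hull_facets(vertices)
  structure(list(name = name, vertices = vertices, subtract = subtract,
                 A = f$A, b = f$b),
            class = "region_hull")
}

# Enumerate oriented facet half-spaces of conv(V) by checking, for every
# vertex triplet, whether all remaining vertices fall on one side of its
# plane. Scale-relative tolerance guards against coplanar chatter.
hull_facets <- function(V) {
  n <- nrow(V)
  scale <- max(apply(V, 2, function(x) diff(range(x))), 1)
  tol <- 1e-9 * scale
  ctr <- colMeans(V)
  # full dimensionality: coplanar vertex sets have no interior
  sv <- svd(sweep(V, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("region_hull: degenerate (coplanar) vertex set for hull")
  A <- list(); b <- numeric(0)
  combs <- utils::combn(n, 3)
  for (k in seq_len(ncol(combs))) {
    i <- combs[, k]
    p1 <- V[i[1], ]; p2 <- V[i[2], ]; p3 <- V[i[3], ]
    nrm <- c(
      (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
      (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale) next  # degenerate triplet
    nrm <- nrm / nn
    d <- drop(V %*% nrm) - sum(nrm * p1)
    if (all(d <= tol)) {           # all vertices on the negative side
      A[[length(A) + 1L]] <- nrm; b <- c(b, sum(nrm * p1))
    } else if (all(d >= -tol)) {   # or the positive side
      A[[length(A) + 1L]] <- -nrm; b <- c(b, -sum(nrm * p1))
    }
  }
  if (!length(A))
    stop("region_hull: degenerate (coplanar) vertex set for hull")
  A <- do.call(rbind, A)
  # orient sanity: the centroid must satisfy every inequality
  if (any(drop(A %*% ctr) - b > tol))
    stop("region_hull: inconsistent facet orientation (degenerate hull?)")
  # deduplicate near-identical facets
  key <- paste(round(A[, 1], 7), round(A[, 2], 7), round(A[, 3], 7))
  keep <- !duplicated(key)
  list(A = A[keep, , drop = FALSE], b = b[keep])
}

#' Test points for region membership
#'
#' A point is inside a region when it satisfies every facet half-space of
#' the hull's convex tessellation and, when the hull carries a `subtract`
#' reference, is *not* inside the subtracted hull.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix, nm.
#' @param hull a [region_hull()].
#' @param subtract_hull the [region_hull()] named by `hull$subtract`
#'   (required when that field is set).
#' @param tol boundary tolerance in nm.
#' @return logical vector, one entry per point.
#' @export
point_in_region <- function(points, hull, subtract_hull = NULL, tol = 1e-7) {
  stopifnot(inherits(hull, "region_hull"))
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  inside <- rowSums(P %*% t(hull$A) > matrix(hull$b, nrow(P), length(hull$b),
                                             byrow = TRUE) + tol) == 0L
  if (!is.na(hull$subtract)) {
    if (is.null(subtract_hull))
      stop("point_in_region: hull subtracts `", hull$subtract,
           "` but no subtract_hull was supplied")
    inside <- inside & !point_in_region(P, subtract_hull, tol = tol)
  }
  inside
}

#' Fit the distal-proximal axis of a medulla column
#'
#' Runs a principal component analysis on all pre- and postsynaptic sites
#' of one columnar anchor neuron (Mi1-like). The first principal direction
#' is the column's distal-proximal axis; its sign is disambiguated so that
#' increasing depth points towards `proximal_ref` (the medulla centroid in
#' real data). Column bounds are the 0.03 and 0.97 quantiles (linear
#' interpolation between order statistics) of the site projections.
#'
#' @param positions n x 3 matrix of synapse positions, nm; n >= 10.
#' @param proximal_ref 3-vector towards the proximal side.
#' @param column_id,q,r optional identity of the column on the hex lattice.
#' @return a one-row `data.frame` (class `medulla_column`) with the axis,
#'   anchor (cloud centroid) and depth bounds.
#' @export
fit_column_axis <- function(positions, proximal_ref,
                            column_id = NA_character_, q = NA_integer_,
                            r = NA_integer_) {
  P <- as.matrix(positions)
  if (nrow(P) < 10L) stop("fit_column_axis: need at least 10 points")
  ctr <- colMeans(P)
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1] <= 0 || lam[2] / lam[1] < 1e-10)
    stop("fit_column_axis: rank-deficient point cloud (collinear or coincident)")
  if (lam[1] / lam[2] < 1.2)
    warning("fit_column_axis: ill-defined axis (leading eigenvalue ratio < 1.2)")
  axis <- e$vectors[, 1]
  if (sum(axis * (proximal_ref - ctr)) < 0) axis <- -axis
  proj <- drop((P - matrix(ctr, nrow(P), 3, byrow = TRUE)) %*% axis)
  qs <- stats::quantile(proj, c(0.03, 0.97), names = FALSE, type = 7)
  out <- data.frame(column_id = column_id, q = q, r = r,
                    anchor_x = ctr[1], anchor_y = ctr[2], anchor_z = ctr[3],
                    axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                    depth_lo = qs[1], depth_hi = qs[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("medulla_column", class(out))
  out
}

#' Medulla layer table
#'
#' Ten contiguous half-open fractional intervals for layers M1-M10 along
#' the distal-proximal column axis, expressed in percent of the column
#' span. The terminal upper edge is closed (it belongs to M10).
#'
#' @return a `data.frame` with columns layer, lo, hi.
#' @export
layer_table <- function() {
  lo <- c(-3.9, 5.5, 17.1, 30.8, 34.0, 43.2, 50.1, 63.1, 75.4, 92.4)
  hi <- c(lo[-1], 102.2)
  data.frame(layer = paste0("M", 1:10), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Look up the medulla layer of a depth fraction
#'
#' @param depth_percent numeric vector of depths along the distal-proximal
#'   axis, percent of the column span; must lie in \[-3.9, 102.2\].
#' @param layers a [layer_table()].
#' @return character vector of layer labels (M1-M10).
#' @export
layer_of <- function(depth_percent, layers = layer_table()) {
  if (any(!is.finite(depth_percent)))
    stop("layer_of: depth must be finite")
  lo <- layers$lo[1]; hi <- layers$hi[nrow(layers)]
  if (any(depth_percent < lo | depth_percent > hi))
    stop("layer_of: depth out of range [", lo, ", ", hi, "]")
  idx <- findInterval(depth_percent, c(layers$lo, hi),
                      rightmost.closed = TRUE)
  layers$layer[idx]
}

#' Flag equatorial medulla columns from photoreceptor counts
#'
#' Equatorial columns carry seven or eight R1-R6 photoreceptors where
#' non-equatorial columns carry six; the equator row anchors the hex-grid
#' alignment between columns and ommatidia.
#'
#' @param counts named integer vector: photoreceptor count per column id.
#' @return named logical vector: `TRUE` for equatorial columns.
#' @export
detect_equator <- function(counts) {
  if (any(counts < 0)) stop("detect_equator: counts must be >= 0")
  if (any(counts == 0))
    warning("detect_equator: column(s) with zero photoreceptors flagged non-equatorial")
  out <- counts %in% c(7L, 8L)
  names(out) <- names(counts)
  out
}

# Mirror a hex lattice in axial coordinates about a vertical axis,
# preserving rows (r invariant): q -> -(q + r).
hex_mirror <- function(df) {
  df$q <- -(df$q + df$r)
  df
}

#' Align two hexagonal grids into an eye map
#'
#' Maps medulla columns onto ommatidia by searching integer axial-lattice
#' offsets and the two mirror orientations, constrained so that the two
#' equator rows coincide, and keeping the assignment that minimizes the
#' number of unmatched points. Ties are broken by smallest offset
#' magnitude, then lexicographically by (dq, dr), with the unmirrored
#' orientation preferred. Every matched column inherits the viewing
#' direction (azimuth/elevation, degrees) of its ommatidium.
#'
#' @param columns `data.frame` with column_id, q, r, is_equator.
#' @param ommatidia `data.frame` with q, r, is_equator, azimuth_deg,
#'   elevation_deg.
#' @param allow_mirror search the mirrored orientation as well.
#' @return an `eye_map`: a `data.frame` (column_id, q, r, azimuth_deg,
#'   elevation_deg, is_equator) of matched columns, with attributes
#'   `unmatched_columns`, `offset` (dq, dr), `mirrored` and
#'   `n_unmatched`.
#' @export
align_hex_grids <- function(columns, ommatidia, allow_mirror = TRUE) {
  if (!nrow(columns) || !nrow(ommatidia))
    stop("align_hex_grids: empty lattice")
  if (!any(columns$is_equator) || !any(ommatidia$is_equator))
    stop("align_hex_grids: both lattices need at least one equator row")
  eq_c <- sort(unique(columns$r[columns$is_equator]))
  eq_o <- sort(unique(ommatidia$r[ommatidia$is_equator]))
  dr_cand <- sort(unique(as.vector(outer(eq_o, eq_c, "-"))))
  okey <- paste(ommatidia$q, ommatidia$r)
  best <- NULL
  for (mir in if (allow_mirror) c(FALSE, TRUE) else FALSE) {
    cc <- if (mir) hex_mirror(columns) else columns
    dq_cand <- seq(min(ommatidia$q) - max(cc$q), max(ommatidia$q) - min(cc$q))
    for (dr in dr_cand) for (dq in dq_cand) {
      hit <- paste(cc$q + dq, cc$r + dr) %in% okey
      unmatched <- (nrow(cc) - sum(hit)) + (nrow(ommatidia) - sum(hit))
      cand <- list(unmatched = unmatched, dq = dq, dr = dr, mir = mir,
                   mag = dq * dq + dr * dr)
      if (is.null(best) ||
          unmatched < best$unmatched ||
          (unmatched == best$unmatched && cand$mag < best$mag) ||
          (unmatched == best$unmatched && cand$mag == best$mag &&
           (cand$dq < best$dq ||
            (cand$dq == best$dq && cand$dr < best$dr) ||
            (cand$dq == best$dq && cand$dr == best$dr && !cand$mir && best$mir))))
        best <- cand
    }
  }
  cc <- if (best$mir) hex_mirror(columns) else columns
  idx <- match(paste(cc$q + best$dq, cc$r + best$dr), okey)
  ok <- !is.na(idx)
  out <- data.frame(column_id = columns$column_id[ok],
                    q = columns$q[ok], r = columns$r[ok],
                    azimuth_deg = ommatidia$azimuth_deg[idx[ok]],
                    elevation_deg = ommatidia$elevation_deg[idx[ok]],
                    is_equator = columns$is_equator[ok],
                    stringsAsFactors = FALSE)
  class(out) <- c("eye_map", class(out))
  attr(out, "unmatched_columns") <- columns$column_id[!ok]
  attr(out, "offset") <- c(dq = best$dq, dr = best$dr)
  attr(out, "mirrored") <- best$mir
  attr(out, "n_unmatched") <- best$unmatched
  out
}

#' Write an eye map as CSV
#'
#' @param eyemap an `eye_map` from [align_hex_grids()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eye_map <- function(eyemap, path) {
  utils::write.csv(as.data.frame(eyemap), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Perpendicular distance of points to each column axis; returns the
# nearest column id per point, breaking distance ties towards the
# lexicographically smaller column_id (columns are pre-sorted by id).
nearest_column <- function(points, columns, chunk = 4096L) {
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  cols <- columns[order(columns$column_id), , drop = FALSE]
  A <- as.matrix(cols[, c("anchor_x", "anchor_y", "anchor_z")])
  U <- as.matrix(cols[, c("axis_x", "axis_y", "axis_z")])
  out <- integer(nrow(P))
  for (s in seq(1L, nrow(P), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(P))
    # squared distance to line: |p-a|^2 - ((p-a).u)^2
    pa2 <- outer(rowSums(P[i, , drop = FALSE]^2), rowSums(A^2), "+") -
      2 * P[i, , drop = FALSE] %*% t(A)
    dot <- P[i, , drop = FALSE] %*% t(U) -
      matrix(rowSums(A * U), length(i), nrow(cols), byrow = TRUE)
    d2 <- pa2 - dot^2
    out[i] <- max.col(-d2, ties.method = "first")
  }
  cols$column_id[out]
}
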