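# Receptive-field prediction by synaptic back-tracing: MeTu column
# occupancies, direct (ER <- TuBu <- MeTu) and indirect
# (ER <- TuBu <- TuTu <- MeTu) per-column pathway values, covered-column
# counts with hexagonal outlines in eye coordinates, and analysis of
# imaging stimulus-response grids (dF/F, responsiveness, contour
# ellipses).

#' Medulla column occupancy of a MeTu neuron
#'
#' Assigns each of the neuron's qualifying synaptic sites (presynaptic by
#' default; a switch substitutes dendritic postsynaptic sites) to the
#' nearest column axis and reports the fraction of sites per column.
#' Fractions sum to 1 whenever the neuron has at least one site.
#'
#' @param sites n x 3 matrix of site positions, nm (may have zero rows).
#' @param columns a column table (rows as from [fit_column_axis()]).
#' @param metu_id optional id attached to the result.
#' @return a list (class `occupancy`) with `metu_id` and `fractions`
#'   (named numeric, one entry per occupied column).
#' @export
column_occupancy <- function(sites, columns, metu_id = NA_character_) {
  if (!nrow(columns)) stop("column_occupancy: no columns defined")
  S <- as.matrix(sites)
  if (!nrow(S)) {
    warning("column_occupancy: neuron has no qualifying sites")
    return(structure(list(metu_id = metu_id, fractions = numeric()),
                     class = "occupancy"))
  }
  assign <- nearest_column(S, columns)
  tab <- table(assign)
  structure(list(metu_id = metu_id,
                 fractions = stats::setNames(as.numeric(tab) / nrow(S),
                                             names(tab))),
            class = "occupancy")
}

# Occupancy list -> MeTu x column matrix over the given column ids.
occupancy_matrix <- function(occupancies, column_ids) {
  M <- matrix(0, length(occupancies), length(column_ids),
              dimnames = list(names(occupancies), column_ids))
  for (m in names(occupancies)) {
    fr <- occupancies[[m]]$fractions
    M[m, names(fr)] <- fr
  }
  M
}

#' Back-trace an ER neuron's visual field onto medulla columns
#'
#' For every medulla column, the direct pathway value is the sum over all
#' weighted branches ER <- TuBu <- MeTu ending at the column:
#' `D(c) = sum_b sum_m w(b->ER) * w(m->b) * occ(m, c)`. The indirect
#' pathway inserts the bilateral TuTu neurons:
#' `I(c) = sum_b sum_t sum_m w(b->ER) * w(t->b) * w(m->t) * occ(m, c)`.
#' Pathways through AOTU046 are excluded (its transmitter is not
#' conclusive); pass its id in `exclude`.
#'
#' @param er_id the ER neuron.
#' @param tubu_er `weight_matrix`: pre = TuBu, post = ER (bulb).
#' @param metu_tubu `weight_matrix`: pre = MeTu, post = TuBu (AOTUsu).
#' @param occupancies named list of [column_occupancy()] results, one per
#'   MeTu neuron.
#' @param metu_tutu,tutu_tubu weight matrices for the indirect pathway
#'   (pre = MeTu, post = TuTu and pre = TuTu, post = TuBu); required when
#'   `pathway` includes the indirect route.
#' @param pathway `"direct"`, `"indirect"` or `"both"`.
#' @param exclude neuron ids removed from every intermediate layer
#'   (e.g. AOTU046).
#' @return a list (class `column_field`) with `er_id`, `direct` and
#'   `indirect` (named numeric vectors over column ids; zero-length when
#'   the pathway was not requested).
#' @export
backtrace_field <- function(er_id, tubu_er, metu_tubu, occupancies,
                            metu_tutu = NULL, tutu_tubu = NULL,
                            pathway = c("both", "direct", "indirect"),
                            exclude = character()) {
  pathway <- match.arg(pathway)
  if (!er_id %in% tubu_er$post_ids) {
    warning("backtrace_field: ER neuron ", er_id, " has no TuBu input")
    return(structure(list(er_id = er_id, direct = numeric(),
                          indirect = numeric()), class = "column_field"))
  }
  keep_b <- setdiff(intersect(tubu_er$pre_ids, metu_tubu$post_ids), exclude)
  keep_m <- setdiff(intersect(metu_tubu$pre_ids, names(occupancies)), exclude)
  w_b <- tubu_er$values[keep_b, er_id]
  col_ids <- sort(unique(unlist(lapply(occupancies[keep_m],
                                       function(o) names(o$fractions)))))
  Occ <- occupancy_matrix(occupancies[keep_m], col_ids)  # m x c
  direct <- indirect <- numeric()
  if (pathway %in% c("both", "direct")) {
    W_mb <- metu_tubu$values[keep_m, keep_b, drop = FALSE]
    u_m <- drop(W_mb %*% w_b)                 # per-MeTu branch weight
    direct <- drop(t(Occ) %*% u_m)
    names(direct) <- col_ids
  }
  if (pathway %in% c("both", "indirect")) {
    if (is.null(metu_tutu) || is.null(tutu_tubu))
      stop("backtrace_field: indirect pathway needs metu_tutu and tutu_tubu")
    keep_t <- setdiff(intersect(tutu_tubu$pre_ids, metu_tutu$post_ids),
                      exclude)
    W_tb <- tutu_tubu$values[keep_t, keep_b, drop = FALSE]
    W_mt <- metu_tutu$values[intersect(keep_m, metu_tutu$pre_ids), keep_t,
                             drop = FALSE]
    u_t <- drop(W_tb %*% w_b)
    u_m <- stats::setNames(numeric(length(keep_m)), keep_m)
    u_m[rownames(W_mt)] <- drop(W_mt %*% u_t)
    indirect <- drop(t(Occ) %*% u_m[keep_m])
    names(indirect) <- col_ids
  }
  structure(list(er_id = er_id, direct = direct, indirect = indirect),
            class = "column_field")
}

#' Covered columns and outline of a visual field
#'
#' A column is covered when its direct pathway value exceeds `eps`
#' (default exactly 0: any positive direct weight covers). The outline is
#' the boundary of the union of the hexagonal eye-coordinate cells of the
#' covered columns, computed combinatorially (edges shared by two covered
#' cells cancel; surviving edges are stitched into closed loops). The hex
#' cell size derives from the nearest-neighbour angular spacing of the
#' eye map. Columns missing from the eye map are reported separately and
#' take no part in the outline.
#'
#' @param field a `column_field` from [backtrace_field()], or a named
#'   numeric vector of per-column values.
#' @param eyemap an `eye_map` ([align_hex_grids()]); optional when only
#'   the count is needed.
#' @param eps coverage threshold on the direct value.
#' @return a list (class `visual_area`) with `covered` (column ids),
#'   `n_covered`, `unmapped` (covered ids absent from the eye map) and
#'   `outline` (list of closed polygons, columns azimuth/elevation deg;
#'   empty when no eye map given).
#' @export
visual_area <- function(field, eyemap = NULL, eps = 0) {
  vals <- if (inherits(field, "column_field")) field$direct else field
  covered <- names(vals)[vals > eps]
  unmapped <- character(); outline <- list()
  if (!is.null(eyemap) && length(covered)) {
    unmapped <- setdiff(covered, eyemap$column_id)
    mapped <- eyemap[match(setdiff(covered, unmapped), eyemap$column_id), ,
                     drop = FALSE]
    outline <- hex_union_outline(mapped, eyemap)
  }
  structure(list(covered = covered, n_covered = length(covered),
                 unmapped = unmapped, outline = outline),
            class = "visual_area")
}

#' Union outline of several neurons' visual areas
#'
#' @param fields list of `column_field`s (one neuron type's population).
#' @inheritParams visual_area
#' @return a `visual_area` for the union of the individual covered sets.
#' @export
population_outline <- function(fields, eyemap, eps = 0) {
  covered <- unique(unlist(lapply(fields, function(f)
    names(f$direct)[f$direct > eps])))
  v <- stats::setNames(rep(1, length(covered)), covered)
  visual_area(v, eyemap, eps = 0)
}

# Boundary of a union of hexagonal lattice cells in eye coordinates.
# Each covered cell contributes 6 edges keyed by quantized endpoints;
# edges appearing twice are interior and cancel.
hex_union_outline <- function(cells, eyemap) {
  if (!nrow(cells)) return(list())
  # cell size: nearest-neighbour spacing on the eye map
  az <- eyemap$azimuth_deg; el <- eyemap$elevation_deg
  if (nrow(eyemap) > 1) {
    d2 <- as.matrix(stats::dist(cbind(az, el)))
    diag(d2) <- Inf
    pitch <- stats::median(apply(d2, 1, min))
  } else pitch <- 1
  rad <- pitch / sqrt(3)  # hexagon circumradius for centre spacing `pitch`
  ang <- pi / 6 + (0:5) * pi / 3  # vertices between the 6 neighbour axes
  edges <- list()
  for (i in seq_len(nrow(cells))) {
    cx <- cells$azimuth_deg[i]; cy <- cells$elevation_deg[i]
    vx <- cx + rad * cos(ang)
    vy <- cy + rad * sin(ang)
    for (k in seq_len(6)) {
      k2 <- if (k == 6) 1L else k + 1L
      a <- c(vx[k], vy[k]); b <- c(vx[k2], vy[k2])
      key_a <- paste(round(a / pitch, 3), collapse = ",")
      key_b <- paste(round(b / pitch, 3), collapse = ",")
      key <- paste(sort(c(key_a, key_b)), collapse = "|")
      edges[[key]] <- if (is.null(edges[[key]]))
        list(a = a, b = b, n = 1L) else {
          e <- edges[[key]]; e$n <- e$n + 1L; e
        }
    }
  }
  boundary <- Filter(function(e) e$n == 1L, edges)
  stitch_edge_loops(boundary)
}

# Stitch undirected edges into closed polygon loops.
stitch_edge_loops <- function(edges) {
  if (!length(edges)) return(list())
  key_of <- function(p) paste(round(p, 6), collapse = ",")
  remaining <- edges
  loops <- list()
  while (length(remaining)) {
    e <- remaining[[1]]; remaining[[1]] <- NULL
    loop <- rbind(e$a, e$b)
    repeat {
      tail_key <- key_of(loop[nrow(loop), ])
      nxt <- NULL
      for (j in seq_along(remaining)) {
        f <- remaining[[j]]
        if (key_of(f$a) == tail_key) { nxt <- f$b; break }
        if (key_of(f$b) == tail_key) { nxt <- f$a; break }
      }
      if (is.null(nxt)) break
      remaining[[j]] <- NULL
      loop <- rbind(loop, nxt)
      if (key_of(loop[nrow(loop), ]) == key_of(loop[1, ])) break
    }
    colnames(loop) <- c("azimuth_deg", "elevation_deg")
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Delta F / F from raw fluorescence
#'
#' Subtracts the empty-control ROI fluorescence frame by frame, takes the
#' baseline F0 as the mean of the lowest decile of the subtracted series,
#' and returns `(F - F0) / F0`.
#'
#' @param raw raw fluorescence series.
#' @param control empty-ROI series of the same length (default all zero).
#' @return numeric dF/F series.
#' @export
dff_from_raw <- function(raw, control = numeric(length(raw))) {
  if (!length(raw)) stop("dff_from_raw: empty series")
  if (length(control) != length(raw))
    stop("dff_from_raw: control length must match raw")
  f <- raw - control
  k <- max(1L, ceiling(length(f) / 10))
  f0 <- mean(sort(f)[seq_len(k)])
  if (f0 <= 0)
    stop("dff_from_raw: baseline F0 <= 0; signal not normalizable")
  (f - f0) / f0
}

#' Stimulus response and responsiveness of one ROI
#'
#' The per-trial response is the mean dF/F during the stimulation window
#' minus the mean dF/F during the pre-stimulus baseline window
#' (stimulus-minus-baseline sign convention). The ROI counts as
#' responsive at a stimulus position when the one-sample Wilcoxon
#' signed-rank test across trials gives p <= 0.05 *and* the mean response
#' exceeds the empty-control response (when one is supplied). With fewer
#' than ~50 trials the exact small-sample test is used automatically.
#'
#' @param traces numeric matrix, one trial per row, dF/F per frame.
#' @param stim_window integer frame indices of the 1-s stimulation
#'   period.
#' @param baseline_window integer frame indices of the 500-ms
#'   pre-stimulus period.
#' @param empty_response response of an empty ROI; the flag requires the
#'   mean response to exceed it (default 0, i.e. no control).
#' @param alpha significance level (default 0.05).
#' @return a list (class `stim_response`) with `trial_responses`,
#'   `mean_response`, `p` and `responsive`.
#' @export
stimulus_response <- function(traces, stim_window, baseline_window,
                              empty_response = 0, alpha = 0.05) {
  T <- if (is.null(dim(traces))) matrix(traces, nrow = 1) else as.matrix(traces)
  if (!nrow(T)) stop("stimulus_response: zero trials")
  nf <- ncol(T)
  if (any(c(stim_window, baseline_window) < 1) ||
      any(c(stim_window, baseline_window) > nf))
    stop("stimulus_response: window outside trace")
  resp <- rowMeans(T[, stim_window, drop = FALSE]) -
    rowMeans(T[, baseline_window, drop = FALSE])
  p <- if (all(resp == 0)) 1 else
    suppressWarnings(stats::wilcox.test(resp, mu = 0)$p.value)
  responsive <- is.finite(p) && p <= alpha &&
    mean(resp) > empty_response
  structure(list(trial_responses = resp, mean_response = mean(resp),
                 p = p, responsive = responsive),
            class = "stim_response")
}

#' Standard 38-position stimulus layout
#'
#' Thirty-eight square stimulus tiles of `extent_deg` by `extent_deg`
#' (18 degrees by default), non-overlapping, arranged as a 7 x 6 grid
#' with the four corners removed, centred on `center`.
#'
#' @param extent_deg tile size, degrees.
#' @param center length-2 centre of the layout (azimuth, elevation).
#' @return a `data.frame` with stim_index, azimuth_deg, elevation_deg,
#'   extent_deg (tile centres).
#' @export
stimulus_layout <- function(extent_deg = 18, center = c(0, 0)) {
  g <- expand.grid(col = 1:7, row = 1:6)
  g <- g[!(g$col %in% c(1, 7) & g$row %in% c(1, 6)), ]
  data.frame(stim_index = seq_len(nrow(g)),
             azimuth_deg = center[1] + (g$col - 4) * extent_deg,
             elevation_deg = center[2] + (g$row - 3.5) * extent_deg,
             extent_deg = extent_deg)
}

# Bilinear interpolation of a regular-grid response matrix onto points.
bilinear_interp <- function(xg, yg, Z, x, y) {
  ix <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  iy <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  tx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  ty <- (y - yg[iy]) / (yg[iy + 1L] - yg[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  Z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    Z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    Z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    Z[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Receptive-field contour ellipse
#'
#' Interpolates the mean responses of a stimulus grid bilinearly onto a
#' fine azimuth-elevation raster (zero-padded by one tile so contours
#' close), extracts the iso-contour at `level` times the maximum, and
#' fits an ellipse to the largest closed contour by the second-moment
#' (regionprops-style) method over the enclosed raster region: semi-axes
#' are twice the square roots of the region's covariance eigenvalues,
#' which is exact for a filled ellipse.
#'
#' @param grid a `data.frame` with azimuth_deg, elevation_deg and
#'   mean_response (one row per stimulus position), e.g. from
#'   [generate_response_grid()] summaries; non-responsive positions
#'   should carry response 0.
#' @param level contour level as a fraction of the maximum (default
#'   0.2).
#' @param raster_step fine raster step, degrees.
#' @return a list (class `rf_fit`) with `ellipse` (an `ellipse_fit`),
#'   `contours` (list of polygon matrices) and `level`.
#' @export
rf_ellipse <- function(grid, level = 0.2, raster_step = 1) {
  if (!nrow(grid) || all(grid$mean_response <= 0))
    stop("rf_ellipse: no responsive position")
  ax <- sort(unique(grid$azimuth_deg)); el <- sort(unique(grid$elevation_deg))
  step_a <- if (length(ax) > 1) min(diff(ax)) else 18
  step_e <- if (length(el) > 1) min(diff(el)) else 18
  # regular coarse grid, zero-filled (missing corners and padding ring)
  axp <- c(min(ax) - step_a, ax, max(ax) + step_a)
  elp <- c(min(el) - step_e, el, max(el) + step_e)
  Z <- matrix(0, length(axp), length(elp))
  Z[cbind(match(grid$azimuth_deg, axp), match(grid$elevation_deg, elp))] <-
    pmax(grid$mean_response, 0)
  xf <- seq(min(axp), max(axp), by = raster_step)
  yf <- seq(min(elp), max(elp), by = raster_step)
  Zi <- outer(seq_along(xf), seq_along(yf), function(i, j)
    bilinear_interp(axp, elp, Z, xf[i], yf[j]))
  thr <- level * max(Zi)
  cl <- grDevices::contourLines(xf, yf, Zi, levels = thr)
  closed <- Filter(function(cc) {
    isTRUE(all.equal(c(cc$x[1], cc$y[1]),
                     c(cc$x[length(cc$x)], cc$y[length(cc$y)]),
                     tolerance = 1e-6)) || length(cc$x) > 3
  }, cl)
  if (!length(closed))
    stop("rf_ellipse: no closed contour at level ", level,
         "; try a lower level")
  # largest contour by enclosed raster mass
  mask_of <- function(cc) {
    inside <- point_in_polygon(rep(xf, length(yf)),
                               rep(yf, each = length(xf)), cc$x, cc$y)
    matrix(inside, length(xf), length(yf))
  }
  masks <- lapply(closed, mask_of)
  sizes <- vapply(masks, sum, numeric(1))
  if (max(sizes) < 10)
    stop("rf_ellipse: contour region too small to fit; try a lower level")
  mask <- masks[[which.max(sizes)]]
  pts <- cbind(rep(xf, length(yf))[as.vector(mask)],
               rep(yf, each = length(xf))[as.vector(mask)])
  ell <- fit_span_ellipse(pts, k_sigma = 2)  # 2 sqrt(lambda): filled ellipse
  polys <- lapply(closed, function(cc) cbind(azimuth_deg = cc$x,
                                             elevation_deg = cc$y))
  structure(list(ellipse = ell, contours = polys, level = level),
            class = "rf_fit")
}

# Even-odd point-in-polygon test (vectorized over points).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
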