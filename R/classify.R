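# MeTu subtype classification: connectivity feature vectors, clustering
# (seeded nonlinear embedding or agglomerative dendrogram) and the
# explicit threshold rules that pin subtypes to printed synapse-count
# boundaries.

#' Build connectivity feature vectors
#'
#' One feature vector per neuron, made of an upstream block (the neuron's
#' summed input weight from each selected medulla input type) and a
#' downstream block (its output weight to each AOTU target type: the ten
#' TuBu types, the bilateral TuTu neurons and AOTU046). The upstream
#' block comes from an input-normalized medulla weight matrix (posts are
#' the classified neurons); the downstream block from the neuron's
#' fractional output in the AOTU. Missing partners contribute 0.
#'
#' The "top five per subtype" selection ranks input types by mean weight
#' within each provisional (sub)type, takes the top `top_n`, and uses the
#' union across subtypes as the upstream feature set. Without
#' provisional groups each neuron ranks its own inputs (the union over
#' neurons), which never drops a type that matters to some channel.
#'
#' @param medulla_matrix `weight_matrix`: pre = medulla input neurons,
#'   post = neurons to classify, input-normalized.
#' @param aotu_matrix `weight_matrix`: pre = neurons to classify, post =
#'   AOTU target neurons (TuBu/TuTu/AOTU046). Output weights are computed
#'   from its raw counts (each neuron's synapses to a type divided by its
#'   total synapses in the matrix).
#' @param type_map named character vector neuron_id -> type, covering the
#'   partners on both sides.
#' @param neuron_ids neurons to featurize (must appear in the matrices).
#' @param provisional named character vector neuron_id -> provisional
#'   (sub)type used for the top-five selection; default: each neuron is
#'   its own group.
#' @param top_n number of input types kept per provisional type.
#' @return a numeric matrix, one row per neuron; upstream columns are
#'   prefixed `in:` and downstream columns `out:`.
#' @export
build_feature_vectors <- function(medulla_matrix, aotu_matrix, type_map,
                                  neuron_ids, provisional = NULL,
                                  top_n = 5L) {
  missing_me <- setdiff(neuron_ids, medulla_matrix$post_ids)
  missing_ao <- setdiff(neuron_ids, aotu_matrix$pre_ids)
  if (length(missing_me) || length(missing_ao))
    stop("build_feature_vectors: neuron(s) absent from matrices: ",
         paste(utils::head(union(missing_me, missing_ao), 5), collapse = ", "))
  # upstream: sum input weight over pre neurons of each type
  pre_types <- unname(type_map[medulla_matrix$pre_ids])
  if (anyNA(pre_types))
    stop("build_feature_vectors: untyped medulla input neuron(s)")
  W <- medulla_matrix$values[, neuron_ids, drop = FALSE]
  up <- rowsum(W, group = pre_types)           # type x neuron
  # select top-n input types per provisional group by mean weight
  if (is.null(provisional))
    provisional <- stats::setNames(neuron_ids, neuron_ids)
  sel <- character()
  for (g in unique(provisional[neuron_ids])) {
    idx <- neuron_ids[provisional[neuron_ids] == g]
    mw <- rowMeans(up[, idx, drop = FALSE])
    sel <- union(sel, rownames(up)[order(-mw)][seq_len(min(top_n, nrow(up)))])
  }
  up <- up[sel, , drop = FALSE]
  # downstream: fractional output to each target type
  post_types <- unname(type_map[aotu_matrix$post_ids])
  if (anyNA(post_types))
    stop("build_feature_vectors: untyped AOTU target neuron(s)")
  cts <- aotu_matrix$counts[neuron_ids, , drop = FALSE]
  down_cts <- t(rowsum(t(cts), group = post_types))  # neuron x type
  tot <- rowSums(down_cts)
  down <- sweep(down_cts, 1, pmax(tot, 1), "/")
  out <- cbind(t(up), down)
  colnames(out) <- c(paste0("in:", rownames(up)),
                     paste0("out:", colnames(down)))
  rownames(out) <- neuron_ids
  out
}

#' Cluster neurons into subtypes
#'
#' Two modes. `"dendrogram"` computes an agglomerative tree (average
#' linkage on euclidean distance by default; the feature vectors are
#' normalized weight fractions, so euclidean distance keeps the
#' magnitude contrasts that separate channels sharing a target type,
#' while correlation distance is available for shape-only similarity)
#' and cuts it at `k` clusters or height `h`. `"embedding"` computes a seeded, reproducible
#' nonlinear 2-D embedding (UMAP) and groups it with model-based
#' (density) clustering. Identical seeds give identical output.
#'
#' @param features numeric matrix, one neuron per row
#'   ([build_feature_vectors()]).
#' @param mode `"dendrogram"` or `"embedding"`.
#' @param k number of clusters (dendrogram cut, and upper bound of the
#'   embedding grouping).
#' @param h dendrogram cut height (alternative to `k`).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param merge_within optional feature-name prefix (e.g. `"in:"` for
#'   the medulla-input block). When set in dendrogram mode, the tree is
#'   cut progressively deeper and clusters whose centroids are
#'   indistinguishable on the matching feature columns (closer than
#'   `merge_factor` times the pooled within-cluster spread) are merged
#'   until exactly `k` groups remain. This recovers channels whose
#'   subpopulations differ only in their downstream targets — the
#'   situation of dorsally versus ventrally projecting neurons of one
#'   medulla channel, which share one input fingerprint.
#' @param merge_factor threshold multiplier for the merge test.
#' @param seed integer seed for the embedding.
#' @return a list (class `subtype_clustering`) with `labels` (named
#'   integer vector), `mode`, and either `tree` (hclust) or `embedding`
#'   (n x 2 matrix).
#' @export
cluster_subtypes <- function(features, mode = c("dendrogram", "embedding"),
                             k = NULL, h = NULL,
                             distance = c("euclidean", "correlation"),
                             linkage = "average", merge_within = NULL,
                             merge_factor = 1, seed = 1L) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  X <- as.matrix(features)
  if (nrow(X) < 2L) {
    if (nrow(X) == 0L) stop("cluster_subtypes: need at least 1 neuron")
    return(structure(list(labels = stats::setNames(1L, rownames(X)),
                          mode = mode), class = "subtype_clustering"))
  }
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("cluster_subtypes: constant feature matrix; single cluster")
    return(structure(list(labels = stats::setNames(rep(1L, nrow(X)),
                                                   rownames(X)),
                          mode = mode), class = "subtype_clustering"))
  }
  if (mode == "dendrogram") {
    d <- if (distance == "correlation") {
      # rows with zero variance correlate as NA; map them to max distance
      cm <- suppressWarnings(stats::cor(t(X)))
      cm[is.na(cm)] <- 0
      stats::as.dist(1 - cm)
    } else stats::dist(X)
    tree <- stats::hclust(d, method = linkage)
    if (is.null(k) && is.null(h)) k <- 2L
    labels <- if (!is.null(k)) stats::cutree(tree, k = k)
    else stats::cutree(tree, h = h)
    if (!is.null(merge_within) && !is.null(k)) {
      cols <- grep(paste0("^", merge_within), colnames(X))
      if (!length(cols))
        stop("cluster_subtypes: no feature matches merge_within prefix")
      B <- X[, cols, drop = FALSE]
      for (extra in 0:(nrow(X) - k)) {
        labs <- stats::cutree(tree, k = min(k + extra, nrow(X)))
        labs <- merge_indistinct(B, labs, merge_factor)
        if (length(unique(labs)) == k && !any_impure(B, labs)) {
          labels <- labs
          break
        }
      }
    }
    labels <- stats::setNames(as.integer(factor(labels)), rownames(X))
    structure(list(labels = labels, mode = mode, tree = tree),
              class = "subtype_clustering")
  } else {
    set.seed(seed)
    nn <- min(15L, nrow(X) - 1L)
    emb <- uwot::umap(X, n_neighbors = nn, n_components = 2L,
                      seed = seed, n_threads = 1L, n_sgd_threads = 1L)
    rownames(emb) <- rownames(X)
    G <- if (is.null(k)) 1:9 else 1:k
    fit <- mclust::Mclust(emb, G = G, verbose = FALSE)
    labels <- stats::setNames(as.integer(fit$classification), rownames(X))
    structure(list(labels = labels, mode = mode, embedding = emb),
              class = "subtype_clustering")
  }
}

# A cluster is impure when its spread on the feature block far exceeds
# the typical cluster spread: the signature of two distinct profiles cut
# together. Used to reject too-shallow tree cuts.
any_impure <- function(B, labels, factor = 4) {
  ids <- unique(labels)
  msd <- vapply(ids, function(g) {
    Bi <- B[labels == g, , drop = FALSE]
    if (nrow(Bi) < 2L) return(0)
    mean(rowSums(sweep(Bi, 2, colMeans(Bi))^2))
  }, numeric(1))
  base <- stats::median(msd[msd > 0])
  if (!length(base) || is.na(base) || base == 0) return(FALSE)
  any(msd > factor * base)
}

# Iteratively merge clusters whose centroids on the given feature block
# are closer than `factor` times the pooled within-cluster RMS distance
# on that block (i.e. whose profiles are indistinguishable there).
merge_indistinct <- function(B, labels, factor = 1) {
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) return(labels)
    cent <- do.call(rbind, lapply(ids, function(g)
      colMeans(B[labels == g, , drop = FALSE])))
    within2 <- mean(unlist(lapply(ids, function(g) {
      Bi <- B[labels == g, , drop = FALSE]
      rowSums(sweep(Bi, 2, colMeans(Bi))^2)
    })))
    thresh <- factor * sqrt(2 * within2)  # expected same-profile spread
    D <- as.matrix(stats::dist(cent))
    diag(D) <- Inf
    if (min(D) >= thresh) return(labels)
    pair <- which(D == min(D), arr.ind = TRUE)[1, ]
    labels[labels == ids[max(pair)]] <- ids[min(pair)]
  }
}

#' Rule-based MeTu subtype label
#'
#' Applies the explicit classification rules. The MeTu class follows the
#' AOTUsu subregion holding the neuron's axonal boutons (posterior
#' lateral -> MeTu1, posterior central -> MeTu2, anterior -> MeTu3,
#' medial -> MeTu4). Within classes: MeTu2a prefers TuBu01 over TuBu06
#' (MeTu2b the reverse); MeTu3a is any MeTu3 with 13 or fewer Mi15
#' synapses, remaining MeTu3 split by dominant TuBu partner (TuBu07 ->
#' MeTu3b, TuBu09/TuBu10 -> MeTu3c); MeTu4d is any MeTu4 with fewer than
#' 15 lobula pre- plus postsynapses, remaining MeTu4 split by dominant
#' TuBu partner (TuBu03/TuBu04 -> MeTu4a, TuBu02 -> MeTu4b, TuBu05 ->
#' MeTu4c). A neuron without axonal synapses in any AOTUsu subregion is
#' labelled `"MeTu_incomplete"`.
#'
#' @param aotu_subregion `"posterior_lateral"`, `"posterior_central"`,
#'   `"anterior"`, `"medial"`, or `NA` when the neuron has no AOTUsu
#'   axonal synapses.
#' @param mi15_synapses synapse count with Mi15 neurons in the medulla.
#' @param lobula_synapses total lobula pre- plus postsynapses.
#' @param tubu_synapses named numeric vector of synapse counts onto TuBu
#'   types (names `"TuBu01"` ... `"TuBu10"`).
#' @return the subtype label (character).
#' @export
rule_subtype <- function(aotu_subregion, mi15_synapses = 0,
                         lobula_synapses = 0,
                         tubu_synapses = numeric()) {
  tb <- function(type) if (type %in% names(tubu_synapses))
    tubu_synapses[[type]] else 0
  dominant <- function() {
    if (!length(tubu_synapses) || all(tubu_synapses == 0)) return(NA_character_)
    names(tubu_synapses)[which.max(tubu_synapses)]
  }
  if (is.na(aotu_subregion)) return("MeTu_incomplete")
  switch(aotu_subregion,
    posterior_lateral = "MeTu1",
    posterior_central = if (tb("TuBu01") >= tb("TuBu06")) "MeTu2a" else "MeTu2b",
    anterior = {
      if (mi15_synapses <= 13) "MeTu3a"
      else if (dominant() %in% c("TuBu09", "TuBu10")) "MeTu3c" else "MeTu3b"
    },
    medial = {
      if (lobula_synapses < 15) "MeTu4d"
      else switch(dominant(),
                  TuBu03 = , TuBu04 = "MeTu4a",
                  TuBu02 = "MeTu4b",
                  TuBu05 = "MeTu4c",
                  "MeTu4")
    },
    stop("rule_subtype: unknown AOTUsu subregion: ", aotu_subregion))
}

#' Fit a dendritic-span ellipse
#'
#' Maximum-likelihood 2-D Gaussian fit (mean and covariance, optionally
#' weighted) of synapse positions projected into the medulla tangent
#' plane. The span ellipse is the k-sigma contour (1 sigma by default):
#' semi-axes are `k` times the square roots of the covariance
#' eigenvalues. The ellipse angle is measured from the dorsal-ventral
#' (second) axis of the projection plane towards the first axis, mapped
#' to \[0, 180).
#'
#' @param points n x 2 matrix: column 1 along the anterior-posterior
#'   axis, column 2 along the dorsal-ventral axis; n >= 10 (rank 2).
#' @param weights optional non-negative point weights.
#' @param k_sigma contour level in sigmas.
#' @return an `ellipse_fit`: list with `centroid`, `a` (semi-major), `b`
#'   (semi-minor), `theta_deg` in \[0, 180) and `ratio = a/b`.
#' @export
fit_span_ellipse <- function(points, weights = NULL, k_sigma = 1) {
  P <- as.matrix(points)
  if (ncol(P) != 2L) stop("fit_span_ellipse: points must be n x 2")
  if (is.null(weights)) weights <- rep(1, nrow(P))
  if (any(weights < 0)) stop("fit_span_ellipse: negative weights")
  if (sum(weights > 0) < 10L)
    stop("fit_span_ellipse: need at least 10 (positively weighted) points")
  w <- weights / sum(weights)
  mu <- colSums(P * w)
  D <- sweep(P, 2, mu)
  C <- t(D) %*% (D * w)  # MLE covariance
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] <= 1e-12 * max(e$values[1], 1))
    stop("fit_span_ellipse: rank-deficient (collinear) point cloud")
  v1 <- e$vectors[, 1]
  theta <- atan2(v1[1], v1[2]) * 180 / pi
  theta <- theta %% 180
  a <- k_sigma * sqrt(e$values[1]); b <- k_sigma * sqrt(e$values[2])
  structure(list(centroid = mu, a = a, b = b, theta_deg = theta,
                 ratio = a / b),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> centre (%.3g, %.3g)  a=%.3g b=%.3g  theta=%.1f deg  ratio=%.2f\n",
              x$centroid[1], x$centroid[2], x$a, x$b, x$theta_deg, x$ratio))
  invisible(x)
}

#' Rayleigh test for axial orientation data
#'
#' Tests orientation angles (axial data in \[0, 180) degrees) for
#' uniformity. Angles are doubled to remove the axial ambiguity; the
#' resultant length of the doubled angles gives the test statistic
#' `z = n * Rbar^2` with the second-order tail approximation
#' `p = exp(-z) * (1 + (2 z - z^2) / (4 n))`, clamped to (0, 1\]. The
#' mean angle is half the circular mean of the doubled angles.
#'
#' @param angles_deg orientation angles in degrees, axial (\[0, 180));
#'   n >= 5.
#' @return a list (class `axial_stats`) with `n`, `mean_angle_deg`,
#'   `Rbar`, `z` and `p`.
#' @export
rayleigh_axial <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 5L) stop("rayleigh_axial: need at least 5 angles")
  a <- 2 * angles_deg * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  Rbar <- sqrt(C^2 + S^2)
  z <- n * Rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  mean_angle <- ((atan2(S, C) * 180 / pi) / 2) %% 180
  structure(list(n = n, mean_angle_deg = mean_angle, Rbar = Rbar,
                 z = z, p = p),
            class = "axial_stats")
}

#' Radial synapse density over equal-area annuli
#'
#' Bins dendritic synapses into concentric annuli of equal area `A`
#' around a centre (outer radii `r_k = sqrt(k A / pi)`) and reports the
#' density `count_k / A` for every annulus up to the one containing the
#' outermost synapse.
#'
#' @param points n x 2 matrix of positions in the tangent plane,
#'   micrometres.
#' @param center length-2 centre (default: the Gaussian-fit centroid of
#'   the points).
#' @param annulus_area_um2 area of each annulus, square micrometres.
#' @return a `data.frame` with annulus, r_inner, r_outer, count, density
#'   (per square micrometre); zero rows when there are no synapses.
#' @export
annulus_density <- function(points, center = NULL,
                            annulus_area_um2 = 314.15) {
  P <- as.matrix(points)
  if (!nrow(P))
    return(data.frame(annulus = integer(), r_inner = numeric(),
                      r_outer = numeric(), count = integer(),
                      density = numeric()))
  if (is.null(center)) center <- colMeans(P)
  r <- sqrt(rowSums(sweep(P, 2, center)^2))
  A <- annulus_area_um2
  k <- pmax(1L, ceiling(pi * r^2 / A))
  K <- max(k)
  counts <- tabulate(k, nbins = K)
  data.frame(annulus = seq_len(K),
             r_inner = sqrt((seq_len(K) - 1) * A / pi),
             r_outer = sqrt(seq_len(K) * A / pi),
             count = counts,
             density = counts / A)
}

#' Retinotopy of a neuron population
#'
#' Pairs each neuron's dendritic position along the medulla
#' anterior-posterior axis with its axonal position along the target
#' region's dorsal-ventral axis and reports the Spearman rank
#' correlation, the statistic behind the observation that anterior
#' medulla positions map to ventral AOTUsu positions.
#'
#' @param neuron_ids character vector.
#' @param medulla_pos numeric: dendritic centroid projected on the
#'   anterior-posterior axis, one per neuron.
#' @param target_pos numeric: axonal centroid projected on the target
#'   dorsal-ventral axis, one per neuron.
#' @return a list (class `retinotopy`) with `pairs` (data.frame) and
#'   `rho`.
#' @export
retinotopy <- function(neuron_ids, medulla_pos, target_pos) {
  n <- length(neuron_ids)
  if (n < 3L) stop("retinotopy: need at least 3 neurons")
  if (stats::sd(medulla_pos) == 0 || stats::sd(target_pos) == 0)
    stop("retinotopy: zero variance in positions; correlation undefined")
  rho <- stats::cor(medulla_pos, target_pos, method = "spearman")
  structure(list(pairs = data.frame(neuron_id = neuron_ids,
                                    medulla_pos = medulla_pos,
                                    target_pos = target_pos,
                                    stringsAsFactors = FALSE),
                 rho = rho),
            class = "retinotopy")
}

#' Columns spanned by dendritic arbors
#'
#' Assigns every dendritic synapse to its nearest medulla column axis
#' (perpendicular distance; ties towards the lexicographically smaller
#' column id) and reports the number of distinct columns each neuron
#' spans plus the inverse tally of neurons per column.
#'
#' @param synapses synapse table of dendritic synapses; `post_id`
#'   identifies the neuron.
#' @param columns a column table (rows as from [fit_column_axis()]).
#' @return a list with `per_neuron` (neuron_id, n_columns),
#'   `per_column` (column_id, n_neurons) and `assignment` (the per-
#'   synapse column ids).
#' @export
columns_spanned <- function(synapses, columns) {
  if (!nrow(columns)) stop("columns_spanned: no columns defined")
  assign <- nearest_column(as.matrix(synapses[, c("x_nm", "y_nm", "z_nm")]),
                           columns)
  per_neuron <- stats::aggregate(
    list(n_columns = assign),
    by = list(neuron_id = synapses$post_id),
    FUN = function(x) length(unique(x)))
  pairs <- unique(data.frame(neuron_id = synapses$post_id,
                             column_id = assign))
  tally <- table(factor(pairs$column_id, levels = sort(columns$column_id)))
  per_column <- data.frame(column_id = names(tally),
                           n_neurons = as.integer(tally),
                           stringsAsFactors = FALSE)
  list(per_neuron = per_neuron, per_column = per_column, assignment = assign)
}
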