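make_feature_fixture <- function(seed = 31) {
  set.seed(seed)
  pre <- sprintf("in%02d", 1:12)
  metu <- sprintf("m%02d", 1:6)
  targ <- sprintf("t%02d", 1:4)
  me_tab <- syn_table(sample(pre, 800, TRUE), sample(metu, 800, TRUE))
  ao_tab <- syn_table(sample(metu, 500, TRUE), sample(targ, 500, TRUE))
  cfg <- pipeline_config(min_regional_connections = 0)
  tmap <- c(stats::setNames(sub("[0-9]+$", "", pre), pre),
            stats::setNames(rep(c("TA", "TB"), 2), targ))
  list(me = neuron_weight_matrix(me_tab, pre, metu, config = cfg),
       ao = neuron_weight_matrix(ao_tab, metu, targ, config = cfg),
       tmap = tmap, metu = metu, me_tab = me_tab, ao_tab = ao_tab)
}

test_that("feature vectors recompute from raw synapse counts", {
  fx <- make_feature_fixture()
  fv <- build_feature_vectors(fx$me, fx$ao, fx$tmap, fx$metu)
  expect_true(all(fv >= 0 & fv <= 1))
  for (m in fx$metu) {
    # upstream: fraction of m's medulla input from each type
    inputs <- fx$me_tab[fx$me_tab$post_id == m, "pre_id"]
    up <- table(fx$tmap[inputs]) / length(inputs)
    for (tp in names(up))
      expect_equal(fv[m, paste0("in:", tp)], unname(up[tp]),
                   tolerance = 1e-12)
    # downstream: fraction of m's AOTU output to each target type
    outs <- fx$ao_tab[fx$ao_tab$pre_id == m, "post_id"]
    dn <- table(fx$tmap[outs]) / length(outs)
    for (tp in names(dn))
      expect_equal(fv[m, paste0("out:", tp)], unname(dn[tp]),
                   tolerance = 1e-12)
  }
})

test_that("feature vectors flag missing neurons and align permuted partners", {
  fx <- make_feature_fixture()
  expect_error(build_feature_vectors(fx$me, fx$ao, fx$tmap,
                                     c(fx$metu, "ghost")), "ghost")
  # a neuron with a single input type at weight 0.6 keeps exactly that
  cfg <- pipeline_config(min_regional_connections = 0)
  me <- neuron_weight_matrix(
    rbind(syn_table(rep("in01", 6), "mx"), syn_table(rep("z", 4), "mx")),
    c("in01", "z"), "mx", config = cfg)
  ao <- neuron_weight_matrix(syn_table(rep("mx", 5), "t01"), "mx", "t01",
                             config = cfg)
  tmap <- c(in01 = "A", z = "Z", t01 = "T")
  fv <- build_feature_vectors(me, ao, tmap, "mx")
  expect_equal(unname(fv["mx", "in:A"]), 0.6)
  expect_equal(unname(fv["mx", "out:T"]), 1)
})

test_that("clustering separates planted blocks and is reproducible", {
  set.seed(33)
  X <- rbind(matrix(rnorm(100, 0), 10), matrix(rnorm(100, 6), 10))
  rownames(X) <- sprintf("n%02d", 1:20)
  cl <- cluster_subtypes(X, "dendrogram", k = 2)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  # single neuron: single cluster, no error
  one <- cluster_subtypes(X[1, , drop = FALSE], "dendrogram")
  expect_equal(unname(one$labels), 1L)
  # constant features warn and collapse
  expect_warning(cc <- cluster_subtypes(matrix(1, 5, 3), "dendrogram"),
                 "constant")
  expect_equal(length(unique(cc$labels)), 1L)
  # embedding mode: same seed, identical output
  e1 <- cluster_subtypes(X, "embedding", k = 4, seed = 9L)
  e2 <- cluster_subtypes(X, "embedding", k = 4, seed = 9L)
  expect_identical(e1$embedding, e2$embedding)
  expect_identical(e1$labels, e2$labels)
  expect_equal(mclust::adjustedRandIndex(e1$labels, rep(1:2, each = 10)), 1)
})

test_that("indistinguishable-profile merging joins split channels only", {
  set.seed(34)
  # three planted groups; group C has a bimodal downstream block but one
  # upstream fingerprint, so a deep cut splits it and the merge step
  # must rejoin it without joining A and B
  up <- rbind(matrix(rnorm(60, 0, .05), 20),
              matrix(rnorm(60, 1, .05), 20),
              matrix(rnorm(60, 2, .05), 20))
  down <- rbind(matrix(0, 40, 1), matrix(rep(c(0, 3), each = 10), 20))
  X <- cbind(up, down)
  colnames(X) <- c(paste0("in:f", 1:3), "out:g")
  rownames(X) <- sprintf("n%02d", 1:60)
  cl <- cluster_subtypes(X, "dendrogram", k = 3, merge_within = "in:")
  truth <- rep(1:3, each = 20)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
})

test_that("explicit subtype rules flip at the printed synapse thresholds", {
  # MeTu class from the AOTUsu subregion
  expect_equal(rule_subtype("posterior_lateral"), "MeTu1")
  expect_equal(rule_subtype(NA), "MeTu_incomplete")
  # MeTu3a at 13 or fewer Mi15 synapses, both sides of the boundary
  expect_equal(rule_subtype("anterior", mi15_synapses = 13), "MeTu3a")
  expect_equal(rule_subtype("anterior", mi15_synapses = 14,
                            tubu_synapses = c(TuBu07 = 5)), "MeTu3b")
  expect_equal(rule_subtype("anterior", mi15_synapses = 14,
                            tubu_synapses = c(TuBu09 = 9, TuBu07 = 3)),
               "MeTu3c")
  # MeTu4d under 15 lobula synapses, both sides
  expect_equal(rule_subtype("medial", lobula_synapses = 14), "MeTu4d")
  expect_equal(rule_subtype("medial", lobula_synapses = 15,
                            tubu_synapses = c(TuBu05 = 4)), "MeTu4c")
  expect_equal(rule_subtype("medial", lobula_synapses = 20,
                            tubu_synapses = c(TuBu02 = 7, TuBu05 = 2)),
               "MeTu4b")
  expect_equal(rule_subtype("medial", lobula_synapses = 20,
                            tubu_synapses = c(TuBu03 = 6)), "MeTu4a")
  # MeTu2a prefers TuBu01 over TuBu06
  expect_equal(rule_subtype("posterior_central",
                            tubu_synapses = c(TuBu01 = 8, TuBu06 = 2)),
               "MeTu2a")
  expect_equal(rule_subtype("posterior_central",
                            tubu_synapses = c(TuBu01 = 1, TuBu06 = 9)),
               "MeTu2b")
  expect_error(rule_subtype("sideways"), "unknown")
})

test_that("span ellipses recover planted Gaussian clouds", {
  set.seed(35)
  # isotropic cloud: ratio close to one
  iso <- matrix(rnorm(2000), ncol = 2)
  f <- fit_span_ellipse(iso)
  expect_gte(f$ratio, 1)
  expect_lt(f$ratio, 1.1)
  # planted ratio 2 at 30 degrees from vertical, n = 300 per draw;
  # the median over replicate draws removes single-sample eigenvalue
  # noise and must sit within 5 % / 3 degrees of the planted values
  th <- 30 * pi / 180
  fits <- replicate(25, {
    u <- rnorm(300, 0, 2); v <- rnorm(300, 0, 1)
    pts <- cbind(u * sin(th) + v * cos(th), u * cos(th) - v * sin(th))
    f <- fit_span_ellipse(pts)
    c(f$ratio, f$theta_deg)
  })
  expect_lt(abs(median(fits[1, ]) - 2) / 2, 0.05)
  expect_lt(abs(median(fits[2, ]) - 30), 3)
  # independent covariance-eigendecomposition oracle on one draw
  u <- rnorm(300, 0, 2); v <- rnorm(300, 0, 1)
  pts <- cbind(u * sin(th) + v * cos(th), u * cos(th) - v * sin(th))
  f2 <- fit_span_ellipse(pts)
  C <- stats::cov(pts) * (299 / 300)
  ev <- eigen(C)$values
  expect_equal(f2$ratio, sqrt(ev[1] / ev[2]), tolerance = 1e-9)
  # collinear points are an error
  expect_error(fit_span_ellipse(cbind(1:20, (1:20) * 2)), "rank-deficient")
  expect_error(fit_span_ellipse(iso[1:5, ]), "at least 10")
})

test_that("span-ellipse fits are rotation equivariant", {
  set.seed(36)
  u <- rnorm(200, 0, 3); v <- rnorm(200, 0, 1)
  pts <- cbind(v, u)   # major axis vertical: theta ~ 0
  base <- fit_span_ellipse(pts)
  for (phi in runif(5, 0, 180)) {
    a <- phi * pi / 180
    R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    rot <- fit_span_ellipse(pts %*% t(R))
    expect_equal(rot$ratio, base$ratio, tolerance = 1e-9)
    # counter-clockwise point rotation decreases the angle-from-vertical
    want <- (base$theta_deg - phi) %% 180
    d <- abs(rot$theta_deg - want)
    expect_lt(min(d, 180 - d), 1e-6)
  }
})

test_that("axial Rayleigh statistics behave at the concentration extremes", {
  same <- rep(37.5, 20)
  s <- rayleigh_axial(same)
  expect_equal(s$Rbar, 1)
  expect_lt(s$p, 1e-6)
  expect_equal(s$mean_angle_deg, 37.5, tolerance = 1e-9)
  # perpendicular orientations cancel after angle doubling
  anti <- rep(c(0, 90), 10)
  s2 <- rayleigh_axial(anti)
  expect_equal(s2$Rbar, 0, tolerance = 1e-12)
  expect_gt(s2$p, 0.99)
  expect_error(rayleigh_axial(c(1, 2, 3, 4)), "at least 5")
})

test_that("annulus densities are flat for uniform discs", {
  set.seed(37)
  # uniform disc of radius covering ~8 annuli of area A
  A <- 314.15
  R <- sqrt(8 * A / pi)
  r <- R * sqrt(runif(10000)); a <- runif(10000, 0, 2 * pi)
  prof <- annulus_density(cbind(r * cos(a), r * sin(a)),
                          center = c(0, 0), annulus_area_um2 = A)
  dens <- prof$density[1:5]
  expect_true(all(abs(dens - mean(dens)) / mean(dens) < 0.1))
  # single synapse at the centre occupies only the first annulus
  one <- annulus_density(matrix(c(0, 0), 1), center = c(0, 0))
  expect_equal(one$annulus, 1L)
  expect_equal(one$count, 1L)
  # all synapses just inside the first radius: density n / A
  r1 <- sqrt(A / pi) * 0.999
  all1 <- annulus_density(cbind(rep(r1, 50), 0), center = c(0, 0),
                          annulus_area_um2 = A)
  expect_equal(all1$density[1], 50 / A)
  expect_equal(nrow(annulus_density(matrix(numeric(), 0, 2))), 0L)
})

test_that("retinotopy reports rank correlations with guards", {
  set.seed(38)
  me <- runif(30); dv <- 2 + 3 * me
  expect_gte(retinotopy(sprintf("n%d", 1:30), me, dv)$rho, 0.95)
  expect_lte(retinotopy(sprintf("n%d", 1:30), me, -dv)$rho, -0.95)
  expect_error(retinotopy(c("a", "b"), c(1, 2), c(1, 2)), "at least 3")
  expect_error(retinotopy(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1)),
               "zero variance")
})

test_that("column spans count distinct nearest columns with stable ties", {
  centres <- cbind(c(0, 1000, 2000, 0, 1000, 2000),
                   c(0, 0, 0, 1000, 1000, 1000))
  cols <- toy_columns(centres)
  # all synapses nearest one column
  one <- syn_table(rep("p", 5), rep("n1", 5), x = 10, y = -5,
                   z = c(1, 2, 3, 4, 5))
  cs <- columns_spanned(one, cols)
  expect_equal(cs$per_neuron$n_columns, 1L)
  # a neuron planted over all six columns with zero noise spans six
  six <- syn_table(rep("p", 6), rep("n2", 6), x = centres[, 1],
                   y = centres[, 2], z = 1)
  expect_equal(columns_spanned(six, cols)$per_neuron$n_columns, 6L)
  # equidistant synapse: lexicographically smaller column id wins
  mid <- syn_table("p", "n3", x = 500, y = 0, z = 0)
  expect_equal(columns_spanned(mid, cols)$assignment, "c01")
  expect_error(columns_spanned(one, cols[0, ]), "no columns")
})
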