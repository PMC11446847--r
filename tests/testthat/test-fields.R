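test_that("column occupancy fractions count nearest-axis sites", {
  cols <- toy_columns(cbind(c(0, 1000), c(0, 0)))
  occ <- column_occupancy(rbind(c(10, 0, 5), c(-5, 2, 1), c(990, 0, 3)),
                          cols, "m1")
  expect_equal(occ$fractions, c(c01 = 2 / 3, c02 = 1 / 3))
  one <- column_occupancy(rbind(c(0, 0, 0), c(1, 1, 9)), cols)
  expect_equal(one$fractions, c(c01 = 1))
  expect_warning(em <- column_occupancy(matrix(numeric(), 0, 3), cols),
                 "no qualifying")
  expect_equal(length(em$fractions), 0L)
  expect_error(column_occupancy(rbind(c(0, 0, 0)), cols[0, ]), "no columns")
})

test_that("occupancy assignment matches a brute-force nearest-axis oracle", {
  set.seed(41)
  centres <- cbind(runif(12, 0, 5000), runif(12, 0, 5000))
  cols <- toy_columns(centres)
  pts <- cbind(runif(200, -500, 5500), runif(200, -500, 5500),
               runif(200, 0, 800))
  got <- avpconnect:::nearest_column(pts, cols)
  # brute force: axes are vertical lines, so distance is planar
  want <- vapply(seq_len(200), function(i) {
    d <- sqrt((pts[i, 1] - centres[, 1])^2 + (pts[i, 2] - centres[, 2])^2)
    sort(cols$column_id)[which.min(d[order(cols$column_id)])]
  }, character(1))
  expect_identical(got, want)
})

test_that("back-traced fields multiply weights along single chains", {
  w_be <- toy_weight_matrix(matrix(0.5, 1, 1, dimnames = list("b", "er")))
  w_mb <- toy_weight_matrix(matrix(0.4, 1, 1, dimnames = list("m", "b")))
  occ <- list(m = structure(list(metu_id = "m", fractions = c(cA = 1)),
                            class = "occupancy"))
  f <- backtrace_field("er", w_be, w_mb, occ, pathway = "direct")
  expect_equal(f$direct, c(cA = 0.2))
  # no MeTu upstream: an all-zero field
  w_mb0 <- toy_weight_matrix(matrix(0, 1, 1, dimnames = list("m", "b")))
  f0 <- backtrace_field("er", w_be, w_mb0, occ, pathway = "direct")
  expect_true(all(f0$direct == 0))
  # unknown ER: empty field with warning
  expect_warning(fe <- backtrace_field("nope", w_be, w_mb, occ,
                                       pathway = "direct"), "no TuBu")
  expect_equal(length(fe$direct), 0L)
})

test_that("fields equal brute-force path enumeration on random fixtures", {
  for (seed in 1:100) {
    fx <- make_backtrace_fixture(seed)
    f <- backtrace_field("er", fx$w_be, fx$w_mb, fx$occ,
                         metu_tutu = fx$w_mt, tutu_tubu = fx$w_tb,
                         pathway = "both")
    # brute force over all (m, b) and (m, t, b) paths
    D <- I <- stats::setNames(numeric(length(fx$cols)), fx$cols)
    for (b in fx$tubu) for (m in fx$metu) {
      wb <- fx$w_be$values[b, "er"] * fx$w_mb$values[m, b]
      for (cc in fx$cols)
        D[cc] <- D[cc] + wb * fx$occ[[m]]$fractions[cc]
      for (t in fx$tutu) {
        wi <- fx$w_be$values[b, "er"] * fx$w_tb$values[t, b] *
          fx$w_mt$values[m, t]
        for (cc in fx$cols)
          I[cc] <- I[cc] + wi * fx$occ[[m]]$fractions[cc]
      }
    }
    expect_lt(max(abs(f$direct[fx$cols] - D)), 1e-12)
    expect_lt(max(abs(f$indirect[fx$cols] - I)), 1e-12)
  }
})

test_that("direct fields conserve total pathway weight", {
  for (seed in 1:20) {
    fx <- make_backtrace_fixture(seed)
    f <- backtrace_field("er", fx$w_be, fx$w_mb, fx$occ, pathway = "direct")
    want <- sum(fx$w_be$values[, "er"] *
                  colSums(fx$w_mb$values))
    expect_equal(sum(f$direct), want, tolerance = 1e-9)
  }
})

test_that("excluded intermediates take no part in the field", {
  fx <- make_backtrace_fixture(7)
  f_all <- backtrace_field("er", fx$w_be, fx$w_mb, fx$occ,
                           pathway = "direct")
  f_ex <- backtrace_field("er", fx$w_be, fx$w_mb, fx$occ,
                          pathway = "direct", exclude = "b1")
  manual <- stats::setNames(numeric(length(fx$cols)), fx$cols)
  for (b in setdiff(fx$tubu, "b1")) for (m in fx$metu)
    manual <- manual + fx$w_be$values[b, "er"] * fx$w_mb$values[m, b] *
      fx$occ[[m]]$fractions[fx$cols]
  expect_equal(unname(f_ex$direct[fx$cols]), unname(manual))
  expect_gt(sum(f_all$direct), sum(f_ex$direct))
})

test_that("visual areas count covered columns and trace hex outlines", {
  vals <- stats::setNames(c(1, 2, 0.5, 0, 0, 1, 3), sprintf("c%d", 1:7))
  va <- visual_area(vals)
  expect_equal(va$n_covered, 5L)
  expect_equal(visual_area(vals, eps = 10)$n_covered, 0L)

  # planted 12-column patch: count and outline match the construction
  cn <- generate_connectome(synth_config(n_cols_side = 6,
                                         neurons_per_subtype = 2,
                                         convergence = 2, divergence = 1,
                                         seed = 5))
  omm <- cn$ommatidia
  em <- structure(data.frame(column_id = cn$columns$column_id,
                             q = cn$columns$q, r = cn$columns$r,
                             azimuth_deg = omm$azimuth_deg,
                             elevation_deg = omm$elevation_deg,
                             is_equator = cn$columns$is_equator),
                  class = c("eye_map", "data.frame"))
  patch <- cn$columns$column_id[1:12]
  field <- stats::setNames(rep(1, 12), patch)
  va2 <- visual_area(field, em)
  expect_equal(va2$n_covered, 12L)
  expect_length(va2$outline, 1L)
  loop <- va2$outline[[1]]
  # the loop is closed and every covered cell centre lies inside it
  expect_equal(loop[1, ], loop[nrow(loop), ])
  inside <- avpconnect:::point_in_polygon(
    em$azimuth_deg[1:12], em$elevation_deg[1:12],
    loop[-1, 1], loop[-1, 2])
  expect_true(all(inside))
  # no uncovered cell centre lies inside
  out_idx <- 13:nrow(em)
  outside <- avpconnect:::point_in_polygon(
    em$azimuth_deg[out_idx], em$elevation_deg[out_idx],
    loop[-1, 1], loop[-1, 2])
  expect_false(any(outside))
  # unmapped covered columns are reported separately
  va3 <- visual_area(stats::setNames(1, "ghost"), em)
  expect_equal(va3$unmapped, "ghost")
})

test_that("population outlines union individual covered sets", {
  cn <- generate_connectome(synth_config(n_cols_side = 6,
                                         neurons_per_subtype = 2,
                                         convergence = 2, divergence = 1,
                                         seed = 5))
  omm <- cn$ommatidia
  em <- structure(data.frame(column_id = cn$columns$column_id,
                             q = cn$columns$q, r = cn$columns$r,
                             azimuth_deg = omm$azimuth_deg,
                             elevation_deg = omm$elevation_deg,
                             is_equator = cn$columns$is_equator),
                  class = c("eye_map", "data.frame"))
  f1 <- structure(list(er_id = "e1",
                       direct = stats::setNames(1, em$column_id[1]),
                       indirect = numeric()), class = "column_field")
  f2 <- structure(list(er_id = "e2",
                       direct = stats::setNames(1, em$column_id[10]),
                       indirect = numeric()), class = "column_field")
  pop <- population_outline(list(f1, f2), em)
  expect_equal(pop$n_covered, 2L)
})

test_that("dF/F normalizes by the lowest-decile baseline", {
  expect_equal(dff_from_raw(rep(10, 50)), rep(0, 50))
  # lowest decile mean 5; a frame at 10 maps to 1.0
  series <- c(rep(5, 10), rep(8, 89), 10)
  dff <- dff_from_raw(series)
  expect_equal(dff[length(dff)], 1.0)
  expect_error(dff_from_raw(rep(3, 20), rep(3, 20)), "F0 <= 0")
  expect_error(dff_from_raw(numeric()), "empty")
})

test_that("stimulus responses subtract baseline and test responsiveness", {
  frames <- 40
  stim <- 21:30; base <- 11:20
  flat <- matrix(0.3, 10, frames)
  r0 <- stimulus_response(flat, stim, base)
  expect_equal(r0$mean_response, 0)
  expect_false(r0$responsive)
  # a +1 step exactly during stimulation across 10 trials
  step <- flat
  step[, stim] <- step[, stim] + 1
  r1 <- stimulus_response(step, stim, base)
  expect_equal(r1$mean_response, 1.0)
  expect_true(r1$responsive)
  # planted effect 0.5 with noise sd 0.1
  set.seed(43)
  noisy <- matrix(rnorm(10 * frames, 0, 0.1), 10)
  noisy[, stim] <- noisy[, stim] + 0.5
  r2 <- stimulus_response(noisy, stim, base)
  expect_lt(abs(r2$mean_response - 0.5), 0.1)
  expect_true(r2$responsive)
  # responses failing the empty-control comparison are not responsive
  r3 <- stimulus_response(step, stim, base, empty_response = 2)
  expect_false(r3$responsive)
  expect_error(stimulus_response(step, 39:45, base), "window")
  expect_error(stimulus_response(flat[0, ], stim, base), "zero trials")
})

test_that("the 38-dot layout tiles without overlap", {
  lay <- stimulus_layout()
  expect_equal(nrow(lay), 38L)
  # non-overlap: centres of 18-degree tiles are at least 18 degrees
  # apart in azimuth or elevation
  d <- as.matrix(stats::dist(lay[, c("azimuth_deg", "elevation_deg")],
                             method = "maximum"))
  diag(d) <- Inf
  expect_gte(min(d), 18)
})

test_that("response grids reproduce the planted profile", {
  ell <- ellipse_fit(c(0, 0), a = 30, b = 30, theta_deg = 0)
  g0 <- generate_response_grid(ell, n_trials = 3, noise_sd = 0, seed = 2)
  prof <- attr(g0, "planted_profile")
  expect_equal(g0$response,
               rep(prof, each = 3), ignore_attr = TRUE)
  # determinism under a fixed seed
  g1 <- generate_response_grid(ell, n_trials = 10, noise_sd = 0.2, seed = 4)
  g2 <- generate_response_grid(ell, n_trials = 10, noise_sd = 0.2, seed = 4)
  expect_identical(g1, g2)
  expect_error(generate_response_grid(ell, n_trials = 0), "n_trials")
  expect_error(generate_response_grid(ell, noise_sd = -1), "noise sd")
})

test_that("receptive-field ellipses recover planted contours", {
  # circular planted profile, noiseless: ratio close to 1
  circ <- ellipse_fit(c(0, 0), a = 25, b = 25, theta_deg = 0)
  g <- response_grid_summary(
    generate_response_grid(circ, n_trials = 1, noise_sd = 0, seed = 1))
  f <- rf_ellipse(g, level = 0.2)
  expect_gte(f$ellipse$ratio, 1)
  expect_lt(f$ellipse$ratio, 1.1)
  # circular profile with noise at 10 trials stays within 10 %
  g10 <- response_grid_summary(
    generate_response_grid(circ, n_trials = 10, noise_sd = 0.05, seed = 3))
  f10 <- rf_ellipse(g10, level = 0.2)
  expect_lt(abs(f10$ellipse$ratio - 1), 0.1)
  # planted ratio 2.5 at 90 degrees (horizontal major axis), noiseless
  ell <- ellipse_fit(c(0, 0), a = 35, b = 14, theta_deg = 90)
  ge <- response_grid_summary(
    generate_response_grid(ell, n_trials = 1, noise_sd = 0, seed = 1))
  fe <- rf_ellipse(ge, level = 0.2)
  expect_lt(abs(fe$ellipse$ratio - 2.5) / 2.5, 0.1)
  d <- abs(fe$ellipse$theta_deg - 90)
  expect_lt(min(d, 180 - d), 5)
  # flat responses have no contour
  flat <- data.frame(azimuth_deg = g$azimuth_deg,
                     elevation_deg = g$elevation_deg,
                     mean_response = 0)
  expect_error(rf_ellipse(flat), "responsive")
})

test_that("rf fits recover randomly planted ellipses end to end", {
  set.seed(44)
  for (i in 1:20) {
    a <- runif(1, 20, 32); b <- runif(1, 12, 0.9 * a)
    th <- runif(1, 0, 180)
    ell <- ellipse_fit(c(runif(1, -10, 10), runif(1, -8, 8)), a, b, th)
    g <- response_grid_summary(
      generate_response_grid(ell, n_trials = 1, noise_sd = 0, seed = i))
    f <- rf_ellipse(g, level = 0.2)
    expect_lt(abs(f$ellipse$ratio - ell$ratio) / ell$ratio, 0.25)
    if (ell$ratio > 1.3) {
      d <- abs(f$ellipse$theta_deg - th)
      expect_lt(min(d, 180 - d), 15)
    }
  }
})
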