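# Shared fixtures. The reference synthetic connectome (default study
# conditions) is generated once per test run and cached; smaller bespoke
# fixtures are built inline by the tests that need them.

.fixture_env <- new.env(parent = emptyenv())

default_connectome <- function() {
  if (is.null(.fixture_env$cn))
    .fixture_env$cn <- generate_connectome(synth_config(seed = 20240101L))
  .fixture_env$cn
}

default_analysis <- function() {
  if (is.null(.fixture_env$res))
    .fixture_env$res <- analyze_connectome(default_connectome())
  .fixture_env$res
}

# small synapse table builder
syn_table <- function(pre, post, x = 0, y = 0, z = 0, cleft = 100) {
  n <- max(length(pre), length(post))
  data.frame(pre_id = rep_len(as.character(pre), n),
             post_id = rep_len(as.character(post), n),
             x_nm = rep_len(x, n), y_nm = rep_len(y, n),
             z_nm = rep_len(z, n),
             cleft_score = rep_len(cleft, n),
             stringsAsFactors = FALSE)
}

# unit-box hull and a simple tetrahedron
unit_box_hull <- function(name = "BOX") {
  region_hull(name, as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))))
}

tetra_hull <- function(name = "TET") {
  region_hull(name, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
}

# independent brute-force membership oracle: for one point, enumerate
# every vertex triplet, keep triplets whose plane has all vertices on
# one side (hull facets), and test the point against each such
# half-space. Written without reference to the package internals.
oracle_in_hull <- function(p, V, tol = 1e-9) {
  n <- nrow(V)
  scale <- max(apply(V, 2, function(x) diff(range(x))), 1)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- V[i, ]; b <- V[j, ]; c <- V[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale^2) next
    nrm <- nrm / nn
    d <- drop(V %*% nrm) - sum(nrm * a)
    side_p <- sum(nrm * p) - sum(nrm * a)
    if (all(d <= tol * scale) && side_p > tol * scale) return(FALSE)
    if (all(d >= -tol * scale) && side_p < -tol * scale) return(FALSE)
  }
  TRUE
}

# column table for a plain vertical-axis lattice (axes all +z)
toy_columns <- function(centres) {
  data.frame(column_id = sprintf("c%02d", seq_len(nrow(centres))),
             q = seq_len(nrow(centres)), r = 0L,
             anchor_x = centres[, 1], anchor_y = centres[, 2],
             anchor_z = 0,
             axis_x = 0, axis_y = 0, axis_z = 1,
             depth_lo = 0, depth_hi = 1,
             stringsAsFactors = FALSE)
}

# weight_matrix builder for hand-made fixtures
toy_weight_matrix <- function(values, region = "X", counts = NULL,
                              denominators = NULL) {
  avpconnect:::new_weight_matrix(
    region = region,
    pre_ids = rownames(values), post_ids = colnames(values),
    values = values, counts = counts, denominators = denominators)
}

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random three-layer pathway fixture for back-tracing oracles
make_backtrace_fixture <- function(seed, n_metu = 8, n_tutu = 2,
                                   n_tubu = 4, n_col = 6) {
  set.seed(seed)
  metu <- sprintf("m%d", 1:n_metu)
  tutu <- sprintf("t%d", 1:n_tutu)
  tubu <- sprintf("b%d", 1:n_tubu)
  cols <- sprintf("c%d", 1:n_col)
  rmat <- function(pre, post) {
    v <- matrix(runif(length(pre) * length(post)), length(pre),
                dimnames = list(pre, post))
    sweep(v, 2, colSums(v), "/")
  }
  occm <- rmat(cols, metu)  # column x metu, columns sum to 1
  occ <- lapply(metu, function(m)
    structure(list(metu_id = m,
                   fractions = stats::setNames(occm[, m], cols)),
              class = "occupancy"))
  names(occ) <- metu
  list(metu = metu, tutu = tutu, tubu = tubu, cols = cols,
       w_mb = toy_weight_matrix(rmat(metu, tubu)),
       w_be = toy_weight_matrix(rmat(tubu, "er")),
       w_mt = toy_weight_matrix(rmat(metu, tutu)),
       w_tb = toy_weight_matrix(rmat(tutu, tubu)),
       occ = occ)
}
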