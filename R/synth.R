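# Synthetic AVP connectome with planted ground truth. The generator
# emulates the statistical structure the pipeline must recover: a
# hexagonal lattice of medulla columns with one columnar anchor neuron
# each, ten MeTu-like subtype channels with Dirichlet input fingerprints
# and 2-D Gaussian dendritic spans, retinotopic MeTu->TuBu convergence
# (anterior-posterior medulla position onto dorsal-ventral AOTU
# position), TuBu->ER divergence defining planted receptive fields,
# bilateral TuTu neurons for the indirect pathway, and noise contacts
# (sub-threshold cleft scores, autapses, background) for the filters to
# remove.

SYNTH_INPUT_TYPES <- c(
  "Dm2", "Sm16", "Sm15", "Sm07", "Sm17", "Sm23", "Mi15", "R7", "R7DRA",
  "DmDRA1", "MeMeDRA", "Sm01", "Sm02", "Sm03", "Sm05", "Sm10", "Sm12",
  "Sm14", "Sm19", "Sm21", "Sm25", "Dm4", "Dm9", "Dm12", "Mi4", "Mi9",
  "Ml1", "MeLo1")

# Planted channel structure: AOTUsu subregion, downstream TuBu types
# (with per-synapse probabilities), span shape, dendritic centre band
# (fraction of the dorsal-ventral lattice extent) and the five preferred
# medulla input types of each subtype.
synth_subtype_table <- function() {
  st <- list(
    MeTu1  = list(sub = "posterior_lateral", tubu = c(TuBu08 = 1),
                  elong = TRUE, band = c(0, 1),
                  inputs = c("Dm2", "Sm16", "Sm15", "Sm07", "Sm17")),
    MeTu2a = list(sub = "posterior_central", tubu = c(TuBu01 = 0.8, TuBu06 = 0.2),
                  elong = TRUE, band = c(0.6, 1),
                  inputs = c("R7DRA", "DmDRA1", "Sm01", "Sm02", "Sm16")),
    MeTu2b = list(sub = "posterior_central", tubu = c(TuBu06 = 0.9, TuBu01 = 0.1),
                  elong = TRUE, band = c(0.6, 1),
                  inputs = c("MeMeDRA", "R7DRA", "Mi15", "Sm03", "DmDRA1")),
    MeTu3a = list(sub = "anterior", tubu = c(TuBu07 = 1),
                  elong = FALSE, band = c(0.6, 1),
                  inputs = c("DmDRA1", "MeMeDRA", "Sm05", "Sm17", "Sm23")),
    MeTu3b = list(sub = "anterior", tubu = c(TuBu07 = 1),
                  elong = FALSE, band = c(0.5, 1),
                  inputs = c("Mi15", "R7", "Sm10", "Sm17", "Sm23")),
    MeTu3c = list(sub = "anterior", tubu = c(TuBu09 = 0.5, TuBu10 = 0.5),
                  elong = FALSE, band = c(0, 1),
                  inputs = c("Sm12", "Mi15", "R7", "Sm23", "Sm17")),
    MeTu4a = list(sub = "medial", tubu = c(TuBu03 = 0.7, TuBu04 = 0.3),
                  elong = FALSE, band = c(0.5, 1),
                  inputs = c("Sm14", "Sm19", "Sm21", "Dm4", "Sm25")),
    MeTu4b = list(sub = "medial", tubu = c(TuBu02 = 1),
                  elong = FALSE, band = c(0.4, 0.6),
                  inputs = c("Dm9", "Dm12", "Mi4", "Sm14", "Sm19")),
    MeTu4c = list(sub = "medial", tubu = c(TuBu05 = 1),
                  elong = FALSE, band = c(0.5, 1),
                  inputs = c("Mi9", "Ml1", "MeLo1", "Sm21", "Sm25")),
    MeTu4d = list(sub = "medial", tubu = c(TuBu05 = 0.6, TuBu02 = 0.4),
                  elong = FALSE, band = c(0, 0.5),
                  inputs = c("Dm4", "Sm25", "Sm21", "Mi9", "Ml1")))
  st
}

#' Synthetic connectome configuration
#'
#' Defaults define the reference study conditions used throughout the
#' test suite: a 15-column hex lattice side (225 medulla columns, the
#' order of magnitude of a fly medulla patch at desk scale), 10 planted
#' MeTu subtypes of 50 neurons each (about the 10^2 scale of the real
#' MeTu population), 80 dendritic and 30 axonal synapses per neuron,
#' 10-fold MeTu->TuBu convergence and 2-fold TuBu->ER divergence, a 5 %
#' admixture of sub-threshold (cleft score < 50) contacts, and a lattice
#' pitch of 5,000 nm approximating medulla column spacing.
#'
#' @param n_cols_side columns per lattice side (lattice is
#'   `n_cols_side` x `n_cols_side` in axial coordinates).
#' @param neurons_per_subtype MeTu-like neurons per planted subtype.
#' @param synapses_per_neuron dendritic (medulla) synapses per MeTu.
#' @param axon_synapses_per_neuron axonal (AOTUsu) synapses per MeTu.
#' @param span_ratio planted semi-major / semi-minor ratio of the
#'   elongated (vertical) channels.
#' @param span_angle_deg mean span angle from the dorsal-ventral axis.
#' @param span_angle_sd_deg angular jitter of planted spans.
#' @param span_sigma_nm semi-minor sigma of the dendritic Gaussian.
#' @param convergence MeTu neurons converging per TuBu.
#' @param divergence adjacent TuBu neurons feeding each ER.
#' @param position_noise_sd_nm positional noise added to wiring-derived
#'   synapse positions.
#' @param cleft_mean,cleft_sd cleft-score distribution of genuine
#'   contacts (truncated at the filter threshold).
#' @param low_cleft_fraction fraction of extra sub-threshold contacts.
#' @param n_background contacts onto the background sentinel id "0".
#' @param n_autapses injected self-contacts.
#' @param pitch_nm hex lattice pitch.
#' @param depth_nm distal-proximal column depth.
#' @param mi1_sites synapse sites per columnar anchor neuron.
#' @param fingerprint_concentration Dirichlet concentration of subtype
#'   input fingerprints (larger = better-separated subtypes).
#' @param eye_offset integer axial offset (dq, dr) of the ommatidia grid
#'   relative to the column grid.
#' @param seed integer seed; identical seeds give identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_cols_side = 15L,
                         neurons_per_subtype = 50L,
                         synapses_per_neuron = 80L,
                         axon_synapses_per_neuron = 30L,
                         span_ratio = 2.0,
                         span_angle_deg = 0,
                         span_angle_sd_deg = 5,
                         span_sigma_nm = 4500,
                         convergence = 10L,
                         divergence = 2L,
                         position_noise_sd_nm = 150,
                         cleft_mean = 120, cleft_sd = 30,
                         low_cleft_fraction = 0.05,
                         n_background = 30L,
                         n_autapses = 10L,
                         pitch_nm = 5000,
                         depth_nm = 10000,
                         mi1_sites = 40L,
                         fingerprint_concentration = 60,
                         eye_offset = c(0L, 0L),
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_cols_side", "neurons_per_subtype", "synapses_per_neuron",
              "axon_synapses_per_neuron", "convergence", "divergence",
              "mi1_sites")
  for (f in counts)
    if (cfg[[f]] < 1) stop("synth_config: `", f, "` must be >= 1")
  if (position_noise_sd_nm < 0 || span_angle_sd_deg < 0)
    stop("synth_config: noise sd must be >= 0")
  if (low_cleft_fraction < 0 || low_cleft_fraction >= 1)
    stop("synth_config: low_cleft_fraction must be in [0, 1)")
  if (convergence > neurons_per_subtype)
    stop("synth_config: convergence factor exceeds available MeTu count")
  class(cfg) <- "synth_config"
  cfg
}

#' Read a synthetic-connectome configuration from YAML
#'
#' @param path YAML file with any subset of the [synth_config()] fields.
#' @return a `synth_config`.
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(synth_config, x[intersect(names(x), names(formals(synth_config)))])
}

# Dirichlet draw via gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Truncated-normal cleft scores, integer, >= lo.
rcleft <- function(n, mean, sd, lo = 50) {
  x <- round(stats::rnorm(n, mean, sd))
  pmax(x, lo)
}

box_hull <- function(name, xr, yr, zr, subtract = NA_character_) {
  v <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  region_hull(name, v, subtract = subtract)
}

#' Generate a synthetic AVP connectome
#'
#' Builds the full four-artifact bundle: a synapse table, a neuron
#' annotation table, region hulls (ME_R, LO_R, AOTU_R, BU_R) and a
#' ground-truth object recording every planted quantity (subtype per
#' neuron, span ellipse per MeTu, the strictly monotone retinotopic map,
#' the per-ER planted receptive-field column sets, the column lattice,
#' photoreceptor counts and the ommatidia grid).
#'
#' The generative structure, stage by stage: each column's anchor neuron
#' scatters sites along the distal-proximal (z) axis; each MeTu draws
#' its dendritic synapses from a planted 2-D Gaussian in the tangent
#' plane, with presynaptic partners drawn from its subtype's Dirichlet
#' type fingerprint; MeTu axons target the TuBu of their channel whose
#' anterior-posterior bin contains the neuron's dendritic centroid, at
#' an AOTU position given by the planted monotone map; the MeTu3c-like
#' channel instead tiles the medulla two-dimensionally (dorsal/ventral
#' TuBu types by bin); ERs pool adjacent same-type TuBu; TuTu neurons
#' collect broad MeTu input and feed TuBu, forming the indirect
#' pathway. Finally sub-threshold, autapse and background contacts are
#' injected.
#'
#' @param config a [synth_config()].
#' @return a list with `synapses`, `annotations`, `hulls`,
#'   `ground_truth` and `columns` (the generated column lattice with
#'   photoreceptor counts).
#' @export
generate_connectome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cols_side
  pitch <- config$pitch_nm
  depth <- config$depth_nm
  st <- synth_subtype_table()
  subtypes <- names(st)

  ## --- column lattice ------------------------------------------------
  # rectangular hex patch (offset rows), so anterior-posterior bins are
  # vertical stripes at every elevation; in axial coordinates the patch
  # is the parallelogram q = i - floor(j/2), r = j
  lattice <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  lattice$q <- lattice$i - floor(lattice$j / 2)
  lattice$r <- lattice$j
  lattice$column_id <- sprintf("C_%+03d_%02d", lattice$q, lattice$r)
  lattice$x <- pitch * (lattice$q + lattice$r / 2)
  lattice$y <- pitch * sqrt(3) / 2 * lattice$r
  eq_row <- floor(n / 2)
  lattice$is_equator <- lattice$r == eq_row
  lattice$pr_count <- ifelse(lattice$is_equator,
                             7L + (lattice$q %% 2L), 6L)
  width <- max(lattice$x) - min(lattice$x)
  height <- max(lattice$y)

  syn_parts <- list()
  budget <- c()

  ## --- columnar anchor neurons (Mi1-like) -----------------------------
  nc <- nrow(lattice)
  ns <- config$mi1_sites
  mi1_ids <- sprintf("Mi1_%s", lattice$column_id)
  l1_ids <- sprintf("L1_%s", lattice$column_id)
  zz <- stats::runif(nc * ns, 0, depth)
  syn_parts$mi1 <- data.frame(
    pre_id = rep(l1_ids, each = ns),
    post_id = rep(mi1_ids, each = ns),
    x_nm = rep(lattice$x, each = ns) + stats::rnorm(nc * ns, 0, 300),
    y_nm = rep(lattice$y, each = ns) + stats::rnorm(nc * ns, 0, 300),
    z_nm = zz,
    cleft_score = rcleft(nc * ns, config$cleft_mean, config$cleft_sd),
    stringsAsFactors = FALSE)
  budget["mi1"] <- nc * ns

  ## --- input-neuron pools ---------------------------------------------
  pool_size <- 6L
  input_pool <- lapply(SYNTH_INPUT_TYPES, function(tp)
    sprintf("%s_%d", tp, seq_len(pool_size)))
  names(input_pool) <- SYNTH_INPUT_TYPES

  ## --- planted fingerprints -------------------------------------------
  k <- length(SYNTH_INPUT_TYPES)
  fingerprints <- matrix(0, length(subtypes), k,
                         dimnames = list(subtypes, SYNTH_INPUT_TYPES))
  for (s in subtypes) {
    alpha <- rep(0.05, k)
    names(alpha) <- SYNTH_INPUT_TYPES
    pref <- st[[s]]$inputs
    alpha[pref] <- config$fingerprint_concentration *
      c(0.35, 0.25, 0.18, 0.12, 0.10)
    fingerprints[s, ] <- rdirichlet1(alpha)
  }
  # MeTu3a-like channel carries (almost) no Mi15 input by construction
  fingerprints["MeTu3a", "Mi15"] <- 0
  fingerprints["MeTu3a", ] <- fingerprints["MeTu3a", ] /
    sum(fingerprints["MeTu3a", ])

  ## --- MeTu neurons: centres, spans, dendritic synapses ----------------
  npm <- config$neurons_per_subtype
  metu <- do.call(rbind, lapply(subtypes, function(s) {
    band <- st[[s]]$band
    data.frame(
      neuron_id = sprintf("%s_n%03d", s, seq_len(npm)),
      subtype = s,
      cx = stats::runif(npm, pitch, width - pitch),
      cy = stats::runif(npm, band[1] * height + 0.02 * height,
                        band[2] * height - 0.02 * height),
      stringsAsFactors = FALSE)
  }))
  elong <- vapply(metu$subtype, function(s) st[[s]]$elong, logical(1))
  metu$sigma_b <- config$span_sigma_nm
  metu$sigma_a <- ifelse(elong, config$span_ratio, 1.05) * metu$sigma_b
  metu$theta <- ifelse(
    elong,
    (config$span_angle_deg +
       stats::rnorm(nrow(metu), 0, config$span_angle_sd_deg)) %% 180,
    stats::runif(nrow(metu), 0, 180))

  nd <- config$synapses_per_neuron
  nm <- nrow(metu)
  # planted span sample: major axis at theta from the dorsal-ventral (y)
  # axis, measured towards +x
  th <- rep(metu$theta, each = nd) * pi / 180
  u <- stats::rnorm(nm * nd, 0, rep(metu$sigma_a, each = nd))
  v <- stats::rnorm(nm * nd, 0, rep(metu$sigma_b, each = nd))
  dx <- u * sin(th) + v * cos(th)
  dy <- u * cos(th) - v * sin(th)
  den_x <- rep(metu$cx, each = nd) + dx
  den_y <- rep(metu$cy, each = nd) + dy
  # presynaptic partner types from the subtype fingerprint
  den_type <- unlist(lapply(seq_len(nm), function(i) {
    p <- fingerprints[metu$subtype[i], ]
    SYNTH_INPUT_TYPES[sample.int(k, nd, replace = TRUE, prob = p)]
  }))
  den_pre <- vapply(den_type, function(tp)
    input_pool[[tp]][sample.int(pool_size, 1L)], character(1))
  m7_lo <- 0.501 * depth; m7_hi <- 0.631 * depth
  syn_parts$dendrite <- data.frame(
    pre_id = unname(den_pre),
    post_id = rep(metu$neuron_id, each = nd),
    x_nm = den_x, y_nm = den_y,
    z_nm = stats::runif(nm * nd, m7_lo, m7_hi),
    cleft_score = rcleft(nm * nd, config$cleft_mean, config$cleft_sd),
    stringsAsFactors = FALSE)
  budget["dendrite"] <- nm * nd

  # planted home column of each dendritic synapse (lattice arithmetic,
  # independent of the geometry module)
  home_r <- pmin(pmax(round(den_y / (pitch * sqrt(3) / 2)), 0), n - 1)
  home_i <- pmin(pmax(round(den_x / pitch - (home_r %% 2) / 2), 0), n - 1)
  home_q <- home_i - floor(home_r / 2)
  home_col <- sprintf("C_%+03d_%02d", home_q, home_r)

  ## --- TuBu neurons and the retinotopic map ----------------------------
  n_tubu <- max(1L, round(npm / config$convergence))
  # the 2-D tiling channel splits its population over two elevation
  # halves, so its TuBu types get proportionally fewer (wider) bins to
  # keep the per-TuBu convergence comparable
  n_tubu_split <- max(1L, ceiling(npm / (2 * config$convergence)))
  tubu_types <- sort(unique(unlist(lapply(st, function(x) names(x$tubu)))))
  bins_of_type <- function(tp)
    as.integer(if (tp %in% c("TuBu09", "TuBu10")) n_tubu_split else n_tubu)
  tubu <- do.call(rbind, lapply(tubu_types, function(tp) {
    nb <- bins_of_type(tp)
    data.frame(neuron_id = sprintf("%s_n%02d", tp, seq_len(nb)),
               tubu_type = tp, ap_bin = seq_len(nb), n_bins = nb,
               stringsAsFactors = FALSE)
  }))
  # strictly monotone planted map: medulla AP position -> AOTU DV position
  aotu <- list(x = c(150000, 170000), y = c(0, 20000), z = c(0, 8000))
  map_intercept <- 2000; map_slope <- 16000 / width
  retino_map <- function(ap) map_intercept + map_slope * ap
  bin_of <- function(ap, nb) pmin(pmax(ceiling(ap / width * nb), 1L), nb)
  tubu$dv_pos <- retino_map((tubu$ap_bin - 0.5) * width / tubu$n_bins)

  ## --- MeTu -> TuBu axonal synapses ------------------------------------
  na <- config$axon_synapses_per_neuron
  ax_rows <- vector("list", nm)
  for (i in seq_len(nm)) {
    s <- metu$subtype[i]
    probs <- st[[s]]$tubu
    types <- names(probs)
    if (s == "MeTu3c") {
      # 2-D tiling channel: the dorsal/ventral half of the dendritic
      # centre selects the TuBu type, so each target pools a compact
      # 2-D tile (anterior-posterior bin x elevation half)
      tp <- if (metu$cy[i] >= height / 2) "TuBu09" else "TuBu10"
      draw <- rep(tp, na)
    } else {
      draw <- types[sample.int(length(types), na, replace = TRUE,
                               prob = probs)]
    }
    post <- sprintf("%s_n%02d", draw,
                    bin_of(metu$cx[i],
                           vapply(draw, bins_of_type, integer(1))))
    ax_rows[[i]] <- data.frame(
      pre_id = metu$neuron_id[i], post_id = post,
      x_nm = stats::runif(na, aotu$x[1] + 2000, aotu$x[2] - 2000),
      y_nm = retino_map(metu$cx[i]) +
        stats::rnorm(na, 0, config$position_noise_sd_nm),
      z_nm = stats::runif(na, aotu$z[1] + 1000, aotu$z[2] - 1000),
      cleft_score = rcleft(na, config$cleft_mean, config$cleft_sd),
      stringsAsFactors = FALSE)
  }
  syn_parts$axon <- do.call(rbind, ax_rows)
  budget["axon"] <- nm * na

  ## --- lobula boutons of the MeTu4-like channels -----------------------
  lo <- list(x = c(-120000, -90000), y = c(0, 15000), z = c(0, 8000))
  lob_n <- ifelse(metu$subtype %in% c("MeTu4a", "MeTu4b", "MeTu4c"), 30L,
                  ifelse(metu$subtype == "MeTu4d", 5L, 0L))
  lob_idx <- rep(seq_len(nm), lob_n)
  if (length(lob_idx)) {
    syn_parts$lobula <- data.frame(
      pre_id = metu$neuron_id[lob_idx],
      post_id = sprintf("Lo_sink_%d", 1L + (seq_along(lob_idx) %% 8L)),
      x_nm = stats::runif(length(lob_idx), lo$x[1] + 1000, lo$x[2] - 1000),
      y_nm = stats::runif(length(lob_idx), lo$y[1] + 1000, lo$y[2] - 1000),
      z_nm = stats::runif(length(lob_idx), lo$z[1] + 1000, lo$z[2] - 1000),
      cleft_score = rcleft(length(lob_idx), config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE)
    budget["lobula"] <- length(lob_idx)
  }

  ## --- bilateral neurons: TuTu and AOTU046 -----------------------------
  tutu_ids <- c("TuTuB_a_n01", "TuTuB_b_n01")
  tutu_in_sub <- list(TuTuB_a_n01 = c("MeTu2a", "MeTu2b", "MeTu3a",
                                      "MeTu3b", "MeTu3c"),
                      TuTuB_b_n01 = c("MeTu2a", "MeTu2b"))
  tutu_out_tp <- list(TuTuB_a_n01 = c("TuBu01", "TuBu06", "TuBu07",
                                      "TuBu09", "TuBu10"),
                      TuTuB_b_n01 = c("TuBu01", "TuBu06"))
  tt_rows <- list()
  for (t_id in tutu_ids) {
    donors <- metu$neuron_id[metu$subtype %in% tutu_in_sub[[t_id]]]
    n_in <- 5L
    tt_rows[[paste0(t_id, "_in")]] <- data.frame(
      pre_id = rep(donors, each = n_in), post_id = t_id,
      x_nm = stats::runif(length(donors) * n_in, aotu$x[1] + 2000,
                          aotu$x[2] - 2000),
      y_nm = stats::runif(length(donors) * n_in, aotu$y[1] + 1000,
                          aotu$y[2] - 1000),
      z_nm = stats::runif(length(donors) * n_in, aotu$z[1] + 1000,
                          aotu$z[2] - 1000),
      cleft_score = rcleft(length(donors) * n_in, config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE)
    targets <- tubu$neuron_id[tubu$tubu_type %in% tutu_out_tp[[t_id]]]
    n_out <- 10L
    tt_rows[[paste0(t_id, "_out")]] <- data.frame(
      pre_id = t_id, post_id = rep(targets, each = n_out),
      x_nm = stats::runif(length(targets) * n_out, aotu$x[1] + 2000,
                          aotu$x[2] - 2000),
      y_nm = rep(tubu$dv_pos[match(targets, tubu$neuron_id)], each = n_out) +
        stats::rnorm(length(targets) * n_out, 0,
                     config$position_noise_sd_nm),
      z_nm = stats::runif(length(targets) * n_out, aotu$z[1] + 1000,
                          aotu$z[2] - 1000),
      cleft_score = rcleft(length(targets) * n_out, config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE)
  }
  syn_parts$tutu <- do.call(rbind, tt_rows)
  budget["tutu"] <- nrow(syn_parts$tutu)

  a46 <- "AOTU046_n01"
  donors <- metu$neuron_id[metu$subtype %in% c("MeTu4b", "MeTu4c")]
  targets <- tubu$neuron_id[tubu$tubu_type %in% c("TuBu02", "TuBu05")]
  n46 <- length(donors) * 3L + length(targets) * 5L
  syn_parts$aotu046 <- data.frame(
    pre_id = c(rep(donors, each = 3L), rep(a46, length(targets) * 5L)),
    post_id = c(rep(a46, length(donors) * 3L), rep(targets, each = 5L)),
    x_nm = stats::runif(n46, aotu$x[1] + 2000, aotu$x[2] - 2000),
    y_nm = stats::runif(n46, aotu$y[1] + 1000, aotu$y[2] - 1000),
    z_nm = stats::runif(n46, aotu$z[1] + 1000, aotu$z[2] - 1000),
    cleft_score = rcleft(n46, config$cleft_mean, config$cleft_sd),
    stringsAsFactors = FALSE)
  budget["aotu046"] <- n46

  ## --- TuBu -> ER divergence -------------------------------------------
  bu <- list(x = c(190000, 202000), y = c(0, 12000), z = c(0, 6000))
  er_of_tubu <- c(TuBu08 = "ER4d", TuBu01 = "ER4m", TuBu06 = "ER5",
                  TuBu07 = "ER3w_ab", TuBu09 = "ER2_ad", TuBu10 = "ER2_c",
                  TuBu03 = "ER3a_ad", TuBu04 = "ER3a_ad", TuBu02 = "ER3m",
                  TuBu05 = "ER3d_a")
  # each TuBu diverges onto `divergence` ER neurons of its channel's ER
  # type; every ER inherits the (retinotopic) field of exactly one TuBu
  div <- config$divergence
  er_rows <- list(); er_wiring <- list()
  for (tp in tubu_types) {
    er_type <- er_of_tubu[[tp]]
    for (j in seq_len(bins_of_type(tp))) {
      for (d in seq_len(div)) {
        er_id <- sprintf("%s_n%02d", er_type, (j - 1L) * div + d)
        pres <- sprintf("%s_n%02d", tp, j)
        er_wiring[[er_id]] <- union(er_wiring[[er_id]], pres)
      }
    }
  }
  n_be <- 20L
  for (er_id in names(er_wiring)) {
    pres <- er_wiring[[er_id]]
    er_rows[[er_id]] <- data.frame(
      pre_id = rep(pres, each = n_be), post_id = er_id,
      x_nm = stats::runif(length(pres) * n_be, bu$x[1] + 500, bu$x[2] - 500),
      y_nm = stats::runif(length(pres) * n_be, bu$y[1] + 500, bu$y[2] - 500),
      z_nm = stats::runif(length(pres) * n_be, bu$z[1] + 500, bu$z[2] - 500),
      cleft_score = rcleft(length(pres) * n_be, config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE)
  }
  syn_parts$bulb <- do.call(rbind, er_rows)
  budget["bulb"] <- nrow(syn_parts$bulb)

  ## --- assemble and inject noise --------------------------------------
  syn <- do.call(rbind, unname(syn_parts))
  rownames(syn) <- NULL
  n_real <- nrow(syn)
  n_low <- round(config$low_cleft_fraction * n_real)
  if (n_low > 0) {
    idx <- sample.int(n_real, n_low, replace = TRUE)
    low <- syn[idx, ]
    low$x_nm <- low$x_nm + stats::rnorm(n_low, 0, 100)
    low$cleft_score <- sample(0:49, n_low, replace = TRUE)
    syn <- rbind(syn, low)
  }
  if (config$n_background > 0) {
    bg_pre <- sample(metu$neuron_id, config$n_background, replace = TRUE)
    syn <- rbind(syn, data.frame(
      pre_id = bg_pre, post_id = BACKGROUND_ID,
      x_nm = stats::runif(config$n_background, 0, width),
      y_nm = stats::runif(config$n_background, 0, height),
      z_nm = stats::runif(config$n_background, 0, depth),
      cleft_score = rcleft(config$n_background, config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE))
  }
  if (config$n_autapses > 0) {
    au <- sample(metu$neuron_id, config$n_autapses, replace = TRUE)
    syn <- rbind(syn, data.frame(
      pre_id = au, post_id = au,
      x_nm = stats::runif(config$n_autapses, 0, width),
      y_nm = stats::runif(config$n_autapses, 0, height),
      z_nm = stats::runif(config$n_autapses, 0, depth),
      cleft_score = rcleft(config$n_autapses, config$cleft_mean,
                           config$cleft_sd),
      stringsAsFactors = FALSE))
  }
  rownames(syn) <- NULL
  budget["noise"] <- n_low + config$n_background + config$n_autapses

  ## --- region hulls -----------------------------------------------------
  me_pad <- 8 * pitch
  hulls <- list(
    ME_R = box_hull("ME_R", c(-me_pad, width + me_pad),
                    c(-me_pad, height + me_pad), c(-1000, depth + 1000)),
    LO_R = box_hull("LO_R", lo$x, lo$y, lo$z),
    AOTU_R = box_hull("AOTU_R", aotu$x, aotu$y, aotu$z),
    BU_R = box_hull("BU_R", bu$x, bu$y, bu$z))

  ## --- annotations -------------------------------------------------------
  ann <- rbind(
    data.frame(neuron_id = metu$neuron_id, cell_class = metu$subtype,
               hemisphere = "R", subtype = metu$subtype,
               stringsAsFactors = FALSE),
    data.frame(neuron_id = tubu$neuron_id, cell_class = tubu$tubu_type,
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = names(er_wiring),
               cell_class = sub("_n[0-9]+$", "", names(er_wiring)),
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = c(tutu_ids, a46),
               cell_class = c("TuTuB_a", "TuTuB_b", "AOTU046"),
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = mi1_ids, cell_class = "Mi1",
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = l1_ids, cell_class = "L1",
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = unlist(input_pool),
               cell_class = rep(SYNTH_INPUT_TYPES, each = pool_size),
               hemisphere = "R", subtype = NA_character_),
    data.frame(neuron_id = sprintf("Lo_sink_%d", 1:8), cell_class = "other",
               hemisphere = "R", subtype = NA_character_))

  ## --- ommatidia grid and ground truth ----------------------------------
  spacing_deg <- 5
  omm <- lattice[, c("q", "r", "is_equator")]
  omm$q <- omm$q + config$eye_offset[1]
  omm$r <- omm$r + config$eye_offset[2]
  omm$azimuth_deg <- spacing_deg * (omm$q + omm$r / 2) -
    spacing_deg * (n - 1) / 2
  omm$elevation_deg <- spacing_deg * sqrt(3) / 2 * (omm$r - eq_row)

  # per-ER planted column set: columns hosting dendritic synapses of any
  # MeTu wired (via its TuBu draw) into the ER
  metu_cols <- split(home_col, rep(metu$neuron_id, each = nd))
  tubu_of_metu <- split(syn_parts$axon$post_id, syn_parts$axon$pre_id)
  metu_by_tubu <- split(rep(names(tubu_of_metu),
                            lengths(tubu_of_metu)),
                        unlist(tubu_of_metu, use.names = FALSE))
  metu_by_tubu <- lapply(metu_by_tubu, unique)
  er_columns <- lapply(er_wiring, function(pres) {
    ms <- unique(unlist(metu_by_tubu[pres]))
    sort(unique(unlist(metu_cols[ms])))
  })

  ground_truth <- list(
    seed = config$seed,
    subtype = stats::setNames(metu$subtype, metu$neuron_id),
    spans = data.frame(neuron_id = metu$neuron_id, cx = metu$cx,
                       cy = metu$cy, sigma_a = metu$sigma_a,
                       sigma_b = metu$sigma_b, theta_deg = metu$theta,
                       stringsAsFactors = FALSE),
    fingerprints = fingerprints,
    retinotopy = list(intercept = map_intercept, slope = map_slope,
                      ap = stats::setNames(metu$cx, metu$neuron_id)),
    tubu = tubu,
    er_wiring = er_wiring,
    er_columns = er_columns,
    metu_home_columns = metu_cols,
    equator_row = eq_row,
    budget = budget,
    config = config)

  lattice_out <- lattice[, c("column_id", "q", "r", "x", "y",
                             "is_equator", "pr_count")]
  list(synapses = syn, annotations = ann, hulls = hulls,
       ground_truth = ground_truth, columns = lattice_out,
       ommatidia = omm)
}

#' Construct an ellipse
#'
#' Plain constructor for the ellipse representation used for planted
#' receptive fields and fitted spans: centroid, semi-axes and the angle
#' of the semi-major axis measured from the dorsal-ventral (vertical)
#' axis, in \[0, 180).
#'
#' @param centroid length-2 numeric.
#' @param a,b semi-major and semi-minor axis, a >= b > 0.
#' @param theta_deg angle from vertical, degrees.
#' @return an `ellipse_fit`.
#' @export
ellipse_fit <- function(centroid, a, b, theta_deg) {
  if (b <= 0 || a < b) stop("ellipse_fit: need a >= b > 0")
  theta_deg <- theta_deg %% 180
  structure(list(centroid = centroid, a = a, b = b, theta_deg = theta_deg,
                 ratio = a / b),
            class = "ellipse_fit")
}

# Gaussian-ellipse profile (amplitude 1 at the centre) at points.
ellipse_profile <- function(ellipse, az, el) {
  th <- ellipse$theta_deg * pi / 180
  dx <- az - ellipse$centroid[1]
  dy <- el - ellipse$centroid[2]
  # rotate into the ellipse frame: u along the major axis (from vertical)
  u <- dx * sin(th) + dy * cos(th)
  v <- dx * cos(th) - dy * sin(th)
  exp(-0.5 * ((u / ellipse$a)^2 + (v / ellipse$b)^2))
}

#' Generate a synthetic stimulus-response grid
#'
#' Simulates trial responses at the 38 standard stimulus positions
#' ([stimulus_layout()]): the planted mean at each position is a
#' Gaussian-ellipse profile (amplitude at the ellipse centre = `amp`,
#' semi-axes = 1-sigma extents), and each trial adds zero-mean Gaussian
#' noise.
#'
#' @param planted an `ellipse_fit` describing the planted receptive
#'   field (degrees).
#' @param n_trials trials per position (>= 1).
#' @param noise_sd response noise sd (dF/F units, >= 0).
#' @param seed integer seed.
#' @param amp peak mean response.
#' @param layout stimulus layout ([stimulus_layout()]).
#' @return a `data.frame` with stim_index, azimuth_deg, elevation_deg,
#'   trial, response; attribute `planted_profile` holds the noiseless
#'   means.
#' @export
generate_response_grid <- function(planted, n_trials = 10L, noise_sd = 0.1,
                                   seed = 1L, amp = 1,
                                   layout = stimulus_layout()) {
  if (n_trials < 1L) stop("generate_response_grid: n_trials must be >= 1")
  if (noise_sd < 0) stop("generate_response_grid: noise sd must be >= 0")
  set.seed(seed)
  prof <- amp * ellipse_profile(planted, layout$azimuth_deg,
                                layout$elevation_deg)
  np <- nrow(layout)
  out <- data.frame(
    stim_index = rep(layout$stim_index, each = n_trials),
    azimuth_deg = rep(layout$azimuth_deg, each = n_trials),
    elevation_deg = rep(layout$elevation_deg, each = n_trials),
    trial = rep(seq_len(n_trials), np),
    response = rep(prof, each = n_trials) +
      stats::rnorm(np * n_trials, 0, noise_sd))
  attr(out, "planted_profile") <- stats::setNames(prof, layout$stim_index)
  out
}

#' Summarize a response grid into per-position means
#'
#' @param grid output of [generate_response_grid()].
#' @return a `data.frame` with azimuth_deg, elevation_deg,
#'   mean_response.
#' @export
response_grid_summary <- function(grid) {
  agg <- stats::aggregate(list(mean_response = grid$response),
                          by = list(stim_index = grid$stim_index,
                                    azimuth_deg = grid$azimuth_deg,
                                    elevation_deg = grid$elevation_deg),
                          FUN = mean)
  agg[order(agg$stim_index), ]
}
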