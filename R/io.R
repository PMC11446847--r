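# File readers/writers for the plain-text interchange formats:
# synapse tables and annotations as CSV, region hulls as JSON,
# weight matrices as rectangular CSV. All geometry is carried in nm;
# voxel-to-nm scaling (if configured) is applied exactly once, at read time.

SYNAPSE_COLUMNS <- c("pre_id", "post_id", "x_nm", "y_nm", "z_nm", "cleft_score")
BACKGROUND_ID <- "0"

#' Read a synapse table
#'
#' Reads a CSV of synaptic contacts with columns
#' `pre_id,post_id,x_nm,y_nm,z_nm,cleft_score`. Identifiers are kept as
#' character strings so ids from any connectome platform fit; positions are
#' interpreted in nm unless `config$coordinate_units` is a voxel size, in
#' which case the scaling to nm happens here (and only here). Background
#' contacts (partner id `"0"`) are kept so that raw counts stay auditable;
#' they are removed later by [filter_synapses()].
#'
#' @param path path to a CSV file with a header row.
#' @param config a [pipeline_config()]; controls coordinate units.
#' @return a `data.frame` with the six synapse columns.
#' @export
read_synapse_table <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("synapse table not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(SYNAPSE_COLUMNS, names(df))
  if (length(missing))
    stop("synapse table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[SYNAPSE_COLUMNS]
  for (col in c("x_nm", "y_nm", "z_nm", "cleft_score")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      stop("synapse table: non-numeric `", col, "` at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  validate_synapse_table(df)
  if (is.numeric(config$coordinate_units)) {
    s <- config$coordinate_units
    df$x_nm <- df$x_nm * s[1]
    df$y_nm <- df$y_nm * s[2]
    df$z_nm <- df$z_nm * s[3]
  }
  df
}

validate_synapse_table <- function(df) {
  pos <- as.matrix(df[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(df)) {
    bad <- which(!is.finite(pos), arr.ind = TRUE)
    if (nrow(bad))
      stop("synapse table: non-finite position at row ", bad[1, 1])
    if (anyNA(df$cleft_score) || any(df$cleft_score < 0))
      stop("synapse table: cleft_score must be a non-negative number (row ",
           which(is.na(df$cleft_score) | df$cleft_score < 0)[1], ")")
    if (any(!nzchar(df$pre_id)) || any(!nzchar(df$post_id)))
      stop("synapse table: empty pre_id or post_id")
  }
  invisible(df)
}

#' Write a synapse table
#'
#' @param synapses a synapse `data.frame` as returned by
#'   [read_synapse_table()] or [generate_connectome()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(synapses, path) {
  validate_synapse_table(synapses[SYNAPSE_COLUMNS])
  utils::write.csv(synapses[SYNAPSE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a neuron annotation table
#'
#' Reads a CSV with columns `neuron_id,cell_class,hemisphere` (and an
#' optional `subtype` column filled in by the classification stage).
#' Duplicate neuron ids are an error; unknown cell-class labels are kept
#' verbatim with a warning so that new types pass through unharmed.
#'
#' @param path path to a CSV file with a header row.
#' @param known_classes character vector of recognized cell-class labels;
#'   defaults to the AVP vocabulary ([avp_cell_classes()]).
#' @return a `data.frame` with columns neuron_id, cell_class, hemisphere,
#'   subtype.
#' @export
read_annotations <- function(path, known_classes = avp_cell_classes()) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("neuron_id", "cell_class", "hemisphere")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  df <- df[c(need, "subtype")]
  dup <- unique(df$neuron_id[duplicated(df$neuron_id)])
  if (length(dup))
    stop("annotation table: duplicated neuron_id(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (nrow(df) && !all(df$hemisphere %in% c("L", "R")))
    stop("annotation table: hemisphere must be \"L\" or \"R\"")
  unknown <- setdiff(unique(df$cell_class), known_classes)
  if (length(unknown))
    warning("annotation table: unknown cell_class label(s) kept verbatim: ",
            paste(utils::head(unknown, 10), collapse = ", "))
  df
}

#' @rdname read_annotations
#' @param annotations an annotation `data.frame`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Controlled vocabulary of AVP cell classes
#'
#' MeTu classes/subtypes, TuBu types, visual ER types, the bilateral
#' AOTU neurons, the columnar medulla anchor Mi1 and the most common
#' medulla input types.
#'
#' @return a character vector of labels.
#' @export
avp_cell_classes <- function() {
  c("MeTu1", "MeTu2", "MeTu2a", "MeTu2b",
    "MeTu3", "MeTu3a", "MeTu3b", "MeTu3c",
    "MeTu4", "MeTu4a", "MeTu4b", "MeTu4c", "MeTu4d", "MeTu_incomplete",
    sprintf("TuBu%02d", 1:10),
    "ER2_ad", "ER2_b", "ER2_c", "ER3a_ad", "ER3d_a", "ER3d_b", "ER3d_c",
    "ER3d_d", "ER3m", "ER3p_ab", "ER3w_ab", "ER4d", "ER4m", "ER5", "ExR1",
    "TuTuB_a", "TuTuB_b", "AOTU046", "EPG",
    "Mi1", "Dm2", "Sm16", "Sm15", "Sm07", "Sm17", "Sm23", "Mi15",
    "R7", "R7DRA", "DmDRA1", "MeMeDRA", "L1",
    "other")
}

#' Write / read a weight matrix as rectangular CSV
#'
#' The text layout has presynaptic ids as rows and postsynaptic ids as
#' columns; values survive a round trip to at least 12 decimal digits.
#' NaN entries are refused (a weight is always defined or the post is
#' dropped upstream).
#'
#' @param matrix a [weight_matrix] object.
#' @param path file path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns a `weight_matrix` (values only; counts and denominators are
#'   not serialized).
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "weight_matrix"))
  v <- matrix$values
  if (length(v) && any(!is.finite(v)))
    stop("write_matrix: matrix contains non-finite values")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("pre_id", matrix$post_ids), collapse = ","), con)
  if (length(matrix$pre_ids))
    for (i in seq_along(matrix$pre_ids)) {
      row <- if (length(matrix$post_ids))
        formatC(v[i, ], format = "g", digits = 17) else character()
      writeLines(paste(c(matrix$pre_ids[i], row), collapse = ","), con)
    }
  invisible(path)
}

#' @rdname write_matrix
#' @param region,level metadata attached to the read-back matrix.
#' @export
read_matrix <- function(path, region = NA_character_, level = "individual") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  pre_ids <- df[[1]]
  post_ids <- setdiff(names(df), names(df)[1])
  vals <- matrix(0, nrow = length(pre_ids), ncol = length(post_ids),
                 dimnames = list(pre_ids, post_ids))
  for (j in seq_along(post_ids)) vals[, j] <- as.numeric(df[[j + 1L]])
  new_weight_matrix(region = region, pre_ids = pre_ids, post_ids = post_ids,
                    values = vals, counts = NULL, denominators = NULL,
                    level = level)
}

#' Read / write region hulls as JSON
#'
#' A region hull is a named convex vertex cloud in nm (a neuropil such as
#' ME_R or AOTU_R); an optional `subtract` field names a second hull whose
#' interior is excluded from membership (used when one neuropil's vertex
#' cloud overhangs a neighbour).
#'
#' @param path JSON file path.
#' @return `read_region_hulls()` returns a named list of [region_hull]
#'   objects.
#' @export
read_region_hulls <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  hulls <- lapply(x, function(h) {
    v <- matrix(unlist(h$vertices), ncol = 3, byrow = TRUE)
    sub <- h$subtract
    region_hull(name = h$name, vertices = v,
                subtract = if (is.character(sub) && length(sub) == 1L)
                  sub else NA_character_)
  })
  names(hulls) <- vapply(hulls, function(h) h$name, character(1))
  hulls
}

#' @rdname read_region_hulls
#' @param hulls a named list of [region_hull] objects.
#' @export
write_region_hulls <- function(hulls, path) {
  out <- lapply(hulls, function(h) {
    e <- list(name = h$name,
              vertices = lapply(seq_len(nrow(h$vertices)),
                                function(i) unname(h$vertices[i, ])))
    if (!is.na(h$subtract)) e$subtract <- h$subtract
    e
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
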