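#' Construct atlas metadata
#'
#' An atlas describes the parcellation every map in the pipeline lives on:
#' parcel labels, hemisphere membership, spherical centroid directions (used
#' by the spin permutation machinery) and, optionally, von Economo-Koskinas
#' cytoarchitectonic class labels.
#'
#' @param parcel_id character vector of unique parcel labels. Labels are
#'   normalized to canonical FreeSurfer-style `lh_`/`rh_` prefixes; the
#'   `L_`/`R_` dialect is accepted.
#' @param hemisphere character vector, `"L"` or `"R"` per parcel.
#' @param centroid numeric matrix (n x 3) of unit-norm centroid directions on
#'   the sphere.
#' @param cyto_class optional character vector of cytoarchitectonic classes
#'   (one of agranular, frontal, parietal, polar, granular), or `NA`.
#'
#' @return A data.frame of class `coalt_atlas` with columns `parcel_id`,
#'   `hemisphere`, `cx`, `cy`, `cz`, `cyto_class`.
#' @export
coalt_atlas <- function(parcel_id, hemisphere, centroid, cyto_class = NULL) {
  parcel_id <- normalize_parcel_id(parcel_id)
  n <- length(parcel_id)
  if (anyDuplicated(parcel_id))
    stop("duplicated parcel_id: ",
         paste(unique(parcel_id[duplicated(parcel_id)]), collapse = ", "))
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R' for every parcel")
  if (sum(hemisphere == "L") != sum(hemisphere == "R"))
    stop("parcel count must be equal per hemisphere")
  centroid <- as.matrix(centroid)
  if (!is.numeric(centroid) || nrow(centroid) != n || ncol(centroid) != 3)
    stop("centroid must be an n x 3 numeric matrix")
  norms <- sqrt(rowSums(centroid^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("centroids must be unit-norm (tolerance 1e-9)")
  if (is.null(cyto_class)) cyto_class <- rep(NA_character_, n)
  cyto_class <- as.character(cyto_class)
  bad <- !is.na(cyto_class) & !cyto_class %in% CYTO_CLASSES
  if (any(bad))
    stop("unknown cyto_class: ", paste(unique(cyto_class[bad]), collapse = ", "))
  out <- data.frame(parcel_id = parcel_id, hemisphere = hemisphere,
                    cx = centroid[, 1], cy = centroid[, 2], cz = centroid[, 3],
                    cyto_class = cyto_class, stringsAsFactors = FALSE)
  class(out) <- c("coalt_atlas", "data.frame")
  out
}

#' @export
print.coalt_atlas <- function(x, ...) {
  cat("<coalt_atlas> ", nrow(x), " parcels (",
      sum(x$hemisphere == "L"), " per hemisphere)\n", sep = "")
  invisible(x)
}

CYTO_CLASSES <- c("agranular", "frontal", "parietal", "polar", "granular")

#' Normalize parcel labels to canonical FreeSurfer-style names
#'
#' ENIGMA and HCP releases use different label dialects for the same
#' Desikan-Killiany parcels; `"L_bankssts"` and `"lh_bankssts"` both map to
#' `"lh_bankssts"`.
#'
#' @param x character vector of parcel labels.
#' @return character vector of canonical labels.
#' @export
normalize_parcel_id <- function(x) {
  x <- as.character(x)
  x <- sub("^L_", "lh_", x)
  x <- sub("^R_", "rh_", x)
  x
}

atlas_centroids <- function(atlas) {
  m <- as.matrix(atlas[, c("cx", "cy", "cz")])
  rownames(m) <- atlas$parcel_id
  m
}

atlas_hash <- function(atlas) {
  rlang::hash(list(atlas$parcel_id, round(atlas_centroids(atlas), 10)))
}

# Abort when a map carries too many missing values for pairwise-complete
# handling to be trustworthy (threshold fraction of NA entries).
check_na_fraction <- function(x, what = "map", max_frac = 0.1) {
  frac <- mean(is.na(x))
  if (frac > max_frac)
    stop(sprintf("%s has %.0f%% missing values (limit %.0f%%)",
                 what, 100 * frac, 100 * max_frac))
  invisible(frac)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read an atlas table
#'
#' Expects a tab-separated table with columns `parcel_id`, `hemisphere`,
#' `cx`, `cy`, `cz` and optionally `cyto_class`.
#'
#' @param path file path.
#' @return A [coalt_atlas()] object.
#' @export
load_atlas <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("parcel_id", "hemisphere", "cx", "cy", "cz")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("atlas table missing columns: ", paste(miss, collapse = ", "))
  coalt_atlas(tab$parcel_id, tab$hemisphere,
              as.matrix(tab[, c("cx", "cy", "cz")]),
              if ("cyto_class" %in% names(tab)) tab$cyto_class else NULL)
}

#' Write an atlas table
#' @param atlas a [coalt_atlas()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a parcels x disorders effect table
#'
#' Reads a tab-separated table with a `parcel_id` column and one numeric
#' column of Cohen's d values per disorder. Rows may be in any order; they
#' are reordered to the atlas order. Unknown or missing parcels and
#' non-numeric cells are hard errors naming the offender.
#'
#' @param path file path.
#' @param atlas a [coalt_atlas()].
#' @return numeric matrix (parcels x disorders) with parcel row names, in
#'   atlas order.
#' @export
load_effect_table <- function(path, atlas) {
  tab <- read_tsv_checked(path)
  if (!"parcel_id" %in% names(tab)) stop("effect table needs a parcel_id column")
  ids <- normalize_parcel_id(tab$parcel_id)
  unknown <- setdiff(ids, atlas$parcel_id)
  if (length(unknown))
    stop("unknown parcel_id in effect table: ", paste(unknown, collapse = ", "))
  missing <- setdiff(atlas$parcel_id, ids)
  if (length(missing))
    stop("effect table missing parcel_id: ", paste(missing, collapse = ", "))
  cols <- setdiff(names(tab), "parcel_id")
  if (!length(cols)) stop("effect table has no disorder columns")
  for (cn in cols) {
    v <- tab[[cn]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric cell in column '%s', row %d ('%s')",
                     cn, bad[1], v[bad[1]]))
      tab[[cn]] <- suppress
    }
    if (!is.numeric(tab[[cn]]))
      stop(sprintf("column '%s' is not numeric", cn))
  }
  m <- as.matrix(tab[match(atlas$parcel_id, ids), cols, drop = FALSE])
  rownames(m) <- atlas$parcel_id
  m
}

#' Write an effect table
#' @param effects parcels x disorders matrix with parcel row names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  df <- data.frame(parcel_id = rownames(effects), effects,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a labeled square matrix
#'
#' Reads an n x n tab-separated numeric table whose first column holds row
#' labels and whose header holds column labels. Labels are validated against
#' the atlas (when given) and symmetry is checked for symmetric kinds.
#'
#' @param path file path.
#' @param atlas optional [coalt_atlas()]; when given, labels must match the
#'   atlas parcels in order.
#' @param kind one of `"coalteration"`, `"affinity"`, `"connectivity"`,
#'   `"similarity"`. All are symmetric kinds.
#' @param tol symmetry tolerance.
#' @return numeric matrix with dimnames.
#' @export
load_square_matrix <- function(path, atlas = NULL, kind = "connectivity",
                               tol = 1e-10) {
  tab <- read_tsv_checked(path)
  lab <- normalize_parcel_id(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  colnames(m) <- normalize_parcel_id(colnames(m))
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix is not square: %d x %d", nrow(m), ncol(m)))
  if (!identical(lab, colnames(m)))
    stop("row labels do not match column labels")
  rownames(m) <- lab
  if (!is.null(atlas) && !identical(lab, atlas$parcel_id))
    stop("matrix labels do not match atlas parcels")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop("matrix is asymmetric beyond tolerance for kind '", kind, "'")
  attr(m, "kind") <- kind
  m
}

#' Write a labeled square matrix
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(parcel_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load subcortical seed-to-cortex connectivity profiles
#'
#' @param path file path to a seeds x parcels tab-separated table (first
#'   column seed labels).
#' @param atlas a [coalt_atlas()]; columns must match its parcels.
#' @return numeric matrix (seeds x parcels).
#' @export
load_seed_profiles <- function(path, atlas) {
  tab <- read_tsv_checked(path)
  lab <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  colnames(m) <- normalize_parcel_id(colnames(m))
  if (!identical(colnames(m), atlas$parcel_id))
    stop("seed profile columns do not match atlas parcels")
  rownames(m) <- lab
  m
}

#' Write a parcel map as a two-column table
#' @param values named numeric vector (names = parcel ids).
#' @param path output file path.
#' @param value_name column name for the values.
#' @return `path`, invisibly.
#' @export
write_parcel_map <- function(values, path, value_name = "value") {
  df <- data.frame(parcel_id = names(values), v = as.numeric(values),
                   stringsAsFactors = FALSE)
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stage report: result tables plus a run manifest
#'
#' Writes each table in `results` as a tab-separated file and a
#' `run_manifest.json` carrying provenance (package version, seed, config and
#' its hash) sufficient to re-run the stage.
#'
#' @param results named list of data.frames / matrices / named vectors.
#' @param dir output directory (created if needed).
#' @param seed integer seed used for the stage (or `NA`).
#' @param config list of stage parameters recorded verbatim in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_report <- function(results, dir, seed = NA_integer_, config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.list(results) ||
      (length(results) > 0 && (is.null(names(results)) || any(names(results) == ""))))
    stop("results must be a named list")
  for (nm in names(results)) {
    x <- results[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (is.matrix(x) && !is.null(rownames(x))) {
      write_square_matrix_like(x, path)
    } else if (is.data.frame(x)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.numeric(x) && !is.null(names(x))) {
      write_parcel_map(x, path, value_name = nm)
    } else {
      stop("cannot serialize result '", nm, "'")
    }
  }
  manifest <- list(
    package = "coalt",
    version = as.character(utils::packageVersion("coalt")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    tables = paste0(names(results), ".tsv")
  )
  mpath <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

write_square_matrix_like <- function(m, path) {
  df <- data.frame(parcel_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
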