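#' Build a spherical-rotation (spin) permutation ensemble
#'
#' Spin tests provide a null distribution for spatial correlations between
#' parcellated cortical maps that respects spatial autocorrelation: parcel
#' centroids are randomly rotated on the sphere and each parcel is
#' reassigned the value of the nearest original centroid within its
#' hemisphere (great-circle distance; duplicates allowed, no rejection).
#' For every spin a uniform random 3D rotation is drawn, applied to
#' left-hemisphere centroids, and its x-mirrored counterpart applied to the
#' right hemisphere, so mirrored hemispheres rotate coherently.
#'
#' @param atlas a [coalt_atlas()] with unit-sphere centroids.
#' @param n_spins number of rotations (>= 100 recommended; a warning is
#'   issued below that since p-value resolution suffers). The smallest
#'   attainable p is `1 / (n_spins + 1)`, so publication-grade bounds such
#'   as p < 1e-4 need 10000 spins.
#' @param seed integer RNG seed.
#' @return list of class `coalt_spins`: `permutations` (n_spins x n_parcels
#'   source-index matrix), `n_spins`, `seed`, `atlas_hash`, `parcel_id`.
#' @export
build_spins <- function(atlas, n_spins = 1000, seed = 1L) {
  if (n_spins < 100)
    warning("n_spins < 100 gives coarse p-value resolution")
  cen <- atlas_centroids(atlas)
  left <- which(atlas$hemisphere == "L")
  right <- which(atlas$hemisphere == "R")
  set.seed(as.integer(seed))
  perms <- matrix(NA_integer_, n_spins, nrow(atlas))
  M <- diag(c(-1, 1, 1))
  for (k in seq_len(n_spins)) {
    R <- random_rotation()
    perms[k, ] <- spin_permutation(cen, left, right, R, M %*% R %*% M)
  }
  out <- list(permutations = perms, n_spins = as.integer(n_spins),
              seed = as.integer(seed), atlas_hash = atlas_hash(atlas),
              parcel_id = atlas$parcel_id)
  class(out) <- "coalt_spins"
  out
}

#' @export
print.coalt_spins <- function(x, ...) {
  cat("<coalt_spins> ", x$n_spins, " spins on ", length(x$parcel_id),
      " parcels (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# uniform (Haar) random rotation in SO(3): QR of a Gaussian matrix with the
# standard sign fix, then determinant forced to +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# one spin: rotate each hemisphere's centroids and assign each parcel the
# index of the nearest original centroid of the same hemisphere (max cosine
# = min great-circle distance)
spin_permutation <- function(cen, left, right, R_left, R_right) {
  perm <- integer(nrow(cen))
  rotL <- cen[left, , drop = FALSE] %*% t(R_left)
  simL <- rotL %*% t(cen[left, , drop = FALSE])
  perm[left] <- left[max.col(simL, ties.method = "first")]
  rotR <- cen[right, , drop = FALSE] %*% t(R_right)
  simR <- rotR %*% t(cen[right, , drop = FALSE])
  perm[right] <- right[max.col(simR, ties.method = "first")]
  perm
}

#' Generate spin surrogate maps
#'
#' Surrogate k carries the original map's values indexed by permutation k;
#' the value distribution is preserved up to duplication and the spatial
#' autocorrelation structure approximately.
#'
#' @param map numeric vector on the ensemble's atlas (named vectors are
#'   checked against the ensemble's parcel ids).
#' @param spins a [build_spins()] ensemble.
#' @return n_parcels x n_spins matrix of surrogate maps.
#' @export
spin_map <- function(map, spins) {
  if (!inherits(spins, "coalt_spins")) stop("spins must be a coalt_spins object")
  if (length(map) != length(spins$parcel_id))
    stop("map length does not match the spin ensemble's atlas")
  if (!is.null(names(map)) && !identical(names(map), spins$parcel_id))
    stop("map parcel names do not match the spin ensemble's atlas")
  matrix(map[t(spins$permutations)], nrow = length(map))
}

#' Empirical permutation p-value (add-one estimator)
#'
#' `p = (1 + #qualifying nulls) / (1 + n_nulls)`; two-sided qualification is
#' `|null| >= |obs|`. The add-one rule avoids p = 0 and is standard
#' permutation practice.
#'
#' @param obs observed statistic.
#' @param nulls numeric vector of null statistics (>= 100 recommended).
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @return p-value in `(0, 1]`.
#' @export
spin_pvalue <- function(obs, nulls, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  nulls <- nulls[!is.na(nulls)]
  if (!length(nulls)) stop("empty null distribution")
  hits <- switch(sided,
                 two = sum(abs(nulls) >= abs(obs)),
                 greater = sum(nulls >= obs),
                 less = sum(nulls <= obs))
  (1 + hits) / (1 + length(nulls))
}
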