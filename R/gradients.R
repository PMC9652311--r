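#' Normalized-angle affinity matrix
#'
#' Row-thresholds a symmetric matrix (keeping the top `(1 - sparsity)`
#' fraction of each row, the embedding-toolbox convention) and converts it
#' into a non-negative symmetric affinity using the normalized angle
#' similarity kernel: `affinity(i, j) = 1 - arccos(cosine(row_i, row_j)) / pi`,
#' computed on the thresholded rows. Values lie in `[0, 1]` (in `[0.5, 1]`
#' when thresholded rows are non-negative) with unit diagonal.
#'
#' @param m symmetric numeric matrix (typically a co-alteration matrix).
#' @param sparsity row threshold, default 0.8 (keep top 20% per row).
#' @return symmetric affinity matrix, attribute `kind = "affinity"` and
#'   `sparsity`.
#' @export
build_affinity <- function(m, sparsity = 0.8) {
  m <- as.matrix(m)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-10)
    stop("build_affinity requires a symmetric matrix")
  thr <- threshold_matrix(m, sparsity = sparsity, scope = "row")
  norms <- sqrt(rowSums(thr^2))
  zero <- norms == 0
  if (any(zero))
    stop("zero row after thresholding at parcel(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  cosine <- tcrossprod(thr / norms)
  cosine[cosine > 1] <- 1
  cosine[cosine < -1] <- -1
  aff <- 1 - acos(cosine) / pi
  diag(aff) <- 1
  aff <- (aff + t(aff)) / 2
  dimnames(aff) <- dimnames(m)
  attr(aff, "kind") <- "affinity"
  attr(aff, "sparsity") <- sparsity
  aff
}

#' Diffusion map embedding of an affinity matrix
#'
#' Density-normalizes the affinity (`W' = D^-alpha W D^-alpha`, `D` the
#' diagonal of row sums), row-normalizes `W'` into a Markov transition
#' operator, and eigendecomposes it (via the standard symmetric
#' conjugation, with a dense symmetric solver — exact at this problem
#' size). The trivial stationary component (eigenvalue 1, constant
#' eigenvector) is dropped; under the diffusion-time-zero rule each
#' remaining eigenvector is scaled by `lambda / (1 - lambda)`. Components
#' are ordered by eigenvalue, and each component's sign is fixed so its
#' correlation with `sign_anchor` is non-negative (gradient sign is
#' otherwise arbitrary); without an anchor, the entry of largest magnitude
#' is made positive.
#'
#' @param aff symmetric non-negative affinity matrix.
#' @param alpha density-anisotropy parameter in `[0, 1]` (0 = maximal
#'   influence of sampling density, 1 = none); 0.5 retains global relations
#'   and is robust to noise, and is the default used throughout.
#' @param n_components number of non-trivial components to return.
#' @param diffusion_time 0 (default) applies the `lambda / (1 - lambda)`
#'   scaling; a positive value scales by `lambda^t`; `NA` returns plain
#'   eigenvectors.
#' @param sign_anchor optional numeric map used to fix component signs
#'   (e.g. a centroid coordinate axis).
#' @return list of class `coalt_gradients`: `components` (parcels x k,
#'   G1 = column 1), `eigenvalues` (non-trivial, descending),
#'   `variance_fraction` (eigenvalue over the retained non-trivial
#'   eigenvalue sum), `alpha`, `diffusion_time`, `sign_anchor`,
#'   `degenerate` (adjacent eigenvalue gaps below 1e-10).
#' @export
diffusion_embedding <- function(aff, alpha = 0.5, n_components = 10,
                                diffusion_time = 0, sign_anchor = NULL) {
  aff <- as.matrix(aff)
  n <- nrow(aff)
  if (n != ncol(aff) || max(abs(aff - t(aff))) > 1e-10)
    stop("affinity must be square symmetric")
  if (min(aff) < -1e-12) stop("affinity must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  n_components <- min(n_components, n - 1)

  d <- rowSums(aff)
  if (any(d <= 0)) stop("affinity has an all-zero row")
  L <- aff / outer(d^alpha, d^alpha)
  d2 <- rowSums(L)
  M <- L / sqrt(outer(d2, d2))
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  # right eigenvectors of the Markov operator P = D2^-1 L
  phi <- e$vectors / sqrt(d2)
  # normalize against the trivial stationary component (constant)
  phi <- phi / phi[, 1]
  idx <- seq_len(n_components) + 1L
  lam_k <- lam[idx]
  comp <- phi[, idx, drop = FALSE]
  scaling <- if (is.na(diffusion_time)) {
    rep(1, length(lam_k))
  } else if (diffusion_time == 0) {
    lam_k / (1 - pmin(lam_k, 1 - 1e-12))
  } else {
    lam_k^diffusion_time
  }
  comp <- sweep(comp, 2, scaling, `*`)
  for (j in seq_len(ncol(comp))) {
    flip <- if (!is.null(sign_anchor)) {
      stats::cor(comp[, j], sign_anchor) < 0
    } else {
      comp[which.max(abs(comp[, j])), j] < 0
    }
    if (isTRUE(flip)) comp[, j] <- -comp[, j]
  }
  dimnames(comp) <- list(rownames(aff), paste0("G", seq_len(ncol(comp))))
  lam_pos <- pmax(lam_k, 0)
  out <- list(components = comp,
              eigenvalues = lam_k,
              variance_fraction = if (sum(lam_pos) > 0) lam_pos / sum(lam_pos)
                                  else rep(NA_real_, length(lam_k)),
              alpha = alpha,
              diffusion_time = diffusion_time,
              sign_anchor = if (is.null(sign_anchor)) "max-abs-positive"
                            else "user anchor",
              degenerate = which(abs(diff(lam_k)) < 1e-10))
  class(out) <- "coalt_gradients"
  out
}

#' @export
print.coalt_gradients <- function(x, ...) {
  cat("<coalt_gradients> ", ncol(x$components), " components on ",
      nrow(x$components), " parcels (alpha = ", x$alpha, ")\n", sep = "")
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$variance_fraction))], 1)
  cat("  variance fraction: ", paste0(vf, "%", collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Variance fraction explained by each gradient
#'
#' Each retained non-trivial eigenvalue divided by the sum over the
#' retained non-trivial eigenvalues (negative eigenvalues clipped at zero).
#'
#' @param g a [diffusion_embedding()] result.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
variance_explained <- function(g) {
  lam <- pmax(g$eigenvalues, 0)
  if (sum(lam) == 0) stop("all-zero spectrum")
  out <- lam / sum(lam)
  names(out) <- colnames(g$components)
  out
}

#' Quantile-bin a gradient into equal-rank bins
#'
#' Rank-based quantile binning (default 20 five-percentile bins). Tied
#' values share the lower bin; binning is invariant to monotone transforms
#' of the component.
#'
#' @param g numeric component values.
#' @param n_bins number of bins (<= number of parcels).
#' @return integer bin label (1..n_bins) per parcel.
#' @export
bin_gradient <- function(g, n_bins = 20) {
  if (anyNA(g) || any(!is.finite(g))) stop("component values must be finite")
  if (n_bins > length(g)) stop("n_bins exceeds the number of parcels")
  out <- bin_by_rank(g, n_bins)
  names(out) <- names(g)
  out
}

#' Leave-one-disorder-out gradient stability
#'
#' Recomputes the co-alteration matrix and the first two gradients with
#' each disorder excluded and reports the absolute correlation (sign
#' aligned) between the full-sample and reduced gradients.
#'
#' @param effects parcels x disorders matrix (>= 4 disorders).
#' @param sparsity,alpha passed to [build_affinity()] /
#'   [diffusion_embedding()].
#' @return n_disorders x 2 matrix of `|r|` values (rows = excluded
#'   disorder, columns = G1, G2).
#' @export
gradient_stability <- function(effects, sparsity = 0.8, alpha = 0.5) {
  effects <- as.matrix(effects)
  if (ncol(effects) < 4)
    stop("leave-one-out stability requires at least 4 disorders")
  full <- diffusion_embedding(
    build_affinity(coalteration_matrix(effects), sparsity), alpha = alpha,
    n_components = 2)
  out <- matrix(NA_real_, ncol(effects), 2,
                dimnames = list(colnames(effects), c("G1", "G2")))
  for (j in seq_len(ncol(effects))) {
    red <- diffusion_embedding(
      build_affinity(coalteration_matrix(effects[, -j, drop = FALSE]), sparsity),
      alpha = alpha, n_components = 2)
    out[j, ] <- abs(diag(stats::cor(full$components[, 1:2],
                                    red$components[, 1:2])))
  }
  out
}
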