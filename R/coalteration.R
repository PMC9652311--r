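#' Cross-disorder co-alteration matrix
#'
#' Computes the inter-regional co-alteration (structural covariance of
#' illness effects) matrix: entry (i, j) is the Pearson correlation between
#' parcel i's and parcel j's vectors of Cohen's d values across disorders.
#' Missing values are handled pairwise-complete. With `weights`, a weighted
#' Pearson correlation (via [stats::cov.wt()]) is used — the usual choice is
#' weights proportional to per-disorder total sample size.
#'
#' @param effects parcels x disorders numeric matrix (>= 3 disorders).
#' @param weights optional positive per-disorder weights.
#' @return symmetric parcels x parcels correlation matrix, diagonal 1,
#'   attribute `kind = "coalteration"`. Parcels with a constant effect
#'   profile yield `NA` rows/columns with a warning.
#' @export
coalteration_matrix <- function(effects, weights = NULL) {
  effects <- as.matrix(effects)
  if (ncol(effects) < 3)
    stop("at least 3 disorders are required for cross-disorder correlation")
  check_na_fraction(effects, "effect table")
  profiles <- t(effects)                       # disorders x parcels
  sds <- apply(profiles, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const))
    warning("constant effect profile at parcel(s): ",
            paste(colnames(profiles)[const], collapse = ", "),
            "; correlations set to NA")
  if (is.null(weights)) {
    m <- suppressWarnings(
      stats::cor(profiles, use = "pairwise.complete.obs"))
  } else {
    if (length(weights) != nrow(profiles) || any(weights <= 0))
      stop("weights must be positive, one per disorder")
    if (anyNA(effects))
      stop("weighted correlation requires complete effect maps")
    m <- stats::cov.wt(profiles, wt = weights / sum(weights), cor = TRUE)$cor
  }
  if (any(const)) {
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  diag(m) <- 1
  dimnames(m) <- list(rownames(effects), rownames(effects))
  attr(m, "kind") <- "coalteration"
  attr(m, "n_obs") <- nrow(profiles)
  m
}

#' Cross-disorder hit map
#'
#' The hit map is the sum of per-disorder effect maps after z-scoring each
#' map across parcels; it indexes how strongly and consistently a parcel is
#' affected across disorders. `part = "reductions"` keeps only negative
#' Cohen's d entries (others set to 0) before z-scoring, `"increases"`
#' analogously keeps positives.
#'
#' @param effects parcels x disorders matrix.
#' @param part `"all"`, `"reductions"` or `"increases"`.
#' @return named numeric vector (one value per parcel).
#' @export
hit_map <- function(effects, part = c("all", "reductions", "increases")) {
  part <- match.arg(part)
  effects <- as.matrix(effects)
  x <- effects
  if (part == "reductions") x[x > 0] <- 0
  if (part == "increases") x[x < 0] <- 0
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  usable <- !is.na(sds) & sds > 0
  if (!all(usable))
    warning("zero-variance map skipped for disorder(s): ",
            paste(colnames(x)[!usable], collapse = ", "))
  if (!any(usable)) stop("no usable disorder maps")
  z <- scale(x[, usable, drop = FALSE])
  out <- rowSums(z)
  names(out) <- rownames(effects)
  out
}

#' Threshold a symmetric matrix, keeping only the strongest connections
#'
#' With `scope = "global"`, the top `(1 - sparsity)` fraction of
#' upper-triangle entries by signed value is retained (count by ceiling) and
#' everything else is zeroed symmetrically; the diagonal is always zeroed.
#' With `scope = "row"`, the top `(1 - sparsity)` fraction of each row's
#' off-diagonal entries is retained independently (the result is not
#' re-symmetrized). Ties are broken by value, then lower label index, so the
#' retained set is deterministic.
#'
#' @param m symmetric numeric matrix.
#' @param sparsity fraction of connections removed, in `[0, 1)`; the
#'   conventional choice of 0.8 keeps the top 20%.
#' @param scope `"global"` or `"row"`.
#' @return thresholded matrix with attributes `sparsity` and `scope`.
#' @export
threshold_matrix <- function(m, sparsity = 0.8, scope = c("global", "row")) {
  scope <- match.arg(scope)
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      sparsity < 0 || sparsity >= 1)
    stop("sparsity must be in [0, 1)")
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m)) stop("matrix must be square")
  out <- matrix(0, n, n, dimnames = dimnames(m))
  if (scope == "global") {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    vals <- m[ut]
    keep_n <- ceiling((1 - sparsity) * length(vals))
    ord <- order(-vals, ut[, 1], ut[, 2])
    keep <- ord[seq_len(keep_n)]
    sel <- ut[keep, , drop = FALSE]
    out[sel] <- vals[keep]
    out[sel[, c(2, 1), drop = FALSE]] <- vals[keep]
  } else {
    keep_n <- ceiling((1 - sparsity) * (n - 1))
    for (i in seq_len(n)) {
      js <- setdiff(seq_len(n), i)
      vals <- m[i, js]
      ord <- order(-vals, js)
      sel <- js[ord[seq_len(keep_n)]]
      out[i, sel] <- m[i, sel]
    }
  }
  attr(out, "sparsity") <- sparsity
  attr(out, "scope") <- scope
  attr(out, "kind") <- attr(m, "kind")
  out
}

#' Degree-centrality hub map of a thresholded matrix
#'
#' Thresholds the matrix (see [threshold_matrix()]) and computes per-parcel
#' degree centrality: the sum of retained (supra-threshold) edge weights
#' (`mode = "weighted_sum"`, the default, matching the "sum of strong
#' connections" convention on thresholded covariance) or the count of
#' retained edges (`mode = "binary_count"`).
#'
#' @param m symmetric numeric matrix.
#' @param sparsity passed to [threshold_matrix()].
#' @param mode `"weighted_sum"` or `"binary_count"`.
#' @param scope passed to [threshold_matrix()].
#' @return named numeric vector of degrees with attributes `sparsity`,
#'   `mode`, `scope`.
#' @export
degree_hubs <- function(m, sparsity = 0.8,
                        mode = c("weighted_sum", "binary_count"),
                        scope = c("global", "row")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  m <- as.matrix(m)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-10)
    stop("degree_hubs requires a symmetric matrix")
  thr <- threshold_matrix(m, sparsity = sparsity, scope = scope)
  deg <- if (mode == "weighted_sum") rowSums(thr) else rowSums(thr != 0)
  names(deg) <- rownames(m)
  attr(deg, "sparsity") <- sparsity
  attr(deg, "mode") <- mode
  attr(deg, "scope") <- scope
  deg
}

#' Correlate two parcel maps with spin-test significance
#'
#' Pearson correlation between two maps on the same atlas, with an empirical
#' p-value from a spherical-rotation null: map `a` is spun
#' (see [build_spins()]) and the correlation recomputed for every rotation.
#' The add-one estimator `p = (1 + #qualifying nulls) / (1 + n_spins)` is
#' used; two-sided compares `|r_null| >= |r_obs|`.
#'
#' @param a,b numeric parcel maps (same length; `a` is the spun map).
#' @param spins a [build_spins()] ensemble on the maps' atlas.
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @return list with `r`, `p_spin`, `n_spins`, `sided`.
#' @export
correlate_maps <- function(a, b, spins, sided = "two") {
  if (length(a) != length(b)) stop("maps differ in length")
  ok <- stats::complete.cases(a, b)
  if (sum(ok) < 10) stop("fewer than 10 complete parcel pairs")
  r_obs <- stats::cor(a[ok], b[ok])
  surr <- spin_map(a, spins)
  r_null <- as.vector(suppressWarnings(
    stats::cor(surr, b, use = "pairwise.complete.obs")))
  p <- spin_pvalue(r_obs, r_null, sided = sided)
  list(r = r_obs, p_spin = p, n_spins = spins$n_spins, sided = sided)
}
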