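# Independent brute-force oracles: deliberately naive re-derivations used to
# cross-check the package implementations on small instances.

# hand-coded Pearson correlation from sum formulas
cor_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# parcel-pair loop re-derivation of the co-alteration matrix
coalteration_oracle <- function(effects) {
  n <- nrow(effects)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(effects), rownames(effects)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- if (i == j) 1 else cor_oracle(effects[i, ], effects[j, ])
  out
}

# enumeration oracle for global thresholding: list every upper-triangle edge,
# sort, keep the top ceiling fraction
threshold_oracle_global <- function(m, sparsity) {
  n <- nrow(m)
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    edges <- rbind(edges, c(i, j, m[i, j]))
  ord <- order(-edges[, 3], edges[, 1], edges[, 2])
  keep <- ord[seq_len(ceiling((1 - sparsity) * nrow(edges)))]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  for (k in keep) {
    out[edges[k, 1], edges[k, 2]] <- edges[k, 3]
    out[edges[k, 2], edges[k, 1]] <- edges[k, 3]
  }
  out
}

# O(n^2) recount oracle for degree centrality on the thresholded graph
degree_oracle <- function(m, sparsity, mode) {
  thr <- threshold_oracle_global(m, sparsity)
  n <- nrow(m)
  deg <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (thr[i, j] != 0)
    deg[i] <- deg[i] + if (mode == "weighted_sum") thr[i, j] else 1
  names(deg) <- rownames(m)
  deg
}

# spreadsheet-style oracle for the hit map: per-column mean/sd then a cell loop
hitmap_oracle <- function(effects) {
  n <- nrow(effects)
  out <- numeric(n)
  for (d in seq_len(ncol(effects))) {
    mu <- mean(effects[, d])
    sdev <- sqrt(sum((effects[, d] - mu)^2) / (n - 1))
    for (i in seq_len(n)) out[i] <- out[i] + (effects[i, d] - mu) / sdev
  }
  names(out) <- rownames(effects)
  out
}

# row-loop oracle for the coupling map (self-entry excluded)
coupling_oracle <- function(a, b) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- cor_oracle(a[i, -i], b[i, -i])
  names(out) <- rownames(a)
  out
}

# hand-coded normalized-angle kernel on row-thresholded profiles
affinity_oracle <- function(m, sparsity) {
  thr <- coalt::threshold_matrix(m, sparsity, scope = "row")
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cs <- sum(thr[i, ] * thr[j, ]) /
      (sqrt(sum(thr[i, ]^2)) * sqrt(sum(thr[j, ]^2)))
    cs <- min(max(cs, -1), 1)
    out[i, j] <- 1 - acos(cs) / pi
  }
  diag(out) <- 1
  out
}

# independent diffusion-operator route: eigendecompose the non-symmetric
# Markov operator directly with the general (non-symmetric) solver
diffusion_oracle <- function(aff, alpha = 0.5, n_components = 5) {
  d <- rowSums(aff)
  L <- aff / outer(d^alpha, d^alpha)
  P <- L / rowSums(L)
  e <- eigen(P)
  ord <- order(-Re(e$values))
  vec <- Re(e$vectors[, ord])
  vec[, seq_len(n_components) + 1, drop = FALSE]
}

# random symmetric affinity-like matrix with positive entries
random_affinity <- function(n) {
  a <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# a small default synthetic atlas shared across tests
test_atlas <- function(n_per_hemi = 34) {
  coalt::make_atlas(coalt::sim_config(n_parcels_per_hemi = n_per_hemi))
}

# Moran-style spatial autocorrelation statistic on a k-nearest-neighbour
# adjacency built from centroid directions
moran_stat <- function(x, atlas, k = 6) {
  cen <- as.matrix(atlas[, c("cx", "cy", "cz")])
  S <- tcrossprod(cen)
  diag(S) <- -Inf
  n <- nrow(cen)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(-S[i, ])[seq_len(k)]] <- 1
  W <- pmax(W, t(W))
  xc <- x - mean(x)
  (n / sum(W)) * sum(W * outer(xc, xc)) / sum(xc^2)
}
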