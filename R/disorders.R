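#' Within-disorder co-alteration matrix from a single effect map
#'
#' Inter-regional similarity of one disorder's effect map via inverted
#' (negated) absolute differences in Cohen's d: `S(i, j) = -|d_i - d_j|`,
#' so larger (closer to 0) means more similar; the diagonal is 0, the
#' maximum.
#'
#' @param d named numeric Cohen's d map.
#' @return symmetric parcels x parcels matrix, attribute
#'   `kind = "similarity"`.
#' @export
disorder_covariance <- function(d) {
  S <- -abs(outer(d, d, `-`))
  diag(S) <- 0
  dimnames(S) <- list(names(d), names(d))
  attr(S, "kind") <- "similarity"
  S
}

#' Parcel-wise coupling between disorder-specific and transdiagnostic
#' covariance
#'
#' For each parcel, the Pearson correlation between its row in the
#' disorder-specific covariance matrix and its row in the transdiagnostic
#' co-alteration matrix (self-entry excluded from both), yielding a
#' coupling map: where on the cortex a disorder's covariance profile
#' resembles the shared pattern.
#'
#' @param disorder_m parcels x parcels disorder-specific matrix.
#' @param trans_m parcels x parcels transdiagnostic co-alteration matrix.
#' @return named numeric coupling map.
#' @export
coupling_map <- function(disorder_m, trans_m) {
  if (!all(dim(disorder_m) == dim(trans_m)))
    stop("matrices must share one atlas")
  n <- nrow(disorder_m)
  out <- vapply(seq_len(n), function(i) {
    a <- disorder_m[i, -i]
    b <- trans_m[i, -i]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      NA_real_
    else stats::cor(a[ok], b[ok])
  }, 1)
  names(out) <- rownames(disorder_m)
  out
}

#' Cross-disorder similarity and clustering
#'
#' Pairwise Pearson correlations between disorder effect maps across
#' parcels, followed by agglomerative hierarchical clustering (average
#' linkage by default, complete linkage as option) on the distance `1 - r`,
#' cut at `k` clusters. Cluster labels are renumbered deterministically by
#' each cluster's smallest member index.
#'
#' @param effects parcels x disorders matrix (>= 3 disorders).
#' @param k number of clusters.
#' @param linkage `"average"` or `"complete"`.
#' @return list: `similarity` (disorders x disorders r matrix), `clusters`
#'   (named integer labels), `hclust` (the tree).
#' @export
cross_disorder_similarity <- function(effects, k = 2,
                                      linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  effects <- as.matrix(effects)
  if (ncol(effects) < 3) stop("at least 3 disorders required")
  sds <- apply(effects, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    stop("constant effect map: ",
         paste(colnames(effects)[sds == 0], collapse = ", "))
  sim <- stats::cor(effects, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
  raw <- stats::cutree(hc, k = k)
  first_member <- vapply(seq_len(k), function(cl) min(which(raw == cl)), 1L)
  relabel <- order(order(first_member))
  clusters <- relabel[raw]
  names(clusters) <- colnames(effects)
  list(similarity = sim, clusters = clusters, hclust = hc)
}

#' Position each disorder within the transdiagnostic co-alteration space
#'
#' For every disorder: (i) correlation of its Cohen's d map with the
#' transdiagnostic hub map (spin-tested); (ii) disorder-specific epicenters
#' (each seed's normative connectivity profile correlated with the
#' disorder's d map) and their percent overlap with the transdiagnostic
#' epicenter set (denominator = number of significant transdiagnostic
#' seeds; 0 with a flag when either set is empty); (iii) correlations with
#' the first two gradients (spin-tested).
#'
#' @param effects parcels x disorders matrix.
#' @param hubs transdiagnostic hub map (see [degree_hubs()]).
#' @param trans_epi transdiagnostic [map_epicenters()] result.
#' @param g a [diffusion_embedding()] result with >= 2 components.
#' @param conn connectivity bundle (see [make_connectome()]).
#' @param spins a [build_spins()] ensemble.
#' @param alpha significance level for disorder-specific epicenters.
#' @return data.frame with one row per disorder: `disorder`, `r_hub`,
#'   `p_hub`, `n_epicenters`, `epicenter_overlap_pct`, `overlap_flag`,
#'   `r_G1`, `p_G1`, `r_G2`, `p_G2`.
#' @export
embed_disorders <- function(effects, hubs, trans_epi, g, conn, spins,
                            alpha = 0.05) {
  effects <- as.matrix(effects)
  trans_sig <- trans_epi$seed[trans_epi$significant]
  rows <- lapply(colnames(effects), function(dz) {
    d <- effects[, dz]
    ch <- correlate_maps(d, hubs, spins)
    epi <- map_epicenters(d, conn, spins, alpha = alpha)
    dz_sig <- epi$seed[epi$significant]
    flag <- ""
    if (!length(trans_sig)) flag <- "no transdiagnostic epicenters"
    else if (!length(dz_sig)) flag <- "no disorder-specific epicenters"
    overlap <- if (nchar(flag)) 0
               else 100 * length(intersect(dz_sig, trans_sig)) / length(trans_sig)
    c1 <- correlate_maps(d, g$components[, 1], spins)
    c2 <- correlate_maps(d, g$components[, 2], spins)
    data.frame(disorder = dz, r_hub = ch$r, p_hub = ch$p_spin,
               n_epicenters = length(dz_sig),
               epicenter_overlap_pct = overlap, overlap_flag = flag,
               r_G1 = c1$r, p_G1 = c1$p_spin,
               r_G2 = c2$r, p_G2 = c2$p_spin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
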