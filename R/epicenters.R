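#' Map cortical and subcortical disease epicenters
#'
#' A disease epicenter is a region whose normative connectivity profile
#' spatially resembles the co-alteration hub map: alterations may be
#' anchored to its network. For each cortical seed, its connectivity row
#' (self-entry excluded from both vectors) is correlated with the hub map;
#' each subcortical seed's profile is correlated over all cortical parcels.
#' Significance comes from spinning the hub map (the only side of the
#' comparison with spherical coordinates) and recomputing every
#' correlation; no multiple-comparison correction is applied across seeds
#' by default (set `fdr = TRUE` for Benjamini-Hochberg significance).
#'
#' @param hubs numeric hub map (or any target parcel map, e.g. a hit map or
#'   a single disorder's Cohen's d map).
#' @param conn a [make_connectome()]-style bundle, or any list with
#'   `cortical` (n x n) and optionally `subcortical` (seeds x n) matrices.
#' @param spins a [build_spins()] ensemble on the same atlas.
#' @param alpha significance level on p_spin.
#' @param fdr apply Benjamini-Hochberg correction before thresholding.
#' @return data.frame of class `coalt_epicenters` with one row per seed:
#'   `seed`, `r`, `p_spin`, `significant`, `rank` (by descending r among
#'   significant seeds, ties broken by label order; NA otherwise), `type`
#'   (cortical/subcortical).
#' @export
map_epicenters <- function(hubs, conn, spins, alpha = 0.05, fdr = FALSE) {
  C <- conn$cortical
  n <- length(hubs)
  if (is.null(C) || nrow(C) != n)
    stop("hub map and cortical connectivity must share one atlas")
  surr <- spin_map(hubs, spins)
  seed_ids <- rownames(C)
  r <- p <- numeric(0)
  type <- character(0)
  for (s in seq_len(n)) {
    prof <- C[s, -s]
    if (stats::sd(prof) == 0 || anyNA(prof)) {
      r <- c(r, NA_real_); p <- c(p, NA_real_)
    } else {
      r_obs <- stats::cor(prof, hubs[-s])
      r_null <- as.vector(stats::cor(surr[-s, , drop = FALSE], prof))
      r <- c(r, r_obs)
      p <- c(p, spin_pvalue(r_obs, r_null))
    }
    type <- c(type, "cortical")
  }
  S <- conn$subcortical
  if (!is.null(S)) {
    for (s in seq_len(nrow(S))) {
      prof <- S[s, ]
      if (stats::sd(prof) == 0 || anyNA(prof)) {
        r <- c(r, NA_real_); p <- c(p, NA_real_)
      } else {
        r_obs <- stats::cor(prof, hubs)
        r_null <- as.vector(stats::cor(surr, prof))
        r <- c(r, r_obs)
        p <- c(p, spin_pvalue(r_obs, r_null))
      }
      type <- c(type, "subcortical")
    }
    seed_ids <- c(seed_ids, rownames(S))
  }
  p_eff <- if (fdr) stats::p.adjust(p, "BH") else p
  sig <- !is.na(p_eff) & p_eff < alpha
  rank_out <- rep(NA_integer_, length(r))
  if (any(sig)) {
    ord <- order(-r[sig], seed_ids[sig])
    rank_out[which(sig)[ord]] <- seq_len(sum(sig))
  }
  out <- data.frame(seed = seed_ids, r = r, p_spin = p, significant = sig,
                    rank = rank_out, type = type, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "fdr") <- fdr
  class(out) <- c("coalt_epicenters", "data.frame")
  out
}

#' Top-ranked significant epicenters
#'
#' @param res a [map_epicenters()] result.
#' @param k maximum number of seeds to return.
#' @return character vector of seed labels, descending r among significant
#'   seeds (fewer than `k`, possibly empty, if fewer are significant).
#' @export
top_epicenters <- function(res, k = 5) {
  sig <- res[!is.na(res$rank), , drop = FALSE]
  sig <- sig[order(sig$rank), , drop = FALSE]
  utils::head(sig$seed, k)
}
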