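#' Stratify a gradient by cytoarchitectonic class
#'
#' Groups parcel gradient values by the five von Economo-Koskinas classes
#' and reports descriptive statistics per class (no inferential claim).
#'
#' @param g numeric gradient component, atlas order.
#' @param atlas a [coalt_atlas()] with `cyto_class` labels.
#' @return data.frame with `class`, `n`, `mean`, `sd`; the per-class value
#'   split is attached as attribute `values`.
#' @export
stratify_by_class <- function(g, atlas) {
  if (all(is.na(atlas$cyto_class))) stop("atlas has no cyto_class labels")
  cls <- factor(atlas$cyto_class, levels = CYTO_CLASSES)
  sp <- split(g, cls)
  out <- data.frame(class = names(sp),
                    n = vapply(sp, length, 1L),
                    mean = vapply(sp, mean, 1),
                    sd = vapply(sp, stats::sd, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "values") <- sp
  out
}

#' Meta-analytic term decoding along a gradient
#'
#' Decomposes the gradient into quantile bins (default 20 five-percentile
#' bins), averages each term's parcel-wise z values within each bin's
#' parcel set, and computes each term's center of gravity along the
#' gradient as the positive-z-weighted mean bin position. Terms are ordered
#' by their center of gravity; because the bins are quantile-based the
#' result is invariant to monotone transforms of the gradient.
#'
#' @param terms parcels x terms matrix of term-association z values.
#' @param g numeric gradient component.
#' @param n_bins number of quantile bins.
#' @return list of class `coalt_term_decoding`: `z_by_bin` (n_bins x
#'   terms), `cog` (per term, in bin units; NA for terms with no positive z
#'   in any bin), `ordering` (term names sorted by cog).
#' @export
term_decoding <- function(terms, g, n_bins = 20) {
  terms <- as.matrix(terms)
  if (nrow(terms) != length(g)) stop("term table not aligned to the gradient")
  bins <- bin_gradient(g, n_bins)
  z_by_bin <- matrix(NA_real_, n_bins, ncol(terms),
                     dimnames = list(NULL, colnames(terms)))
  for (b in seq_len(n_bins)) {
    in_bin <- bins == b
    if (any(in_bin))
      z_by_bin[b, ] <- colMeans(terms[in_bin, , drop = FALSE])
  }
  pos <- pmax(z_by_bin, 0)
  wsum <- colSums(pos, na.rm = TRUE)
  cog <- colSums(pos * seq_len(n_bins), na.rm = TRUE) / wsum
  cog[wsum == 0] <- NA_real_
  ordering <- colnames(terms)[order(cog)]
  out <- list(z_by_bin = z_by_bin, cog = cog, ordering = ordering,
              n_bins = n_bins)
  class(out) <- "coalt_term_decoding"
  out
}

#' Term positions in the two-gradient plane
#'
#' Positive-z-weighted mean parcel position of each term in the (G1, G2)
#' plane, for arranging terms in a combined two-dimensional gradient space.
#'
#' @param terms parcels x terms z matrix.
#' @param g1,g2 gradient components.
#' @return terms x 2 matrix of weighted mean positions.
#' @export
term_positions <- function(terms, g1, g2) {
  terms <- as.matrix(terms)
  w <- pmax(terms, 0)
  wsum <- colSums(w)
  pos <- cbind(G1 = colSums(w * g1) / wsum, G2 = colSums(w * g2) / wsum)
  pos[wsum == 0, ] <- NA_real_
  rownames(pos) <- colnames(terms)
  pos
}

#' Gene-expression decoding of a gradient with spatial and gene nulls
#'
#' Correlates every gene's expression map with the gradient; spatial
#' specificity per gene comes from spin surrogates of the gradient
#' (two-sided, add-one). Genes passing `p_spatial < p_cut` form the
#' candidate set, summarized by its mean `|r|`. Two gene-specificity nulls
#' then test whether the candidate set is more strongly associated with the
#' gradient than comparable gene sets: the null-coexpressed-gene model
#' samples equal-size sets matched on mean absolute coexpression (genes are
#' binned into coexpression deciles and null sets match the candidate set's
#' decile histogram), and the null-brain-gene model samples equal-size sets
#' uniformly from brain-expressed genes.
#'
#' @param expr parcels x genes expression matrix, atlas order.
#' @param g numeric gradient component.
#' @param spins a [build_spins()] ensemble.
#' @param p_cut spatial-specificity threshold defining the candidate set.
#' @param n_null_sets null gene sets per specificity model.
#' @param brain_expressed logical vector per gene (required for the
#'   null-brain-gene model; skipped with a message when absent).
#' @param seed RNG seed for null-set sampling.
#' @return list of class `coalt_gene_decoding`: `table` (per-gene `gene`,
#'   `r`, `p_spatial`, `candidate`), `candidate_set`, `set_stat` (mean |r|),
#'   `p_coexp_null`, `p_brain_null`, `n_positive`, `n_negative`,
#'   `coexp_match` (candidate vs mean null-set mean-coexpression).
#' @export
gene_decoding <- function(expr, g, spins, p_cut = 0.01, n_null_sets = 1000,
                          brain_expressed = NULL, seed = 1L) {
  expr <- as.matrix(expr)
  if (nrow(expr) != length(g)) stop("expression table not aligned to the gradient")
  genes <- colnames(expr)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(ncol(expr)))
  r_obs <- as.vector(stats::cor(expr, g))
  surr <- spin_map(g, spins)
  r_null <- stats::cor(expr, surr)                    # genes x n_spins
  p_spatial <- (1 + rowSums(abs(r_null) >= abs(r_obs))) / (1 + ncol(r_null))
  candidate <- p_spatial < p_cut
  tab <- data.frame(gene = genes, r = r_obs, p_spatial = p_spatial,
                    candidate = candidate, stringsAsFactors = FALSE)

  out <- list(table = tab, candidate_set = genes[candidate],
              set_stat = NA_real_, p_coexp_null = NA_real_,
              p_brain_null = NA_real_,
              n_positive = sum(candidate & r_obs > 0),
              n_negative = sum(candidate & r_obs < 0),
              coexp_match = c(candidate = NA_real_, null_mean = NA_real_))
  class(out) <- "coalt_gene_decoding"
  n_cand <- sum(candidate)
  if (n_cand == 0) {
    message("empty candidate gene set; specificity tests skipped")
    return(out)
  }
  set.seed(as.integer(seed))
  abs_r <- abs(r_obs)
  out$set_stat <- mean(abs_r[candidate])

  # null-coexpressed-gene model: match the candidate set's coexpression profile
  co <- abs(stats::cor(expr))
  mean_coexp <- (rowSums(co) - 1) / (ncol(expr) - 1)
  decile <- bin_by_rank(mean_coexp, 10)
  cand_hist <- tabulate(decile[candidate], nbins = 10)
  by_decile <- split(seq_along(genes), decile)
  null_coexp_stat <- null_coexp_mean <- numeric(n_null_sets)
  for (k in seq_len(n_null_sets)) {
    idx <- unlist(lapply(seq_len(10), function(d) {
      pool <- by_decile[[as.character(d)]]
      if (cand_hist[d] == 0) integer(0)
      else pool[sample.int(length(pool), cand_hist[d])]
    }), use.names = FALSE)
    null_coexp_stat[k] <- mean(abs_r[idx])
    null_coexp_mean[k] <- mean(mean_coexp[idx])
  }
  out$p_coexp_null <- (1 + sum(null_coexp_stat >= out$set_stat)) /
    (1 + n_null_sets)
  out$coexp_match <- c(candidate = mean(mean_coexp[candidate]),
                       null_mean = mean(null_coexp_mean))

  # null-brain-gene model: equal-size sets from brain-expressed genes only
  if (is.null(brain_expressed)) {
    message("no brain_expressed flags; null-brain-gene model skipped")
  } else {
    pool <- which(brain_expressed)
    if (length(pool) < n_cand) {
      message("too few brain-expressed genes; null-brain-gene model skipped")
    } else {
      null_brain_stat <- vapply(seq_len(n_null_sets), function(k)
        mean(abs_r[pool[sample.int(length(pool), n_cand)]]), 1)
      out$p_brain_null <- (1 + sum(null_brain_stat >= out$set_stat)) /
        (1 + n_null_sets)
    }
  }
  out
}

#' @export
print.coalt_gene_decoding <- function(x, ...) {
  cat("<coalt_gene_decoding> ", length(x$candidate_set), " candidate genes (",
      x$n_positive, " positive, ", x$n_negative, " negative)\n", sep = "")
  if (!is.na(x$set_stat))
    cat("  set mean |r| = ", round(x$set_stat, 3),
        "; p(coexpression null) = ", x$p_coexp_null,
        ", p(brain-gene null) = ", x$p_brain_null, "\n", sep = "")
  invisible(x)
}
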