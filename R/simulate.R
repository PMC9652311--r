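#' Simulation configuration for synthetic pipeline inputs
#'
#' The generator emulates the statistical structure the co-alteration
#' analysis assumes: six disorder effect maps built from smooth latent
#' spatial patterns on the cortical sphere (three "psychotic-spectrum-like"
#' disorders sharing the first latent), spatially autocorrelated residual
#' noise, a normative connectome with planted epicenter seeds whose profiles
#' resemble a target hub map, and annotation tables (term maps with a
#' planted peak progression along a gradient; gene expression with planted
#' signal genes).
#'
#' @param n_parcels_per_hemi parcels per hemisphere (34 gives the 68-parcel
#'   Desikan-Killiany-sized atlas).
#' @param disorder_ids disorder labels; default the six ENIGMA-style labels.
#' @param shared_block labels of the disorders sharing latent pattern 1.
#' @param latent_loadings optional disorders x 3 loading matrix on the three
#'   latent spatial patterns (anterior-posterior, inferior-superior,
#'   medial-lateral). Default plants high loading on latent 1 for the shared
#'   block and distinct latents for the rest.
#' @param latent1_binary if `TRUE`, latent 1 is the standardized sign of the
#'   anterior-posterior coordinate instead of the smooth harmonic — a planted
#'   two-block spatial pattern, used to validate block recovery by the
#'   gradient decomposition.
#' @param autocorr_length angular length scale (radians) of the spatial
#'   smoothing kernel applied to noise and latent perturbations.
#' @param noise_sd residual Cohen's d standard deviation per disorder map.
#' @param epicenter_parcels indices of planted cortical epicenter seeds
#'   (default: one mid-lattice parcel per hemisphere).
#' @param subcortical_epicenters indices (1..14) of planted subcortical
#'   epicenter seeds.
#' @param conn_noise_sd relative noise in connectome profiles.
#' @param n_terms,term_width,term_noise_sd term-map generator settings.
#' @param n_genes,n_signal_genes,signal_gene_r expression generator settings.
#' @param seed integer RNG seed; recorded in all outputs.
#' @return list of class `coalt_sim_config`.
#' @export
sim_config <- function(n_parcels_per_hemi = 34,
                       disorder_ids = c("ADHD", "ASD", "BD", "MDD", "OCD", "SCZ"),
                       shared_block = c("BD", "OCD", "SCZ"),
                       latent_loadings = NULL,
                       latent1_binary = FALSE,
                       autocorr_length = 0.4,
                       noise_sd = 0.5,
                       epicenter_parcels = NULL,
                       subcortical_epicenters = c(2, 11),
                       conn_noise_sd = 0.2,
                       n_terms = 24,
                       term_width = 0.1,
                       term_noise_sd = 0.05,
                       n_genes = 500,
                       n_signal_genes = 20,
                       signal_gene_r = 0.8,
                       seed = 1L) {
  if (n_parcels_per_hemi < 4) stop("n_parcels_per_hemi must be >= 4")
  stopifnot(autocorr_length > 0, noise_sd >= 0, conn_noise_sd >= 0,
            term_width > 0, term_noise_sd >= 0,
            n_genes >= 1, n_signal_genes >= 0, n_signal_genes <= n_genes,
            signal_gene_r >= 0, signal_gene_r <= 1)
  if (!all(shared_block %in% disorder_ids))
    stop("shared_block must be a subset of disorder_ids")
  if (is.null(epicenter_parcels)) {
    k <- max(1L, round(n_parcels_per_hemi * 0.3))
    epicenter_parcels <- c(k, n_parcels_per_hemi + k)
  }
  if (any(epicenter_parcels < 1 | epicenter_parcels > 2 * n_parcels_per_hemi))
    stop("epicenter_parcels out of range")
  n_dis <- length(disorder_ids)
  if (is.null(latent_loadings)) {
    latent_loadings <- matrix(0, n_dis, 3,
                              dimnames = list(disorder_ids,
                                              c("latent1", "latent2", "latent3")))
    block <- disorder_ids %in% shared_block
    # shared block: strong, slightly varying loading on latent 1
    latent_loadings[block, 1] <- seq(1.1, 0.8, length.out = sum(block))
    others <- which(!block)
    # remaining disorders: distinct latents, alternating sign on latent 2
    alt <- c(0.5, -0.5)
    k <- 1
    for (i in others) {
      if (k <= 2) latent_loadings[i, 2] <- alt[k]
      else latent_loadings[i, 3] <- 0.5
      k <- k + 1
    }
  } else {
    latent_loadings <- as.matrix(latent_loadings)
    if (nrow(latent_loadings) != n_dis || ncol(latent_loadings) != 3)
      stop("latent_loadings must be n_disorders x 3")
    rownames(latent_loadings) <- disorder_ids
  }
  out <- list(n_parcels_per_hemi = as.integer(n_parcels_per_hemi),
              disorder_ids = disorder_ids, shared_block = shared_block,
              latent_loadings = latent_loadings,
              latent1_binary = isTRUE(latent1_binary),
              autocorr_length = autocorr_length, noise_sd = noise_sd,
              epicenter_parcels = as.integer(epicenter_parcels),
              subcortical_epicenters = as.integer(subcortical_epicenters),
              conn_noise_sd = conn_noise_sd,
              n_terms = as.integer(n_terms), term_width = term_width,
              term_noise_sd = term_noise_sd,
              n_genes = as.integer(n_genes),
              n_signal_genes = as.integer(n_signal_genes),
              signal_gene_r = signal_gene_r,
              seed = as.integer(seed))
  class(out) <- "coalt_sim_config"
  out
}

#' Build a synthetic atlas with quasi-uniform spherical centroids
#'
#' Right-hemisphere centroids are placed on a deterministic Fibonacci
#' lattice over the `x > 0` half-sphere; the left hemisphere is its mirror
#' image (`x -> -x`), so mirrored parcel pairs exist by construction.
#' Cytoarchitectonic classes are assigned by inferior-to-superior latitude
#' bands (quintiles of the z coordinate), giving five contiguous classes.
#'
#' @param config a [sim_config()].
#' @return a [coalt_atlas()].
#' @export
make_atlas <- function(config = sim_config()) {
  n <- config$n_parcels_per_hemi
  i <- seq_len(n)
  u <- (i - 0.5) / n                      # uniform in (0,1): x coordinate
  phi <- (i - 1) * pi * (3 - sqrt(5))     # golden-angle azimuth
  s <- sqrt(pmax(0, 1 - u^2))
  right <- cbind(u, s * cos(phi), s * sin(phi))
  left <- right
  left[, 1] <- -left[, 1]
  centroid <- rbind(left, right)
  hemisphere <- rep(c("L", "R"), each = n)
  parcel_id <- c(sprintf("lh_parcel%02d", i), sprintf("rh_parcel%02d", i))
  z <- centroid[, 3]
  band <- bin_by_rank(z, 5)
  cyto <- CYTO_CLASSES[band]
  coalt_atlas(parcel_id, hemisphere, centroid, cyto)
}

# geodesic (angular) similarity kernel between unit centroids;
# a von Mises-like bump exp((cos(theta) - 1) / ell^2)
angular_kernel <- function(centroids, ell) {
  cosang <- tcrossprod(centroids)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  exp((cosang - 1) / ell^2)
}

# smooth spatially autocorrelated noise maps: kernel-smoothed white noise,
# standardized per column to mean 0 / sd `sd`. The kernel combines geodesic
# proximity with homotopic (x-mirrored) proximity, so fields are smooth
# within each hemisphere and correlated between homotopic parcels — the
# bilateral symmetry structure cortical maps carry and mirrored-rotation
# spin nulls preserve.
smooth_noise <- function(atlas, n_maps, ell, sd = 1) {
  cen <- atlas_centroids(atlas)
  cen_m <- cen
  cen_m[, 1] <- -cen_m[, 1]
  cosang <- tcrossprod(cen, cen_m)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  K <- angular_kernel(cen, ell) + exp((cosang - 1) / ell^2)
  eps <- matrix(stats::rnorm(nrow(K) * n_maps), nrow(K), n_maps)
  x <- scale(K %*% eps) * sd
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

latent_patterns <- function(atlas, latent1_binary = FALSE) {
  cen <- atlas_centroids(atlas)
  # low-order, hemisphere-symmetric spatial harmonics: anterior-posterior,
  # inferior-superior, medial-lateral
  l1 <- if (latent1_binary) sign(cen[, 2]) else cen[, 2]
  L <- scale(cbind(latent1 = l1,
                   latent2 = cen[, 3],
                   latent3 = abs(cen[, 1])))
  attr(L, "scaled:center") <- NULL
  attr(L, "scaled:scale") <- NULL
  L
}

#' Simulate parcel-wise Cohen's d maps for a set of disorders
#'
#' Each disorder map is a loading-weighted sum of fixed smooth latent
#' spatial patterns plus spatially autocorrelated noise. Disorders in the
#' shared block load on the same latent, so their maps correlate; this is
#' the structure the co-alteration and clustering stages are meant to
#' recover.
#'
#' @param atlas a [coalt_atlas()].
#' @param config a [sim_config()].
#' @return parcels x disorders matrix of synthetic Cohen's d values.
#' @export
make_effects <- function(atlas, config = sim_config()) {
  set.seed(config$seed + 1L)
  L <- latent_patterns(atlas, config$latent1_binary)
  signal <- L %*% t(config$latent_loadings)
  noise <- smooth_noise(atlas, ncol(signal), config$autocorr_length,
                        sd = config$noise_sd)
  eff <- signal + noise
  dimnames(eff) <- list(atlas$parcel_id, config$disorder_ids)
  eff
}

SUBCORTICAL_IDS <- c(paste0("L_", c("accumbens", "amygdala", "caudate",
                                    "hippocampus", "pallidum", "putamen",
                                    "thalamus")),
                     paste0("R_", c("accumbens", "amygdala", "caudate",
                                    "hippocampus", "pallidum", "putamen",
                                    "thalamus")))

#' Simulate a normative connectome with planted epicenters
#'
#' The cortical matrix follows a distance-modulated multiplicative degree
#' model: edge weight between parcels i and j is `g_i g_j k(i,j)` where `g`
#' increases with the target hub map and `k` is a smooth angular-distance
#' kernel, so row sums (degree) correlate with `hub_target`. Each planted
#' epicenter seed's row is replaced by the hub map plus noise, so that
#' seed's connectivity profile resembles the hub map. Fourteen subcortical
#' seed profiles are generated likewise, with planted subcortical
#' epicenters.
#'
#' @param atlas a [coalt_atlas()].
#' @param hub_target named numeric vector (length = atlas size) the planted
#'   epicenter profiles and degrees should resemble.
#' @param config a [sim_config()].
#' @return list of class `coalt_connectome` with elements `cortical`
#'   (n x n symmetric, zero diagonal), `subcortical` (14 x n), `modality`,
#'   and the planted seed labels.
#' @export
make_connectome <- function(atlas, hub_target, config = sim_config()) {
  n <- nrow(atlas)
  if (length(hub_target) != n) stop("hub_target length must equal atlas size")
  set.seed(config$seed + 2L)
  h01 <- rescale01(hub_target)
  g <- 0.5 + h01                       # degree propensity in [0.5, 1.5]
  K <- angular_kernel(atlas_centroids(atlas), config$autocorr_length)
  C <- tcrossprod(g) * K
  if (config$conn_noise_sd > 0) {
    Z <- matrix(stats::rnorm(n * n), n, n)
    Z <- (Z + t(Z)) / sqrt(2)
    C <- C * exp(config$conn_noise_sd * Z)
  }
  epi <- config$epicenter_parcels
  for (s in epi) {
    prof <- h01 + if (config$conn_noise_sd > 0)
      drop(smooth_noise(atlas, 1, config$autocorr_length,
                        sd = config$conn_noise_sd)) else 0
    C[s, ] <- prof
    C[, s] <- prof
  }
  C <- pmax(C, 0)
  diag(C) <- 0
  dimnames(C) <- list(atlas$parcel_id, atlas$parcel_id)

  S <- matrix(0, 14, n, dimnames = list(SUBCORTICAL_IDS, atlas$parcel_id))
  for (k in seq_len(14)) {
    if (k %in% config$subcortical_epicenters) {
      S[k, ] <- h01 + if (config$conn_noise_sd > 0)
        drop(smooth_noise(atlas, 1, config$autocorr_length,
                          sd = config$conn_noise_sd)) else 0
    } else {
      S[k, ] <- exp(drop(smooth_noise(atlas, 1, config$autocorr_length, sd = 1)))
    }
  }
  S <- pmax(S, 0)
  out <- list(cortical = C, subcortical = S, modality = "rs-fMRI",
              epicenter_parcels = atlas$parcel_id[epi],
              subcortical_epicenters = SUBCORTICAL_IDS[config$subcortical_epicenters],
              seed = config$seed)
  class(out) <- "coalt_connectome"
  out
}

#' @export
print.coalt_connectome <- function(x, ...) {
  cat("<coalt_connectome> ", nrow(x$cortical), " cortical parcels, ",
      nrow(x$subcortical), " subcortical seeds (", x$modality, ")\n", sep = "")
  invisible(x)
}

TERM_IDS <- c("auditory", "multisensory", "somatosensory", "motor", "pain",
              "visual_perception", "attention", "eye_movements", "reading",
              "language", "semantics", "speech", "social_cognition",
              "face_processing", "autobiographical_memory", "episodic_memory",
              "working_memory", "cognitive_control", "inhibition",
              "decision_making", "reward", "emotion", "fear", "anxiety")

#' Simulate term-association and gene-expression annotation tables
#'
#' Term maps: 24 meta-analytic-style z maps whose response peak moves
#' monotonically along `gradient_target` from one apex to the other (term k
#' peaks at the k-th position along the gradient's rank), so the planted
#' term ordering is known. Expression: `n_genes` gene maps of which
#' `n_signal_genes` correlate with the gradient at population correlation
#' `signal_gene_r` and the rest are spatially autocorrelated noise; a
#' brain-expressed flag is assigned to all signal genes and to half of the
#' null genes.
#'
#' @param atlas a [coalt_atlas()].
#' @param gradient_target named numeric vector the annotations are planted
#'   along.
#' @param config a [sim_config()].
#' @return list with elements `terms` (parcels x terms z matrix),
#'   `expression` (parcels x genes), `genes` (data.frame: gene,
#'   brain_expressed, planted_signal).
#' @export
make_annotations <- function(atlas, gradient_target, config = sim_config()) {
  n <- nrow(atlas)
  if (length(gradient_target) != n)
    stop("gradient_target length must equal atlas size")
  set.seed(config$seed + 3L)
  q <- (rank(gradient_target, ties.method = "average") - 0.5) / n
  nt <- config$n_terms
  centers <- (seq_len(nt) - 0.5) / nt
  terms <- sapply(centers, function(cc)
    exp(-(q - cc)^2 / (2 * config$term_width^2)))
  if (config$term_noise_sd > 0)
    terms <- terms + smooth_noise(atlas, nt, config$autocorr_length,
                                  sd = config$term_noise_sd)
  term_ids <- if (nt == length(TERM_IDS)) TERM_IDS else sprintf("term%02d", seq_len(nt))
  dimnames(terms) <- list(atlas$parcel_id, term_ids)

  ng <- config$n_genes
  ns <- config$n_signal_genes
  rho <- config$signal_gene_r
  gs <- as.numeric(scale(gradient_target))
  noise <- smooth_noise(atlas, ng, config$autocorr_length, sd = 1)
  expr <- noise
  if (ns > 0)
    expr[, seq_len(ns)] <- rho * gs + sqrt(1 - rho^2) * noise[, seq_len(ns)]
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  dimnames(expr) <- list(atlas$parcel_id, gene_ids)
  planted <- c(rep(TRUE, ns), rep(FALSE, ng - ns))
  brain <- planted | (seq_len(ng) %% 2 == 0)
  genes <- data.frame(gene = gene_ids, brain_expressed = brain,
                      planted_signal = planted, stringsAsFactors = FALSE)
  list(terms = terms, expression = expr, genes = genes)
}

#' Write a full synthetic input set to a directory
#'
#' Convenience wrapper generating atlas, effects, connectome and annotation
#' tables in the package's file formats, plus a run manifest.
#'
#' @param dir output directory.
#' @param config a [sim_config()].
#' @return `dir`, invisibly.
#' @export
simulate_inputs <- function(dir, config = sim_config()) {
  atlas <- make_atlas(config)
  effects <- make_effects(atlas, config)
  hubs <- degree_hubs(coalteration_matrix(effects))
  conn <- make_connectome(atlas, hubs, config)
  co <- coalteration_matrix(effects)
  grad <- diffusion_embedding(build_affinity(co), sign_anchor = atlas$cx)
  ann <- make_annotations(atlas, grad$components[, 1], config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  write_effect_table(effects, file.path(dir, "effects.tsv"))
  write_square_matrix(conn$cortical, file.path(dir, "fc.tsv"))
  write_square_matrix_like(conn$subcortical, file.path(dir, "subcortical_fc.tsv"))
  write_square_matrix_like(ann$terms, file.path(dir, "terms.tsv"))
  write_square_matrix_like(ann$expression, file.path(dir, "expression.tsv"))
  utils::write.table(ann$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(list(), dir, seed = config$seed,
               config = unclass(config)[setdiff(names(config), "latent_loadings")])
  invisible(dir)
}

rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# rank-based quantile bins: ties share the min rank and fall in the lower bin
bin_by_rank <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "min")
  pmin(floor((r - 1) * n_bins / n) + 1L, n_bins)
}
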