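#' @keywords internal
"_PACKAGE"

#' Run the full co-alteration analysis pipeline
#'
#' Convenience wrapper chaining the stages: co-alteration matrix, hit map,
#' degree-centrality hubs, disease epicenters, diffusion-map gradients, and
#' the disorder embedding, all sharing one spin ensemble.
#'
#' @param effects parcels x disorders Cohen's d matrix, atlas order.
#' @param atlas a [coalt_atlas()].
#' @param conn connectivity bundle (see [make_connectome()] /
#'   [load_square_matrix()] + [load_seed_profiles()]).
#' @param spins optional [build_spins()] ensemble (built when `NULL`).
#' @param sparsity matrix threshold used for hubs and gradients.
#' @param alpha diffusion anisotropy parameter.
#' @param n_spins,seed spin ensemble settings when `spins` is `NULL`.
#' @return list with `coalteration`, `hit`, `hubs`, `hub_vs_hit`
#'   (correlation of hubs with the hit map), `epicenters`, `gradients`,
#'   `variance_fraction`, `disorders` (the embedding table), `spins`.
#' @export
coalt_pipeline <- function(effects, atlas, conn, spins = NULL,
                           sparsity = 0.8, alpha = 0.5,
                           n_spins = 1000, seed = 1L) {
  if (is.null(spins)) spins <- build_spins(atlas, n_spins = n_spins, seed = seed)
  co <- coalteration_matrix(effects)
  hit <- hit_map(effects)
  hubs <- degree_hubs(co, sparsity = sparsity)
  hub_vs_hit <- correlate_maps(hubs, hit, spins)
  epi <- map_epicenters(hubs, conn, spins)
  grad <- diffusion_embedding(build_affinity(co, sparsity = sparsity),
                              alpha = alpha, sign_anchor = atlas$cx)
  dis <- embed_disorders(effects, hubs, epi, grad, conn, spins)
  list(coalteration = co, hit = hit, hubs = hubs, hub_vs_hit = hub_vs_hit,
       epicenters = epi, gradients = grad,
       variance_fraction = variance_explained(grad),
       disorders = dis, spins = spins)
}
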