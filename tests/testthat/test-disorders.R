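test_that("disorder covariance is the negated absolute difference", {
  d <- c(a = 0, b = 1, c = 3)
  S <- disorder_covariance(d)
  expect_equal(S["a", "c"], -3)
  expect_equal(S["a", "b"], -1)
  expect_equal(S["b", "c"], -2)
  expect_equal(unname(diag(S)), rep(0, 3))
  set.seed(71)
  d2 <- rnorm(10)
  names(d2) <- paste0("p", 1:10)
  S2 <- disorder_covariance(d2)
  expect_equal(S2, t(S2))
  expect_true(all(S2 <= 0))
})

test_that("coupling map matches row-correlation oracle and Pearson
           invariances", {
  set.seed(72)
  a <- random_affinity(4)
  b <- random_affinity(4)
  dimnames(a) <- dimnames(b) <- list(paste0("p", 1:4), paste0("p", 1:4))
  expect_equal(coupling_map(a, b), coupling_oracle(a, b), tolerance = 1e-12)
  # proportional rows -> coupling 1 everywhere
  expect_equal(unname(coupling_map(a, 2 * a + 3)), rep(1, 4), tolerance = 1e-12)
  # adding a constant changes nothing (Pearson)
  expect_equal(coupling_map(a + 5, b), coupling_map(a, b), tolerance = 1e-12)
})

test_that("cross-disorder similarity clusters planted blocks", {
  # duplicated disorder: r = 1 and same cluster
  set.seed(73)
  eff <- matrix(rnorm(60), 20, 3,
                dimnames = list(paste0("p", 1:20), c("A", "B", "C")))
  eff <- cbind(eff, A2 = eff[, "A"])
  cs <- cross_disorder_similarity(eff, k = 2)
  expect_equal(cs$similarity["A", "A2"], 1)
  expect_equal(cs$clusters[["A"]], cs$clusters[["A2"]])

  # two well-separated blocks at zero noise
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  eff2 <- cbind(d1 = base1, d2 = base1 * 2, d3 = base2, d4 = base2 * 1.5)
  cs2 <- cross_disorder_similarity(eff2, k = 2)
  expect_equal(unname(cs2$clusters), c(1, 1, 2, 2))

  # parcel order invariance
  p <- sample(30)
  cs3 <- cross_disorder_similarity(eff2[p, ], k = 2)
  expect_equal(cs3$clusters, cs2$clusters)
  expect_error(cross_disorder_similarity(cbind(d1 = rep(1, 10),
                                               d2 = rnorm(10),
                                               d3 = rnorm(10))), "constant")
})

test_that("disorder embedding recovers exact and degenerate cases", {
  cfg <- sim_config(seed = 74)
  atlas <- make_atlas(cfg)
  eff <- make_effects(atlas, cfg)
  co <- coalteration_matrix(eff)
  hubs <- degree_hubs(co)
  conn <- make_connectome(atlas, hubs, cfg)
  spins <- build_spins(atlas, n_spins = 300, seed = 74)
  grad <- diffusion_embedding(build_affinity(co), sign_anchor = atlas$cx)
  epi <- map_epicenters(hubs, conn, spins)

  # a disorder whose map IS the hub map embeds at r_hub = 1
  eff_h <- cbind(eff, HUBLIKE = hubs)
  pos <- embed_disorders(eff_h, hubs, epi, grad, conn, spins)
  expect_equal(pos$r_hub[pos$disorder == "HUBLIKE"], 1, tolerance = 1e-12)
  expect_true(all(pos$epicenter_overlap_pct >= 0 &
                  pos$epicenter_overlap_pct <= 100))
  expect_equal(nrow(pos), 7)

  # embedding is reproducible bit-for-bit given fixed spins
  pos2 <- embed_disorders(eff_h, hubs, epi, grad, conn, spins)
  expect_identical(pos, pos2)
})

test_that("disorders without significant epicenters are flagged with zero
           overlap", {
  cfg <- sim_config(seed = 75)
  atlas <- make_atlas(cfg)
  eff <- make_effects(atlas, cfg)
  co <- coalteration_matrix(eff)
  hubs <- degree_hubs(co)
  conn <- make_connectome(atlas, hubs, cfg)
  spins <- build_spins(atlas, n_spins = 300, seed = 75)
  grad <- diffusion_embedding(build_affinity(co), sign_anchor = atlas$cx)
  epi <- map_epicenters(hubs, conn, spins)
  # a pure-noise disorder map unrelated to the connectome
  set.seed(76)
  eff_n <- cbind(eff, NOISY = rnorm(68))
  pos <- embed_disorders(eff_n, hubs, epi, grad, conn, spins, alpha = 1e-3)
  noisy <- pos[pos$disorder == "NOISY", ]
  # at 300 spins the smallest attainable p exceeds 1e-3, so no seed can pass
  expect_equal(noisy$n_epicenters, 0)
  expect_equal(noisy$epicenter_overlap_pct, 0)
  expect_match(noisy$overlap_flag, "no disorder-specific")
  expect_true(all(pos$p_hub > 0 & pos$p_hub <= 1))
})

test_that("the pipeline wrapper chains all stages consistently", {
  cfg <- sim_config(seed = 81)
  atlas <- make_atlas(cfg)
  eff <- make_effects(atlas, cfg)
  conn <- make_connectome(atlas, degree_hubs(coalteration_matrix(eff)), cfg)
  out <- coalt_pipeline(eff, atlas, conn, n_spins = 200, seed = 81)
  expect_equal(dim(out$coalteration), c(68, 68))
  expect_equal(nrow(out$epicenters), 82)
  expect_equal(nrow(out$disorders), 6)
  expect_equal(sum(out$variance_fraction), 1, tolerance = 1e-12)
  # wrapper results equal the individually computed stages
  expect_equal(out$hubs, degree_hubs(coalteration_matrix(eff)),
               tolerance = 1e-12)
})
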