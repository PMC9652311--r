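test_that("atlas construction enforces its invariants", {
  atlas <- test_atlas()
  expect_s3_class(atlas, "coalt_atlas")
  expect_equal(nrow(atlas), 68)
  expect_equal(sum(atlas$hemisphere == "L"), sum(atlas$hemisphere == "R"))
  norms <- sqrt(atlas$cx^2 + atlas$cy^2 + atlas$cz^2)
  expect_true(all(abs(norms - 1) < 1e-9))

  expect_error(coalt_atlas(c("lh_a", "lh_a"), c("L", "R"), diag(2) %x% c(1, 0)),
               "duplicated")
  bad_cen <- matrix(c(2, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  expect_error(coalt_atlas(c("lh_a", "rh_a"), c("L", "R"), bad_cen),
               "unit-norm")
})

test_that("parcel label dialects normalize to canonical names", {
  expect_equal(normalize_parcel_id(c("L_bankssts", "R_insula", "lh_cuneus")),
               c("lh_bankssts", "rh_insula", "lh_cuneus"))
})

test_that("effect tables load order-invariantly and round-trip", {
  atlas <- test_atlas(6)
  eff <- make_effects(atlas, sim_config(n_parcels_per_hemi = 6, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_effect_table(eff, path)
  loaded <- load_effect_table(path, atlas)
  expect_equal(loaded, eff, tolerance = 1e-12)

  # shuffle rows: identical result after loading
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  shuffled <- tempfile(fileext = ".tsv")
  set.seed(1)
  write.table(tab[sample(nrow(tab)), ], shuffled, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(load_effect_table(shuffled, atlas), loaded, tolerance = 1e-12)
})

test_that("effect table loader reports offending parcels and cells", {
  atlas <- test_atlas(6)
  eff <- make_effects(atlas, sim_config(n_parcels_per_hemi = 6, seed = 3))
  tab <- data.frame(parcel_id = rownames(eff), eff, check.names = FALSE)

  missing <- tempfile(fileext = ".tsv")
  write.table(tab[tab$parcel_id != "lh_parcel03", ], missing, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_effect_table(missing, atlas), "lh_parcel03")

  bad <- tab
  bad$ASD <- as.character(bad$ASD)
  bad$ASD[4] <- "oops"
  badpath <- tempfile(fileext = ".tsv")
  write.table(bad, badpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_effect_table(badpath, atlas), "non-numeric")
})

test_that("square matrices round-trip and reject shape/symmetry violations", {
  atlas <- test_atlas(5)
  m <- coalteration_matrix(make_effects(atlas, sim_config(n_parcels_per_hemi = 5,
                                                          seed = 2)))
  path <- tempfile(fileext = ".tsv")
  write_square_matrix(m, path)
  loaded <- load_square_matrix(path, atlas, kind = "coalteration")
  expect_equal(unname(loaded), unname(as.matrix(m)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(loaded), atlas$parcel_id)

  # identity is a valid symmetric matrix
  id <- diag(10)
  dimnames(id) <- list(atlas$parcel_id, atlas$parcel_id)
  idpath <- tempfile(fileext = ".tsv")
  write_square_matrix(id, idpath)
  expect_equal(unname(load_square_matrix(idpath, atlas)), diag(10),
               ignore_attr = TRUE)

  # drop a row: shape error
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  short <- tempfile(fileext = ".tsv")
  write.table(tab[-1, ], short, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_square_matrix(short, atlas), "square|labels")

  asym <- m
  asym[1, 2] <- asym[1, 2] + 1
  asympath <- tempfile(fileext = ".tsv")
  write_square_matrix(asym, asympath)
  expect_error(load_square_matrix(asympath, atlas), "asymmetric")
})

test_that("atlas tables round-trip including cytoarchitectonic classes", {
  atlas <- test_atlas(8)
  path <- tempfile(fileext = ".tsv")
  write_atlas(atlas, path)
  loaded <- load_atlas(path)
  expect_equal(loaded$parcel_id, atlas$parcel_id)
  expect_equal(loaded$cyto_class, atlas$cyto_class)
  expect_equal(as.matrix(loaded[, c("cx", "cy", "cz")]),
               as.matrix(atlas[, c("cx", "cy", "cz")]), tolerance = 1e-12)
})

test_that("write_report emits result tables and a provenance manifest", {
  atlas <- test_atlas(6)
  cfg <- sim_config(n_parcels_per_hemi = 6, seed = 5)
  eff <- make_effects(atlas, cfg)
  hubs <- degree_hubs(coalteration_matrix(eff))
  conn <- make_connectome(atlas, hubs, cfg)
  spins <- build_spins(atlas, n_spins = 100, seed = 5)
  epi <- map_epicenters(hubs, conn, spins)

  dir <- tempfile()
  write_report(list(hubs = hubs, epicenters = epi), dir, seed = 5,
               config = list(sparsity = 0.8))
  hub_tab <- read.table(file.path(dir, "hubs.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(hub_tab), 12)
  epi_tab <- read.table(file.path(dir, "epicenters.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(epi_tab), 12 + 14)   # cortical + subcortical seeds
  expect_true(all(c("seed", "r", "p_spin", "rank") %in% names(epi_tab)))
  manifest <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$config$sparsity, 0.8)
  expect_true(nzchar(manifest$config_hash))
})
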