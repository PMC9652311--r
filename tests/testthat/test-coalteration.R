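test_that("co-alteration entries follow perfect (anti)linearity", {
  eff <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 2, 1))
  colnames(eff) <- c("d1", "d2", "d3")
  m <- coalteration_matrix(eff)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["A", "C"], -1)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
})

test_that("co-alteration matrix matches the hand-coded correlation oracle", {
  set.seed(10)
  eff <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("p", 1:3), paste0("d", 1:4)))
  expect_equal(coalteration_matrix(eff), coalteration_oracle(eff),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("co-alteration matrix is invariant to disorder order and global
           affine rescaling, and flags constant parcels", {
  set.seed(11)
  eff <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("p", 1:10), paste0("d", 1:4)))
  m <- coalteration_matrix(eff)
  expect_equal(coalteration_matrix(eff[, c(3, 1, 4, 2)]), m, tolerance = 1e-12)
  expect_equal(coalteration_matrix(2.5 * eff - 3), m, tolerance = 1e-12)

  eff[2, ] <- 7
  expect_warning(mc <- coalteration_matrix(eff), "constant")
  expect_true(all(is.na(mc["p2", -2])))
  expect_equal(mc["p2", "p2"], 1)
})

test_that("weighted co-alteration reduces to unweighted at equal weights", {
  set.seed(12)
  eff <- matrix(rnorm(30), 6, 5)
  rownames(eff) <- paste0("p", 1:6)
  expect_equal(coalteration_matrix(eff, weights = rep(2, 5)),
               coalteration_matrix(eff), tolerance = 1e-12)
})

test_that("hit map matches the spreadsheet oracle and is linear", {
  set.seed(13)
  eff <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_equal(hit_map(eff), hitmap_oracle(eff), tolerance = 1e-12)

  # single disorder: hit map is that map's z-score
  one <- eff[, 1, drop = FALSE]
  expect_equal(hit_map(one), drop(scale(one[, 1])) * 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated disorder doubles the map
  expect_equal(hit_map(cbind(one, one)), 2 * hit_map(one), tolerance = 1e-12)
  # permutation of disorders leaves the hit map unchanged
  eff6 <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("p", 1:4), letters[1:6]))
  expect_equal(hit_map(eff6[, sample(6)]), hit_map(eff6), tolerance = 1e-12)
})

test_that("hit map parts keep only reductions or increases", {
  eff <- matrix(c(-1, 2, -3, 4, 0.5, -0.5, 1.5, -2), 4, 2,
                dimnames = list(paste0("p", 1:4), c("a", "b")))
  red <- eff; red[red > 0] <- 0
  expect_equal(hit_map(eff, "reductions"), hitmap_oracle(red), tolerance = 1e-12)
  inc <- eff; inc[inc < 0] <- 0
  expect_equal(hit_map(eff, "increases"), hitmap_oracle(inc), tolerance = 1e-12)
})

test_that("global thresholding keeps exactly the strongest edges", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[upper.tri(m)] <- c(.9, .8, .7, .3, .2, .1)
  m <- m + t(m)
  thr <- threshold_matrix(m, sparsity = 0.8)
  expect_equal(sum(thr[upper.tri(thr)] != 0), 2)   # ceil(0.2 * 6)
  expect_setequal(thr[upper.tri(thr)][thr[upper.tri(thr)] != 0], c(.9, .8))

  # sparsity 0 keeps everything except the diagonal
  thr0 <- threshold_matrix(m, sparsity = 0)
  off <- m; diag(off) <- 0
  expect_equal(thr0, off, ignore_attr = TRUE)
  expect_error(threshold_matrix(m, sparsity = 1), "sparsity")
})

test_that("thresholding matches the enumeration oracle and is idempotent", {
  set.seed(14)
  for (rep in 1:5) {
    m <- random_affinity(10)
    dimnames(m) <- list(paste0("p", 1:10), paste0("p", 1:10))
    thr <- threshold_matrix(m, 0.8)
    expect_equal(thr, threshold_oracle_global(m, 0.8), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(threshold_matrix(thr, 0.8), thr, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("row-wise thresholding retains a fixed count per row", {
  set.seed(15)
  m <- random_affinity(11)
  thr <- threshold_matrix(m, 0.8, scope = "row")
  expect_true(all(rowSums(thr != 0) == ceiling(0.2 * 10)))
})

test_that("degree centrality matches star/complete closed forms and the
           recount oracle", {
  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(degree_hubs(star, sparsity = 0)), c(3, 1, 1, 1),
               ignore_attr = TRUE)
  expect_equal(unname(degree_hubs(star, sparsity = 0, mode = "binary_count")),
               c(3, 1, 1, 1), ignore_attr = TRUE)

  complete <- matrix(1, 5, 5); diag(complete) <- 0
  rownames(complete) <- colnames(complete) <- letters[1:5]
  expect_true(all(degree_hubs(complete, sparsity = 0) == 4))

  set.seed(16)
  m <- random_affinity(10)
  dimnames(m) <- list(paste0("p", 1:10), paste0("p", 1:10))
  for (mode in c("weighted_sum", "binary_count")) {
    expect_equal(degree_hubs(m, 0.8, mode = mode), degree_oracle(m, 0.8, mode),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("retained edges never decrease endpoint degrees", {
  set.seed(17)
  m <- random_affinity(12)
  for (sp in c(0.9, 0.8, 0.5, 0.2)) {
    lo <- degree_hubs(m, sparsity = sp, mode = "binary_count")
    hi <- degree_hubs(m, sparsity = sp - 0.1, mode = "binary_count")
    expect_true(all(hi >= lo))
  }
})

test_that("correlate_maps returns exact r and the add-one spin p-value", {
  atlas <- test_atlas()
  spins <- build_spins(atlas, n_spins = 999, seed = 1)
  x <- as.numeric(scale(atlas$cy)); names(x) <- atlas$parcel_id
  res <- correlate_maps(x, x, spins)
  expect_equal(res$r, 1)
  # a self-correlation of 1 is only matched when a spin happens to reproduce
  # the identity assignment (duplicates are allowed), so p sits at or near
  # the minimal attainable value
  expect_lte(res$p_spin, 3 / 1000)
  expect_error(correlate_maps(x[1:5], x[1:5], spins), "length|complete")
})
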