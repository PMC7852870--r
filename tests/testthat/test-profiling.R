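# Usage-group clustering, PCA of CUE profiles and the CUE regression.

# a cue_matrix built directly from a carbons x (culture, replicate) matrix
cue_from_matrix <- function(m, cultures = culture_labels(), reps = 3) {
  stopifnot(ncol(m) == length(cultures) * reps)
  grid <- expand.grid(replicate = seq_len(reps), culture = cultures,
                      stringsAsFactors = FALSE)
  data <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(carbon_id = rownames(m)[i], culture = grid$culture,
               replicate = grid$replicate, cue = m[i, ],
               negative_cue = m[i, ] < 0, stringsAsFactors = FALSE)
  }))
  structure(list(data = data, missing = data.frame(), time_h = 24,
                 wavelength = 590, carbons = rownames(m),
                 cultures = cultures, replicates = seq_len(reps)),
            class = "cue_matrix")
}

block_matrix <- function(seed = 1, noise = 0.01) {
  set.seed(seed)
  means <- c(rep(0.05, 8), rep(0.45, 5), rep(0.9, 4))
  m <- outer(means, rep(1, 15)) + matrix(rnorm(17 * 15, 0, noise), 17, 15)
  rownames(m) <- sprintf("C%02d", 1:17)
  m
}

test_that("well-separated blocks are recovered exactly with ordered labels", {
  cue <- cue_from_matrix(block_matrix())
  ug <- cluster_usage_groups(cue, k = 3)
  expect_equal(unname(as.vector(ug$sizes)), c(8, 5, 4))
  # labels ordered by ascending mean CUE: lowest block is U1
  expect_true(all(ug$assignments$usage_group[1:8] == "U1"))
  expect_true(all(ug$assignments$usage_group[9:13] == "U2"))
  expect_true(all(ug$assignments$usage_group[14:17] == "U3"))
  # merge heights are monotone nondecreasing (complete linkage)
  expect_true(all(diff(ug$carbon_hclust$height) >= -1e-12))
})

test_that("clustering is invariant to row permutation and k = 1 is a single group", {
  m <- block_matrix(seed = 2)
  cue <- cue_from_matrix(m)
  ug <- cluster_usage_groups(cue, k = 3)
  perm <- sample(nrow(m))
  ug_p <- cluster_usage_groups(cue_from_matrix(m[perm, ]), k = 3)
  got <- ug_p$assignments$usage_group[match(ug$assignments$carbon_id,
                                            ug_p$assignments$carbon_id)]
  expect_equal(got, ug$assignments$usage_group)

  ug1 <- cluster_usage_groups(cue, k = 1)
  expect_true(all(ug1$assignments$usage_group == "U1"))
  expect_error(cluster_usage_groups(cue, k = 100), "number of carbon")
})

test_that("PCA explains rank-1 structure fully and reconstructs the matrix", {
  # rank-1 matrix: one component carries all variance
  u <- seq(0.1, 1, length.out = 10)
  v <- seq(1, 2, length.out = 15)
  m1 <- outer(u, v)
  rownames(m1) <- sprintf("C%02d", 1:10)
  p1 <- pca_profiles(cue_from_matrix(m1))
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(p1$var_explained), 1, tolerance = 1e-12)

  m <- block_matrix(seed = 3)
  p <- pca_profiles(cue_from_matrix(m))
  # full reconstruction from all retained components
  recon <- p$scores %*% t(p$loadings)
  recon <- sweep(recon, 2, p$center, `+`)
  expect_equal(unname(recon), unname(m), tolerance = 1e-9)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(p$loadings))) {
    lo <- p$loadings[, j]
    expect_gte(lo[which.max(abs(lo))], 0)
  }
  # constant matrix: zero-variance warning, no components
  m0 <- matrix(0.5, 4, 15, dimnames = list(sprintf("C%02d", 1:4), NULL))
  expect_warning(p0 <- pca_profiles(cue_from_matrix(m0)), "zero variance")
  expect_equal(length(p0$var_explained), 0)
})

test_that("PCA agrees with an independent ordination implementation", {
  m <- block_matrix(seed = 4)
  p <- pca_profiles(cue_from_matrix(m))
  rda <- vegan::rda(m)
  ve <- rda$CA$eig / sum(rda$CA$eig)
  expect_equal(unname(p$var_explained[1:3]), unname(ve[1:3]),
               tolerance = 1e-9)
})

test_that("a noiseless linear response is fitted exactly", {
  grid <- expand.grid(usage_group = c("U1", "U2", "U3"),
                      initial_ratio = coculture_labels(),
                      preference = c("none", "EC", "PP"),
                      rep = 1:2, stringsAsFactors = FALSE)
  effects_u <- c(U1 = 0, U2 = 0.3, U3 = 0.5)
  effects_r <- c("1:1" = 0, "1:1000" = -0.1, "1000:1" = -0.05)
  effects_p <- c(none = 0, EC = 0.02, PP = 0.04)
  grid$cue <- 0.2 + effects_u[grid$usage_group] +
    effects_r[grid$initial_ratio] + effects_p[grid$preference]
  fit <- regress_cue(grid)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  co <- fit$coefficients[, "Estimate"]
  expect_equal(unname(co["(Intercept)"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(co["usage_groupU2"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(co["initial_ratio1:1000"]), -0.1, tolerance = 1e-9)
  expect_equal(unname(co["preferencePP"]), 0.04, tolerance = 1e-9)
  # residuals sum to zero with an intercept
  expect_equal(sum(residuals(fit$fit)), 0, tolerance = 1e-9)
})

test_that("pure-noise responses rarely show explanatory power", {
  set.seed(19)
  grid <- expand.grid(usage_group = c("U1", "U2", "U3"),
                      initial_ratio = coculture_labels(),
                      preference = c("none", "EC", "PP"),
                      rep = 1:8, stringsAsFactors = FALSE)
  r2 <- replicate(200, {
    grid$cue <- rnorm(nrow(grid))
    regress_cue(grid)$adj_r_squared
  })
  expect_gte(mean(r2 <= 0.05), 0.95)
})

test_that("planted effect sizes are recovered in the stated influence order", {
  set.seed(23)
  grid <- expand.grid(usage_group = c("U1", "U2", "U3"),
                      initial_ratio = coculture_labels(),
                      preference = c("none", "EC", "PP"),
                      rep = 1:3, stringsAsFactors = FALSE)
  effects_u <- c(U1 = 0, U2 = 0.3, U3 = 0.3)
  effects_r <- c("1:1" = 0, "1:1000" = -0.15, "1000:1" = -0.15)
  effects_p <- c(none = 0, EC = 0.05, PP = 0.05)
  grid$cue <- 0.2 + effects_u[grid$usage_group] +
    effects_r[grid$initial_ratio] + effects_p[grid$preference] +
    rnorm(nrow(grid), 0, 0.05)
  fit <- regress_cue(grid)
  expect_equal(fit$term_order,
               c("usage_group", "initial_ratio", "preference"))
  expect_lte(fit$adj_r_squared, fit$r_squared)
})
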