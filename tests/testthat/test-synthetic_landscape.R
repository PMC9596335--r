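# fraction of rook-adjacent cell pairs sharing a class
same_class_join_fraction <- function(grid) {
  m <- grid$codes
  h <- m[, -1] == m[, -ncol(m)]
  v <- m[-1, ] == m[-nrow(m), ]
  mean(c(h, v))
}

test_that("row-normalizing the published matrix gives a stochastic model", {
  tm <- landuse_transfer_fixture(c("1995", "2020"))
  mdl <- matrix_to_probs(tm)
  expect_equal(unname(rowSums(mdl$P)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(mdl$P >= 0 & mdl$P <= 1))
  expect_equal(mdl$P["arable", "woodland"], 671000 / 1840500, tolerance = 1e-12)
  # diagonal matrix -> identity model
  eye <- transfer_matrix(diag(6) * 100)
  expect_equal(unname(matrix_to_probs(eye)$P), diag(6))
  # zero row -> error naming the class
  z <- diag(6) * 100; z[4, 4] <- 0
  expect_error(matrix_to_probs(transfer_matrix(z)), "water")
})

test_that("initial landscapes hit the target composition and seed", {
  geom <- grid_geometry(100, 100)
  prm <- landscape_params(geom, seed = 7)
  g <- generate_initial(prm)
  freq <- tabulate(g$codes, 6) / 10000
  # rank thresholding realizes the proportions to within rounding, well
  # inside 3 binomial standard errors
  for (i in 1:6) {
    se <- sqrt(prm$proportions[i] * (1 - prm$proportions[i]) / 10000)
    expect_lt(abs(freq[i] - prm$proportions[i]), 3 * se + 1e-4)
  }
  expect_identical(generate_initial(prm)$codes, g$codes)
  # degenerate single-class composition
  solo <- landscape_params(geom, proportions = c(arable = 0, woodland = 1,
                                                 grassland = 0, water = 0,
                                                 construction = 0, unused = 0),
                           seed = 7)
  expect_true(all(generate_initial(solo)$codes == 2L))
})

test_that("patch_scale 0 is consistent with independent cells, larger scales clump", {
  geom <- grid_geometry(80, 80)
  composition <- c(arable = 0.25, woodland = 0.4, grassland = 0.15,
                   water = 0.1, construction = 0.08, unused = 0.02)
  g0 <- generate_initial(landscape_params(geom, composition,
                                          patch_scale = 0, seed = 11))
  # under a random spatial permutation the same-class join probability is
  # ~ sum_c p_c^2; binomial-scale tolerance on ~12640 adjacencies
  p_same <- sum(composition^2)
  jf0 <- same_class_join_fraction(g0)
  expect_lt(abs(jf0 - p_same), 4 * sqrt(p_same * (1 - p_same) / 12000))
  g4 <- generate_initial(landscape_params(geom, composition,
                                          patch_scale = 4, seed = 11))
  expect_gt(same_class_join_fraction(g4), jf0 + 0.2)
})

test_that("evolution follows the transition model row-wise", {
  tm <- landuse_transfer_fixture(c("1995", "2020"))
  mdl <- matrix_to_probs(tm)
  g0 <- generate_initial(landscape_params(grid_geometry(120, 120), seed = 13))
  g1 <- evolve(g0, mdl, seed = 14)
  expect_identical(evolve(g0, mdl, seed = 14)$codes, g1$codes)   # seeded
  emp <- cross_tabulate(g0, g1)
  Phat <- matrix_to_probs(emp)$P
  n_i <- tabulate(g0$codes, 6)
  for (i in which(n_i > 0)) for (j in 1:6) {
    se <- sqrt(mdl$P[i, j] * (1 - mdl$P[i, j]) / n_i[i])
    expect_lt(abs(Phat[i, j] - mdl$P[i, j]), 3 * se + 1 / n_i[i] + 1e-12)
  }
  # identity model leaves the grid unchanged
  eye <- matrix_to_probs(transfer_matrix(diag(6) * 100))
  expect_identical(evolve(g0, eye, seed = 15)$codes, g0$codes)
})

test_that("clustered conversions keep the same marginal flows", {
  mdl <- matrix_to_probs(landuse_transfer_fixture(c("2015", "2020")))
  g0 <- generate_initial(landscape_params(grid_geometry(90, 90), seed = 16))
  g1 <- evolve(g0, mdl, seed = 17, clustering = 5)
  Phat <- matrix_to_probs(cross_tabulate(g0, g1))$P
  n_i <- tabulate(g0$codes, 6)
  for (i in which(n_i > 50)) for (j in 1:6) {
    se <- sqrt(mdl$P[i, j] * (1 - mdl$P[i, j]) / n_i[i])
    expect_lt(abs(Phat[i, j] - mdl$P[i, j]), 4 * se + 2 / n_i[i])
  }
})

test_that("nodata cells are inert under evolution", {
  g0 <- random_aggregate(30, 30, seed = 18, nodata_frac = 0.2)
  mdl <- matrix_to_probs(landuse_transfer_fixture())
  g1 <- evolve(g0, mdl, seed = 19)
  expect_identical(is_nodata(g1), is_nodata(g0))
})

test_that("detailed expansion respects the aggregation and seeds", {
  g <- generate_initial(landscape_params(grid_geometry(50, 50), seed = 20))
  d <- expand_to_detailed(g, seed = 21)
  expect_identical(expand_to_detailed(g, seed = 21)$codes, d$codes)
  expect_identical(reclassify(d)$codes, g$codes)  # splitting inverts cleanly
  # forced sub-proportions: all woodland becomes bush forest
  d2 <- expand_to_detailed(g, seed = 21,
                           sub_props = list(woodland = c(0, 1, 0, 0)))
  expect_true(all(d2$codes[g$codes == 2L] == 22L))
})

test_that("a generated series recovers its generating transition matrix", {
  mdl <- matrix_to_probs(landuse_transfer_fixture(c("2015", "2020")))
  prm <- landscape_params(grid_geometry(100, 100), seed = 23)
  series <- generate_series(prm, mdl, 3)
  Phat <- matrix_to_probs(cross_tabulate(series[[2]], series[[3]]))$P
  n_i <- tabulate(series[[2]]$codes, 6)
  for (i in which(n_i > 0)) for (j in 1:6) {
    se <- sqrt(mdl$P[i, j] * (1 - mdl$P[i, j]) / n_i[i])
    expect_lt(abs(Phat[i, j] - mdl$P[i, j]), 3 * se + 1 / n_i[i] + 1e-12)
  }
})

test_that("more construction monotonically worsens modeled habitat", {
  geom <- grid_geometry(60, 60)
  base <- c(arable = 0.21, woodland = 0.70, grassland = 0.045, water = 0.016,
            construction = 0.019, unused = 0.01)
  fracs <- c(0.019, 0.08, 0.18)
  meanQ <- meanD <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    p <- base
    p["construction"] <- fracs[i]
    p["woodland"] <- base["woodland"] - (fracs[i] - base["construction"])
    g <- generate_initial(landscape_params(geom, p, seed = 24))
    lu <- expand_to_detailed(g, seed = 25)
    res <- run_model(lu)
    meanQ[i] <- mean(res$quality$values, na.rm = TRUE)
    meanD[i] <- mean(res$degradation$values, na.rm = TRUE)
  }
  expect_true(all(diff(meanQ) < 0))
  expect_true(all(diff(meanD) > 0))
})
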