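threats <- read_threats()
sens <- read_sensitivity()

test_that("shipped threat table carries the study parameterization", {
  expect_equal(names(threats$threats),
               c("arable", "reservoir", "urban", "rural_settlements",
                 "other_construction"))
  expect_equal(vapply(threats$threats, `[[`, numeric(1), "max_dist_km"),
               c(arable = 8, reservoir = 3, urban = 6,
                 rural_settlements = 10, other_construction = 1))
  expect_equal(sum(threats$normalized_weights), 1, tolerance = 1e-12)
  expect_equal(unname(threats$normalized_weights),
               c(0.8, 0.5, 0.75, 1, 0.4) / 3.45)
  # S_jr = 0 wherever H_j = 0 in the shipped sensitivity table
  s <- as.matrix(sens[sens$habitat == 0, setdiff(names(sens), c("code", "habitat"))])
  expect_true(all(s == 0))
})

test_that("threat presence marks exactly the source cells", {
  lu <- random_detailed(10, 10, seed = 50, nodata_frac = 0.1)
  p <- threat_presence(lu, threats$threats$rural_settlements)
  expect_equal(p == 1, lu$codes == 52L & !is_nodata(lu))
  none <- categorical_grid(matrix(21L, 3, 3), grid_geometry(3, 3))
  expect_true(all(threat_presence(none, threats$threats$urban) == 0))
  all_src <- categorical_grid(matrix(51L, 3, 3), grid_geometry(3, 3))
  expect_true(all(threat_presence(all_src, threats$threats$urban) == 1))
})

test_that("distance decay follows the linear and exponential forms", {
  lin <- threats$threats$other_construction      # d_rmax 1 km, linear
  ex <- threats$threats$rural_settlements        # d_rmax 10 km, exponential
  expect_equal(decay_weight(0, lin), 1)
  expect_equal(decay_weight(0, ex), 1)
  expect_equal(decay_weight(lin$max_dist_km, lin), 0)
  expect_equal(decay_weight(10, ex), exp(-2.99), tolerance = 1e-12)
  expect_equal(round(decay_weight(10, ex), 5), 0.05029)
  expect_equal(decay_weight(10 + 1e-9, ex), 0)   # truncated past d_rmax
  expect_equal(decay_weight(5, ex), exp(-2.99 * 5 / 10))
  expect_error(decay_weight(-0.1, ex), ">= 0")
})

test_that("kernels are isotropic stencils with a unit center", {
  k <- build_kernel(threats$threats$other_construction, cell_size = 1)
  expect_equal(dim(k), c(3, 3))
  expect_equal(k[2, 2], 1)
  expect_equal(k[1, 2], 0)               # linear decay hits 0 at 1 km
  expect_equal(k[1, 1], 0)               # sqrt(2) km > d_rmax
  for (th in threats$threats) {
    kk <- build_kernel(th, cell_size = 1)
    expect_equal(nrow(kk), 2 * ceiling(th$max_dist_km) + 1)
    expect_true(all(kk >= 0 & kk <= 1))
    expect_equal(kk, t(kk))                        # reflection symmetry
    expect_equal(kk, kk[nrow(kk):1, ncol(kk):1])   # 180-degree rotation
  }
})

test_that("a single source at 2 km degrades woodland by the closed form", {
  geom <- grid_geometry(1, 3)
  lu <- categorical_grid(matrix(c(21L, 21L, 52L), 1), geom)
  ths <- threat_set(threat_spec("rural_settlements", 52L, 10, 1, "exponential"))
  D <- degradation(lu, ths, sens)
  expect_equal(D$values[1, 1], 0.7 * exp(-2.99 * 2 / 10), tolerance = 1e-12)
  expect_equal(D$values[1, 2], 0.7 * exp(-2.99 * 1 / 10), tolerance = 1e-12)
})

test_that("kernel degradation equals the brute-force double sum", {
  for (seed in c(60, 61)) {
    lu <- random_detailed(25, 25, seed = seed, nodata_frac = 0.05)
    D <- degradation(lu, threats, sens)
    expect_equal(D$values, brute_force_degradation(lu, threats, sens),
                 tolerance = 1e-9)
  }
})

test_that("accessibility scales degradation cellwise", {
  lu <- random_detailed(15, 15, seed = 62)
  set.seed(63)
  beta <- matrix(runif(225), 15, 15)
  D <- degradation(lu, threats, sens, access = beta)
  expect_equal(D$values, brute_force_degradation(lu, threats, sens, beta),
               tolerance = 1e-9)
  expect_error(degradation(lu, threats, sens, access = beta * 2), "\\[0,1\\]")
})

test_that("no sources means zero degradation; weight scaling is immaterial", {
  lu <- categorical_grid(matrix(22L, 8, 8), grid_geometry(8, 8))
  D <- degradation(lu, threats, sens)
  expect_true(all(D$values == 0))
  # scaling all raw weights by a common factor leaves D unchanged
  lu2 <- random_detailed(15, 15, seed = 70)
  scaled <- threat_set(lapply(threats$threats, function(th) {
    th$weight <- th$weight * 0.37; th
  }))
  expect_equal(degradation(lu2, scaled, sens)$values,
               degradation(lu2, threats, sens)$values, tolerance = 1e-12)
})

test_that("quality is the half-saturation transform of degradation", {
  geom <- grid_geometry(2, 2)
  lu <- categorical_grid(matrix(c(22L, 22L, 51L, 21L), 2, 2), geom)
  pars <- model_params(k = 0.5, z = 2.5)
  # D = 0 -> Q = H
  D0 <- continuous_grid(matrix(0, 2, 2), geom)
  q0 <- quality(D0, lu, sens, pars)
  expect_equal(q0$values[1, 1], 1)        # bush forest H = 1
  expect_equal(q0$values[2, 2], 0.8)      # woodland H = 0.8
  # D = k -> Q = H/2, any z
  Dk <- continuous_grid(matrix(0.5, 2, 2), geom)
  for (z in c(0.5, 1, 2.5, 4)) {
    qk <- quality(Dk, lu, sens, model_params(k = 0.5, z = z))
    expect_equal(qk$values[1, 1], 0.5, tolerance = 1e-12)
    expect_equal(qk$values[2, 2], 0.4, tolerance = 1e-12)
  }
  # H = 0 (urban) -> Q = 0 regardless of D
  expect_equal(q0$values[1, 2], 0)
  expect_equal(quality(Dk, lu, sens, pars)$values[1, 2], 0)
})

test_that("quality decreases strictly in degradation where H > 0", {
  geom <- grid_geometry(1, 6)
  lu <- categorical_grid(matrix(22L, 1, 6), geom)
  d <- seq(0, 2, length.out = 6)
  q <- quality(continuous_grid(matrix(d, 1, 6), geom), lu, sens,
               model_params(k = 0.7, z = 1.8))
  expect_true(all(diff(as.vector(q$values)) < 0))
})

test_that("k_mode half_of_max_D halves quality at the worst cell", {
  lu <- random_detailed(20, 20, seed = 80)
  D <- degradation(lu, threats, sens)
  q <- quality(D, lu, sens, model_params(z = 2.5, k_mode = "half_of_max_D"))
  H <- sens$habitat[match(lu$codes, sens$code)]
  k <- max(D$values, na.rm = TRUE) / 2
  dz <- D$values^2.5
  expect_equal(as.vector(q$values), as.vector(H * (1 - dz / (dz + k^2.5))),
               tolerance = 1e-12)
})

test_that("all-zero sensitivity collapses quality to the suitability map", {
  lu <- random_detailed(15, 15, seed = 81)
  s0 <- sens
  for (nm in setdiff(names(s0), c("code", "habitat"))) s0[[nm]] <- 0
  D <- degradation(lu, threats, s0)
  expect_true(all(D$values == 0))
  q <- quality(D, lu, s0, model_params())
  expect_equal(as.vector(q$values), s0$habitat[match(lu$codes, s0$code)])
})

test_that("adding a threat source never raises quality anywhere", {
  lu <- random_detailed(20, 20, seed = 82)
  res <- run_model(lu, threats, sens)
  lu2 <- lu
  free <- which(!(lu$codes %in% c(1L, 43L, 51L, 52L, 53L)))[1]
  lu2$codes[free] <- 52L   # plant one rural-settlement source (10 km reach)
  res2 <- run_model(lu2, threats, sens)
  other <- seq_along(lu$codes) != free   # the converted cell changes class
  expect_true(all(res2$degradation$values[other] >=
                  res$degradation$values[other] - 1e-12))
  expect_true(all(res2$quality$values[other] <=
                  res$quality$values[other] + 1e-12))
  expect_gt(mean(res2$degradation$values), mean(res$degradation$values))
  expect_lt(mean(res2$quality$values), mean(res$quality$values))
})

test_that("run_model is deterministic and masks nodata throughout", {
  lu <- random_detailed(15, 15, seed = 83, nodata_frac = 0.2)
  a <- run_model(lu, threats, sens)
  b <- run_model(lu, threats, sens)
  expect_identical(a$degradation$values, b$degradation$values)
  expect_identical(a$quality$values, b$quality$values)
  expect_identical(is.na(a$quality$values), is_nodata(lu))
  expect_equal(a$summary$n_cells[1], sum(!is_nodata(lu)))
  # uniform bush forest, no sources: Q = 1, D = 0
  pure <- categorical_grid(matrix(22L, 6, 6), grid_geometry(6, 6))
  r <- run_model(pure, threats, sens)
  expect_true(all(r$quality$values == 1))
  expect_true(all(r$degradation$values == 0))
})

test_that("rescale01 maps a surface onto [0,1] preserving order", {
  g <- continuous_grid(matrix(c(2, 4, 6, NA), 2, 2), grid_geometry(2, 2))
  r <- rescale01(g)
  expect_equal(as.vector(r$values)[1:3], c(0, 0.5, 1))
  flat <- rescale01(continuous_grid(matrix(3, 2, 2), grid_geometry(2, 2)))
  expect_true(all(flat$values == 0))
})
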