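# Independent oracles and fixture builders shared by the suite. The oracles
# deliberately take the slow, literal route (explicit loops over cell pairs,
# exhaustive partition enumeration) so they share no code with the
# implementations they check.

# a random detailed-coded landscape over the 14 land-use codes
random_detailed <- function(n_rows, n_cols, seed,
                            codes = class_scheme()$code,
                            nodata_frac = 0) {
  set.seed(seed)
  m <- matrix(sample(codes, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
  geom <- grid_geometry(n_rows, n_cols)
  if (nodata_frac > 0) {
    nd <- sample(length(m), round(nodata_frac * length(m)))
    m[nd] <- geom$nodata_code
  }
  categorical_grid(m, geom)
}

# literal evaluation of the degradation sum: for every cell x and every
# source cell y of every threat, accumulate w_r * i_r(d_xy) * S_jr * beta
brute_force_degradation <- function(lu, threats, sens, beta = NULL) {
  nr <- lu$geometry$n_rows; nc <- lu$geometry$n_cols
  cs <- lu$geometry$cell_size
  nd <- is_nodata(lu)
  if (is.null(beta)) beta <- matrix(1, nr, nc)
  w <- threats$normalized_weights
  D <- matrix(0, nr, nc)
  for (ti in seq_along(threats$threats)) {
    th <- threats$threats[[ti]]
    src <- which(matrix(lu$codes %in% th$source_codes, nr, nc) & !nd,
                 arr.ind = TRUE)
    if (!nrow(src)) next
    s <- matrix(sens[[th$name]][match(lu$codes, sens$code)], nr, nc)
    for (r in seq_len(nr)) for (co in seq_len(nc)) {
      d <- cs * sqrt((src[, 1] - r)^2 + (src[, 2] - co)^2)
      imp <- switch(th$decay,
                    linear = pmax(1 - d / th$max_dist_km, 0),
                    exponential = exp(-(2.99 / th$max_dist_km) * d))
      imp[d > th$max_dist_km] <- 0
      D[r, co] <- D[r, co] + w[ti] * sum(imp) * s[r, co] * beta[r, co]
    }
  }
  D[nd] <- NA_real_
  D
}

# exhaustive Fisher partition: minimal within-class SSE over all ways to cut
# the sorted sample into k contiguous classes
exhaustive_jenks_cost <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    cost <- sum(vapply(seq_len(k),
                       function(m) sse(x[(b[m] + 1):b[m + 1]]), numeric(1)))
    if (cost < best) best <- cost
  }
  best
}

# per-cell tally of joint classes, the slow way
brute_force_crosstab <- function(g0, g1, cell_hm2) {
  k <- length(aggregate_classes())
  out <- matrix(0, k, k)
  nd <- is_nodata(g0) | is_nodata(g1)
  for (r in seq_len(nrow(g0$codes))) for (co in seq_len(ncol(g0$codes))) {
    if (nd[r, co]) next
    i <- g0$codes[r, co]; j <- g1$codes[r, co]
    out[i, j] <- out[i, j] + cell_hm2
  }
  out
}

# uniform-random aggregate grid
random_aggregate <- function(n_rows, n_cols, seed, nodata_frac = 0) {
  set.seed(seed)
  geom <- grid_geometry(n_rows, n_cols)
  m <- matrix(sample.int(6, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
  if (nodata_frac > 0) {
    nd <- sample(length(m), round(nodata_frac * length(m)))
    m[nd] <- geom$nodata_code
  }
  categorical_grid(m, geom, level = "aggregate")
}
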