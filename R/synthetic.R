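# Seedable synthetic categorical landscapes with tunable spatial clumping
# and Markov inter-date evolution. Initial maps are built by thresholding a
# smoothed Gaussian random field at the cumulative quantiles of the target
# class proportions: simple, reproducible, and patchiness grows with the
# smoothing length. The generator emulates the class composition and
# transition structure of real multi-date land-cover series, not any real
# region's geography.

# Evaluate `code` with a temporarily fixed RNG state, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for synthetic landscape generation
#'
#' @param geometry A `grid_geometry`.
#' @param proportions Named numeric vector of target class fractions over
#'   [aggregate_classes()] (>= 0, summing to 1). The default mirrors the
#'   study area's composition: woodland-dominated (~69.5%) with ~21.2%
#'   arable and small grassland/water/construction/unused fractions.
#' @param patch_scale Correlation length in cells (Gaussian smoothing sd);
#'   0 gives spatially independent cells.
#' @param seed Integer random seed.
#' @return A `landscape_params` object.
#' @export
landscape_params <- function(geometry,
                             proportions = c(arable = 0.212, woodland = 0.695,
                                             grassland = 0.058, water = 0.016,
                                             construction = 0.019, unused = 0.0001),
                             patch_scale = 4, seed = 1L) {
  proportions <- proportions / sum(proportions)
  if (is.null(names(proportions))) names(proportions) <- aggregate_classes()
  if (!setequal(names(proportions), aggregate_classes()))
    stop("proportions must be named over the six aggregate classes")
  if (any(proportions < 0)) stop("proportions must be >= 0")
  if (patch_scale < 0) stop("patch_scale must be >= 0")
  structure(list(geometry = geometry,
                 proportions = proportions[aggregate_classes()],
                 patch_scale = patch_scale, seed = as.integer(seed)),
            class = "landscape_params")
}

# Separable Gaussian smoothing of a matrix (zero-padded borders,
# renormalized so edges are unbiased).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm((-r):r, sd = sigma)
  w <- w / sum(w)
  pass <- function(mat) {
    nr <- nrow(mat); nc <- ncol(mat)
    acc <- matrix(0, nr, nc); norm <- matrix(0, nr, nc)
    for (o in (-r):r) {
      rows <- max(1L, 1L - o):min(nr, nr - o)
      acc[rows, ] <- acc[rows, ] + w[o + r + 1L] * mat[rows + o, ]
      norm[rows, ] <- norm[rows, ] + w[o + r + 1L]
    }
    acc / norm
  }
  t(pass(t(pass(m))))
}

#' Generate an initial aggregate-class landscape
#'
#' A standard-normal field is smoothed with a Gaussian kernel of sd
#' `patch_scale` cells and thresholded at the cumulative quantiles of the
#' target proportions (rank-based, ties broken by a seeded jitter), so
#' realized class counts match the targets to within rounding and spatial
#' clumping grows with `patch_scale`.
#'
#' @param params A `landscape_params`.
#' @return An aggregate-coded `categorical_grid`, reproducible from
#'   `(params, params$seed)`.
#' @export
generate_initial <- function(params) {
  g <- params$geometry
  n <- g$n_rows * g$n_cols
  with_seed(params$seed, {
    field <- matrix(stats::rnorm(n), g$n_rows, g$n_cols)
    field <- smooth_field(field, params$patch_scale)
    field <- field + stats::rnorm(n, sd = 1e-9)  # break ties deterministically
    cuts <- round(cumsum(params$proportions) * n)
    cuts[length(cuts)] <- n
    cls <- matrix(0L, g$n_rows, g$n_cols)
    ord <- order(field)
    lo <- 0L
    for (i in seq_along(cuts)) {
      if (cuts[i] > lo) cls[ord[(lo + 1L):cuts[i]]] <- i
      lo <- max(lo, cuts[i])
    }
    categorical_grid(cls, g, level = "aggregate")
  })
}

#' Row-normalize a transfer matrix into a Markov transition model
#'
#' @param tm A `transfer_matrix` with strictly positive row totals.
#' @return A `transition_model`: row-stochastic matrix `P` with
#'   `P[i, j] = area(i -> j) / rowtotal(i)`.
#' @export
matrix_to_probs <- function(tm) {
  rs <- rowSums(tm$areas)
  zero <- rs == 0
  if (any(zero))
    stop("zero row total for class(es): ",
         paste(tm$labels[zero], collapse = ", "))
  P <- sweep(tm$areas, 1L, rs, "/")
  structure(list(P = P, labels = tm$labels), class = "transition_model")
}

#' Evolve a landscape one period under a transition model
#'
#' Each cell of class i draws its next class from row i of `P`
#' independently. With `clustering > 0`, the number of i -> j conversions is
#' drawn first (multinomial per class) and the converting cells are then
#' chosen preferentially among cells already adjacent (8-neighborhood) to
#' the destination class, so conversions clump spatially while the row-wise
#' transition frequencies still converge to `P`.
#'
#' @param grid Aggregate-coded `categorical_grid`.
#' @param model A `transition_model`.
#' @param seed Integer seed.
#' @param clustering Non-negative adjacency bias (0 = independent cells).
#' @return The evolved `categorical_grid`.
#' @export
evolve <- function(grid, model, seed = 1L, clustering = 0) {
  if (grid$level != "aggregate") stop("evolve expects an aggregate-coded grid")
  P <- model$P
  k <- nrow(P)
  nd <- is_nodata(grid)
  out <- grid$codes
  with_seed(seed, {
    if (clustering <= 0) {
      for (i in seq_len(k)) {
        idx <- which(grid$codes == i & !nd)
        if (!length(idx)) next
        out[idx] <- sample.int(k, length(idx), replace = TRUE, prob = P[i, ])
      }
    } else {
      adj <- lapply(seq_len(k), function(j)
        neighbor_count(grid$codes == j & !nd))
      for (i in seq_len(k)) {
        idx <- which(grid$codes == i & !nd)
        if (!length(idx)) next
        n_ij <- as.vector(stats::rmultinom(1, length(idx), P[i, ]))
        remaining <- idx
        for (j in sample(seq_len(k))) {    # random destination order
          if (n_ij[j] == 0L || !length(remaining)) next
          wgt <- 1 + clustering * adj[[j]][remaining]
          take <- if (length(remaining) == 1L) remaining
                  else remaining[sample.int(length(remaining), min(n_ij[j], length(remaining)),
                                            prob = wgt)]
          out[take] <- j
          remaining <- setdiff(remaining, take)
        }
        if (length(remaining)) out[remaining] <- i
      }
    }
  })
  out[nd] <- grid$geometry$nodata_code
  categorical_grid(out, grid$geometry, level = "aggregate")
}

# number of TRUE cells among the 8 neighbors of every cell
neighbor_count <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  correlate_kernel(m, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3))
}

#' Generate a multi-date landscape series
#'
#' An initial landscape is generated from `params`, then evolved
#' `n_periods - 1` times under `model` with stage seeds derived
#' deterministically from `params$seed`.
#'
#' @param params A `landscape_params`.
#' @param model A `transition_model`.
#' @param n_periods Number of dates (>= 1).
#' @param clustering Passed to [evolve()].
#' @return List of aggregate-coded `categorical_grid`s.
#' @export
generate_series <- function(params, model, n_periods, clustering = 0) {
  grids <- vector("list", n_periods)
  grids[[1]] <- generate_initial(params)
  if (n_periods > 1) for (t in 2:n_periods)
    grids[[t]] <- evolve(grids[[t - 1]], model,
                         seed = (params$seed + 1000L * t) %% .Machine$integer.max,
                         clustering = clustering)
  grids
}

#' Split an aggregate landscape into detailed land-use codes
#'
#' Each aggregate class's cells are assigned detailed codes from the class
#' scheme, sampled with the given sub-proportions (uniform by default), so
#' that threat-source placement and per-code suitability lookups can be
#' exercised on synthetic data.
#'
#' @param grid Aggregate-coded `categorical_grid`.
#' @param scheme A `class_scheme`.
#' @param seed Integer seed.
#' @param sub_props Optional named list mapping an aggregate class to a
#'   probability vector over its detailed codes (in scheme order).
#' @return A detailed `categorical_grid`.
#' @export
expand_to_detailed <- function(grid, scheme = class_scheme(), seed = 1L,
                               sub_props = NULL) {
  if (grid$level != "aggregate") stop("expects an aggregate-coded grid")
  nd <- is_nodata(grid)
  out <- grid$codes
  with_seed(seed, {
    for (i in seq_along(aggregate_classes())) {
      agg <- aggregate_classes()[i]
      codes <- scheme$code[scheme$aggregate == agg]
      idx <- which(grid$codes == i & !nd)
      if (!length(idx)) next
      p <- sub_props[[agg]]
      if (is.null(p)) p <- rep(1 / length(codes), length(codes))
      out[idx] <- codes[sample.int(length(codes), length(idx),
                                   replace = TRUE, prob = p)]
    }
  })
  out[nd] <- grid$geometry$nodata_code
  categorical_grid(out, grid$geometry, level = "detailed")
}
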