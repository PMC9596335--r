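# Threat-based habitat degradation and quality model.
#
# Degradation of cell x with land-use class j:
#   D_x = sum_r (w_r / sum w) * [ sum_y r_y * i_r(d_xy) ] * beta_x * S_jr
# where r_y is binary threat presence, i_r a linear or exponential
# distance-decay kernel truncated at the threat's maximum effective
# distance, beta_x accessibility in [0,1] (default 1) and S_jr the
# sensitivity of class j to threat r.
#
# Quality applies a half-saturation transform to degradation:
#   Q_x = H_j * (1 - D_x^z / (D_x^z + k^z))
# so Q = H at D = 0 and Q = H/2 at D = k.

#' Specify one threat (stress factor)
#'
#' @param name Threat identifier.
#' @param source_codes Integer land-use codes whose cells emit this threat.
#' @param max_dist_km Maximum effective distance d_rmax in km (> 0); impact
#'   is zero beyond it.
#' @param weight Raw weight in (0, 1]; weights are normalized across the
#'   threat set before use.
#' @param decay `"linear"` or `"exponential"`.
#' @return A `threat_spec` object.
#' @export
threat_spec <- function(name, source_codes, max_dist_km, weight,
                        decay = c("exponential", "linear")) {
  decay <- match.arg(decay)
  if (!is.finite(max_dist_km) || max_dist_km <= 0) stop("max_dist_km must be > 0")
  if (!is.finite(weight) || weight <= 0) stop("threat weight must be > 0")
  structure(list(name = name, source_codes = as.integer(source_codes),
                 max_dist_km = max_dist_km, weight = weight, decay = decay),
            class = "threat_spec")
}

#' Bundle threats and normalize their weights
#'
#' @param threats List of `threat_spec` objects.
#' @return A `threat_set` with element `normalized_weights` summing to 1.
#' @export
threat_set <- function(threats) {
  if (inherits(threats, "threat_spec")) threats <- list(threats)
  stopifnot(length(threats) > 0,
            all(vapply(threats, inherits, logical(1), "threat_spec")))
  w <- vapply(threats, `[[`, numeric(1), "weight")
  nms <- vapply(threats, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate threat names")
  names(threats) <- nms
  structure(list(threats = threats, normalized_weights = w / sum(w)),
            class = "threat_set")
}

#' Read a threat table from CSV
#'
#' Columns: `name`, `source_codes` (codes separated by `;` or spaces),
#' `max_dist_km`, `weight`, `decay`.
#'
#' @param path CSV path; defaults to the shipped parameterization of the
#'   five stress factors of the study (arable land, reservoir, urban land,
#'   rural settlements, other construction land).
#' @return A `threat_set`.
#' @export
read_threats <- function(path = system.file("extdata", "threats.csv",
                                            package = "habiq", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  threat_set(lapply(seq_len(nrow(df)), function(i) {
    codes <- as.integer(strsplit(as.character(df$source_codes[i]), "[;[:space:]]+")[[1]])
    threat_spec(df$name[i], codes, df$max_dist_km[i], df$weight[i], df$decay[i])
  }))
}

#' Read a habitat-suitability / sensitivity table from CSV
#'
#' One row per land-use code with its habitat suitability `habitat`
#' (H in [0,1]) and one sensitivity column per threat (S in [0,1]).
#'
#' @param path CSV path; defaults to the shipped table for the 14 detailed
#'   land-use codes.
#' @return A `sensitivity_table` data.frame.
#' @export
read_sensitivity <- function(path = system.file("extdata", "sensitivity.csv",
                                                package = "habiq", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sensitivity_table(df)
}

#' Construct/validate a sensitivity table
#'
#' @param df Data frame with columns `code`, `habitat` and one column per
#'   threat name.
#' @return A `sensitivity_table`.
#' @export
sensitivity_table <- function(df) {
  stopifnot(all(c("code", "habitat") %in% names(df)))
  sens_cols <- setdiff(names(df), c("code", "habitat"))
  vals <- as.matrix(df[, c("habitat", sens_cols)])
  if (any(vals < 0 | vals > 1)) stop("habitat and sensitivity values must lie in [0,1]")
  if (anyDuplicated(df$code)) stop("duplicate codes in sensitivity table")
  df$code <- as.integer(df$code)
  class(df) <- c("sensitivity_table", "data.frame")
  df
}

#' Model parameters for the half-saturation transform
#'
#' @param k Half-saturation constant (> 0): the degradation level at which
#'   quality drops to half the suitability.
#' @param z Exponent of the transform (> 0).
#' @param k_mode `"fixed"` uses `k` as given; `"half_of_max_D"` sets k to
#'   half the maximum computed degradation before applying the transform.
#' @return A `model_params` object.
#' @export
model_params <- function(k = 0.5, z = 2.5,
                         k_mode = c("fixed", "half_of_max_D")) {
  k_mode <- match.arg(k_mode)
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  if (!is.finite(z) || z <= 0) stop("z must be > 0")
  structure(list(k = k, z = z, k_mode = k_mode), class = "model_params")
}

#' Binary presence grid of one threat's source cells
#'
#' @param landuse Detailed `categorical_grid`.
#' @param threat A `threat_spec`.
#' @return Numeric matrix with 1 on cells whose code is in
#'   `threat$source_codes`, 0 elsewhere (nodata cells are 0: they emit no
#'   threat).
#' @export
threat_presence <- function(landuse, threat) {
  p <- matrix(0, landuse$geometry$n_rows, landuse$geometry$n_cols)
  p[landuse$codes %in% threat$source_codes & !is_nodata(landuse)] <- 1
  p
}

#' Distance-decay impact of a threat
#'
#' Linear: `1 - d/d_rmax`; exponential: `exp(-(2.99/d_rmax) * d)`. Both are
#' truncated to 0 beyond the maximum effective distance `d_rmax` (at exactly
#' `d_rmax` the formula value applies: 0 for linear, `exp(-2.99)` for
#' exponential).
#'
#' @param d_km Distance(s) in km, >= 0.
#' @param threat A `threat_spec`.
#' @return Impact value(s) in [0, 1].
#' @export
decay_weight <- function(d_km, threat) {
  if (any(d_km < 0)) stop("distances must be >= 0")
  i <- switch(threat$decay,
              linear = 1 - d_km / threat$max_dist_km,
              exponential = exp(-(2.99 / threat$max_dist_km) * d_km))
  i[d_km > threat$max_dist_km] <- 0
  pmax(i, 0)
}

#' Distance-decay stencil of a threat on the analysis grid
#'
#' Square odd-sided matrix of impacts at every cell-center offset within the
#' threat's maximum effective distance; the center entry (zero distance)
#' is 1.
#'
#' @param threat A `threat_spec`.
#' @param cell_size Cell side in km.
#' @return Numeric matrix of side `2*ceiling(d_rmax/cell_size) + 1`.
#' @export
build_kernel <- function(threat, cell_size) {
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  r <- ceiling(threat$max_dist_km / cell_size)
  off <- (-r):r
  d <- cell_size * sqrt(outer(off^2, off^2, "+"))
  matrix(decay_weight(as.vector(d), threat), nrow = length(off))
}

# 2-D correlation of a presence grid with a kernel, zero-padded: sources
# outside the raster are assumed absent (edge cells see fewer potential
# sources). acc[x] = sum_y presence[y] * kernel[y - x].
correlate_kernel <- function(presence, kernel) {
  nr <- nrow(presence); nc <- ncol(presence)
  r <- (nrow(kernel) - 1L) / 2L
  acc <- matrix(0, nr, nc)
  for (dr in (-r):r) {
    rx <- max(1L, 1L - dr):min(nr, nr - dr)
    if (length(rx) == 0L || rx[1] > rx[length(rx)]) next
    for (dc in (-r):r) {
      w <- kernel[dr + r + 1L, dc + r + 1L]
      if (w <= 0) next
      cx <- max(1L, 1L - dc):min(nc, nc - dc)
      if (cx[1] > cx[length(cx)]) next
      acc[rx, cx] <- acc[rx, cx] + w * presence[rx + dr, cx + dc]
    }
  }
  acc
}

#' Habitat degradation surface
#'
#' Computes per-cell total threat level: for each threat, source presence is
#' correlated with its distance-decay kernel, scaled by the normalized
#' threat weight, the cell's accessibility and the sensitivity of the cell's
#' land-use class to that threat, then summed over threats. Nodata land-use
#' cells emit no threat and receive no value.
#'
#' @param landuse Detailed `categorical_grid`.
#' @param threats A `threat_set`.
#' @param sens A `sensitivity_table` covering every code present.
#' @param access Optional `continuous_grid` (or matrix) of accessibility
#'   beta in [0,1]; defaults to 1 everywhere.
#' @return A `continuous_grid` of D >= 0 (NA on nodata cells).
#' @export
degradation <- function(landuse, threats, sens, access = NULL) {
  geom <- landuse$geometry
  nd <- is_nodata(landuse)
  codes_present <- unique(landuse$codes[!nd])
  missing <- setdiff(codes_present, sens$code)
  if (length(missing))
    stop("sensitivity table lacks code(s): ", paste(sort(missing), collapse = ", "))
  beta <- if (is.null(access)) {
    matrix(1, geom$n_rows, geom$n_cols)
  } else {
    b <- if (inherits(access, "continuous_grid")) {
      if (!same_geometry(access$geometry, geom)) stop("accessibility geometry mismatch")
      access$values
    } else access
    if (any(b < 0 | b > 1, na.rm = TRUE)) stop("accessibility must lie in [0,1]")
    b
  }
  row_idx <- match(landuse$codes, sens$code)
  D <- matrix(0, geom$n_rows, geom$n_cols)
  w <- threats$normalized_weights
  for (i in seq_along(threats$threats)) {
    th <- threats$threats[[i]]
    if (!th$name %in% names(sens))
      stop("sensitivity table has no column for threat '", th$name, "'")
    s_col <- sens[[th$name]]
    s_jr <- matrix(s_col[row_idx], geom$n_rows, geom$n_cols)
    s_jr[nd] <- 0
    if (all(s_jr == 0)) next  # threat cannot affect any cell present
    acc <- correlate_kernel(threat_presence(landuse, th),
                            build_kernel(th, geom$cell_size))
    D <- D + w[i] * acc * s_jr
  }
  D <- D * beta
  D[nd] <- NA_real_
  continuous_grid(D, geom)
}

#' Habitat quality surface
#'
#' Applies the half-saturation transform
#' `Q = H_j * (1 - D^z / (D^z + k^z))` to a degradation surface, with H_j
#' the suitability of each cell's land-use class. With
#' `k_mode = "half_of_max_D"`, k is set to half the maximum D over
#' non-nodata cells (if the surface is identically zero, Q = H).
#'
#' @param D `continuous_grid` of degradation (from [degradation()]).
#' @param landuse Detailed `categorical_grid` on the same geometry.
#' @param sens A `sensitivity_table` supplying H_j.
#' @param params A `model_params`.
#' @return A `continuous_grid` with values in `[0, H_j]`.
#' @export
quality <- function(D, landuse, sens, params = model_params()) {
  if (!same_geometry(D$geometry, landuse$geometry)) stop("geometry mismatch")
  nd <- is_nodata(landuse)
  H <- matrix(sens$habitat[match(landuse$codes, sens$code)],
              landuse$geometry$n_rows, landuse$geometry$n_cols)
  d <- D$values
  k <- params$k
  if (params$k_mode == "half_of_max_D") {
    dmax <- suppressWarnings(max(d, na.rm = TRUE))
    k <- if (is.finite(dmax) && dmax > 0) dmax / 2 else NA_real_
  }
  if (is.na(k)) {
    q <- H  # degenerate: no degradation anywhere
  } else {
    dz <- d^params$z
    q <- H * (1 - dz / (dz + k^params$z))
  }
  q[nd] <- NA_real_
  continuous_grid(q, landuse$geometry)
}

#' Run the full habitat model on one land-use map
#'
#' Convenience orchestration: degradation, quality and zonal summaries over
#' the full extent plus any named masks.
#'
#' @param landuse Detailed `categorical_grid`.
#' @param threats A `threat_set` (default: shipped study parameterization).
#' @param sens A `sensitivity_table` (default: shipped table).
#' @param params A `model_params`.
#' @param access Optional accessibility grid.
#' @param masks Optional named list of logical matrices.
#' @return List with `degradation`, `quality` (continuous grids) and
#'   `summary` (data.frame of zonal statistics for both surfaces).
#' @export
run_model <- function(landuse, threats = read_threats(),
                      sens = read_sensitivity(), params = model_params(),
                      access = NULL, masks = NULL) {
  D <- degradation(landuse, threats, sens, access)
  Q <- quality(D, landuse, sens, params)
  sq <- zonal_stats(Q, masks)
  sd_ <- zonal_stats(D, masks)
  sq$surface <- "quality"; sd_$surface <- "degradation"
  list(degradation = D, quality = Q,
       summary = rbind(sq, sd_)[, c("surface", setdiff(names(sq), "surface"))])
}

#' Min-max rescale a continuous surface to [0, 1]
#'
#' Optional normalization of degradation surfaces for cross-study
#' comparison; constant surfaces map to 0.
#'
#' @param grid A `continuous_grid`.
#' @return A `continuous_grid` on [0, 1].
#' @export
rescale01 <- function(grid) {
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  out <- if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
  continuous_grid(out, grid$geometry)
}
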