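# Banding of quality surfaces and zonal summary statistics.
#
# Default bands follow the study's printed thresholds: poor [0, 0.2),
# medium [0.2, 0.5), good [0.5, 0.7), high [0.7, 1]. Natural-breaks (Fisher-
# Jenks) thresholds are available as an alternative; both feed the same
# half-open upward-inclusive binning (a value exactly on a threshold joins
# the upper band).

#' Quality band labels
#' @return Character vector `c("poor","medium","good","high")`.
#' @export
quality_bands <- function() c("poor", "medium", "good", "high")

#' Default fixed quality thresholds
#' @return Numeric vector `c(0.2, 0.5, 0.7)`.
#' @export
default_breaks <- function() c(0.2, 0.5, 0.7)

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D partition of a sample into `n_classes` contiguous classes
#' minimizing the total within-class sum of squared deviations, computed by
#' dynamic programming over the sorted sample (Fisher's algorithm, exact).
#' The returned thresholds are the smallest value of each upper class, so
#' that half-open upward-inclusive binning reproduces the optimal partition.
#'
#' @param values Finite numeric sample (length >= `n_classes` distinct
#'   values required).
#' @param n_classes Number of classes (>= 2).
#' @param sample_max For samples larger than this, the DP runs on a
#'   deterministic systematic subsample of the sorted values (the algorithm
#'   is O(n_classes * n^2)); set to `Inf` to force the exact solution.
#' @return List with `breaks` (interior thresholds, length `n_classes - 1`)
#'   and `cost` (the minimized within-class sum of squares, on the sample
#'   actually used).
#' @export
jenks_breaks <- function(values, n_classes = 4, sample_max = 5000) {
  values <- values[is.finite(values)]
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(values) < n_classes) stop("sample smaller than n_classes")
  if (length(unique(values)) < n_classes)
    stop("too few distinct values for ", n_classes, " classes")
  x <- sort(values)
  n <- length(x)
  if (n > sample_max) {
    keep <- unique(round(seq(1, n, length.out = sample_max)))
    x <- x[keep]
    n <- length(x)
  }
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # sse of x[i..j], vectorized over i for fixed j
  sse_to <- function(i, j) {
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  cost <- matrix(Inf, n_classes, n)     # cost[m, j]: best split of x[1..j] into m classes
  split_at <- matrix(NA_integer_, n_classes, n)
  cost[1, ] <- sse_to(rep(1L, n), seq_len(n))
  for (m in 2:n_classes) {
    for (j in m:n) {
      i <- m:j                           # first index of the last class
      tot <- cost[m - 1, i - 1] + sse_to(i, j)
      best <- which.min(tot)
      cost[m, j] <- tot[best]
      split_at[m, j] <- i[best]
    }
  }
  # backtrack the first index of each class
  starts <- integer(n_classes)
  j <- n
  for (m in n_classes:2) {
    starts[m] <- split_at[m, j]
    j <- starts[m] - 1L
  }
  starts[1] <- 1L
  list(breaks = x[starts[-1]], cost = cost[n_classes, n])
}

#' Classify a continuous surface into bands
#'
#' Half-open upward-inclusive binning: with thresholds (t1, t2, t3) the
#' bands are [0, t1), [t1, t2), [t2, t3), [t3, 1]. Nodata (NA) cells are
#' preserved as nodata.
#'
#' @param surface `continuous_grid` with values in [0, 1].
#' @param breaks Strictly increasing interior thresholds in (0, 1); default
#'   the study's printed bands [default_breaks()].
#' @return A `categorical_grid` with codes 1..length(breaks)+1 and a
#'   `"bands"` attribute of labels.
#' @export
classify_quality <- function(surface, breaks = default_breaks()) {
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0 | breaks >= 1))
    stop("breaks must be strictly increasing and inside (0, 1)")
  v <- surface$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("surface values outside [0, 1] cannot be banded")
  cls <- findInterval(v, breaks) + 1L
  m <- matrix(cls, nrow(v), ncol(v))
  m[is.na(v)] <- surface$geometry$nodata_code
  out <- categorical_grid(m, surface$geometry, level = "aggregate")
  attr(out, "bands") <- if (length(breaks) == 3) quality_bands()
                        else paste0("band", seq_len(length(breaks) + 1))
  attr(out, "breaks") <- breaks
  out
}

#' Rectangular/named region masks
#'
#' @param geometry A `grid_geometry`.
#' @param regions Named list; each element is `c(row_min, row_max, col_min,
#'   col_max)` (1-based, inclusive).
#' @return Named list of logical matrices.
#' @export
make_masks <- function(geometry, regions) {
  stopifnot(length(regions) > 0, !is.null(names(regions)))
  lapply(regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 4) stop("a region is c(row_min, row_max, col_min, col_max)")
    if (r[1] > r[2] || r[3] > r[4]) stop("empty region (min exceeds max)")
    if (r[1] < 1 || r[3] < 1 || r[2] > geometry$n_rows || r[4] > geometry$n_cols)
      stop("region out of grid bounds")
    m <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
    m[r[1]:r[2], r[3]:r[4]] <- TRUE
    m
  })
}

#' Zonal summary statistics of a surface
#'
#' Minimum, maximum, average and standard deviation over the non-nodata
#' cells of each mask (plus the full extent). The standard deviation uses
#' the population convention (divide by N) by default, matching common GIS
#' zonal tools.
#'
#' @param surface A `continuous_grid`.
#' @param masks Optional named list of logical matrices; the full extent is
#'   always reported as zone `"all"`.
#' @param sd_type `"population"` or `"sample"`.
#' @return Data frame with columns `zone`, `n_cells`, `minimum`, `maximum`,
#'   `average`, `std_dev`. Empty zones give an NA row with a warning.
#' @export
zonal_stats <- function(surface, masks = NULL,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  zones <- c(list(all = matrix(TRUE, nrow(surface$values), ncol(surface$values))),
             masks)
  rows <- lapply(names(zones), function(nm) {
    mk <- zones[[nm]]
    if (!all(dim(mk) == dim(surface$values))) stop("mask geometry mismatch: ", nm)
    v <- surface$values[mk]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      warning("zone '", nm, "' contains no valid cells")
      return(data.frame(zone = nm, n_cells = 0L, minimum = NA_real_,
                        maximum = NA_real_, average = NA_real_,
                        std_dev = NA_real_))
    }
    s <- if (n == 1L) 0 else stats::sd(v) * if (sd_type == "population")
      sqrt((n - 1) / n) else 1
    data.frame(zone = nm, n_cells = n, minimum = min(v), maximum = max(v),
               average = mean(v), std_dev = s)
  })
  do.call(rbind, rows)
}
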