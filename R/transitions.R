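# Land-use change accounting: cross-tabulation of aggregate-class rasters
# into area transfer matrices (hm2) and the inflow/outflow share statistics
# derived from them. Areas are kept in hm2 internally; km2 only appears in
# presentation columns (1 km2 = 100 hm2).

#' Construct a transfer matrix
#'
#' @param areas 6x6 numeric matrix of areas in hm2; entry `[i, j]` is the
#'   area changing from class `i` at the first date to class `j` at the
#'   second.
#' @param period Length-2 character vector of date labels, e.g.
#'   `c("1995", "2020")`.
#' @param labels Class labels (defaults to [aggregate_classes()]).
#' @return A `transfer_matrix` object.
#' @export
transfer_matrix <- function(areas, period = c("t0", "t1"),
                            labels = aggregate_classes()) {
  areas <- as.matrix(areas)
  if (nrow(areas) != length(labels) || ncol(areas) != length(labels))
    stop("areas must be a square matrix over the class labels")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("transfer matrix entries must be finite and >= 0")
  dimnames(areas) <- list(from = labels, to = labels)
  structure(list(areas = areas, labels = labels,
                 period = as.character(period)),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix %s -> %s (hm2), total %s\n",
              x$period[1], x$period[2],
              format(sum(x$areas), big.mark = ",")))
  print(round(x$areas, 1))
  invisible(x)
}

#' Cross-tabulate two aggregate-class grids into a transfer matrix
#'
#' Counts the joint class membership of every cell that is non-nodata at
#' both dates (and inside `mask`, if given) and converts counts to areas in
#' hm2 using the shared cell size. Cells nodata at either date are excluded
#' entirely, so the matrix marginals are the class areas over the common
#' valid extent.
#'
#' @param grid_t0,grid_t1 Aggregate-coded `categorical_grid`s on identical
#'   geometries.
#' @param mask Optional logical matrix restricting the tabulation.
#' @param period Date labels for the pair.
#' @return A `transfer_matrix`.
#' @export
cross_tabulate <- function(grid_t0, grid_t1, mask = NULL,
                           period = c("t0", "t1")) {
  if (!same_geometry(grid_t0$geometry, grid_t1$geometry))
    stop("grids have different geometries")
  if (grid_t0$level != "aggregate" || grid_t1$level != "aggregate")
    stop("cross_tabulate expects aggregate-coded grids; run reclassify() first")
  keep <- !is_nodata(grid_t0) & !is_nodata(grid_t1)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(keep))) stop("mask does not match grid geometry")
    keep <- keep & mask
  }
  if (!any(keep)) stop("no overlapping valid cells to tabulate")
  k <- length(aggregate_classes())
  counts <- table(factor(grid_t0$codes[keep], levels = seq_len(k)),
                  factor(grid_t1$codes[keep], levels = seq_len(k)))
  transfer_matrix(unclass(counts) * cell_area_hm2(grid_t0$geometry),
                  period = period)
}

#' Inflow/outflow accounting for a transfer matrix
#'
#' For each class: inflow = column total minus the diagonal (area gained),
#' outflow = row total minus the diagonal (area lost). For each ordered pair
#' of distinct classes the entry is also expressed as a percentage of the
#' destination's inflow (`share_of_inflow`) and of the source's outflow
#' (`share_of_outflow`). Shares are undefined (NA), not zero, when the
#' corresponding inflow/outflow is zero; diagonals are NA.
#'
#' @param tm A `transfer_matrix`.
#' @return A `flow_stats` list with elements `classes` (data.frame of areas,
#'   inflow, outflow in hm2), `share_of_inflow` and `share_of_outflow`
#'   (matrices in percent).
#' @export
flow_shares <- function(tm) {
  a <- tm$areas
  if (any(a < 0)) stop("transfer matrix has negative entries")
  d <- diag(a)
  inflow <- colSums(a) - d
  outflow <- rowSums(a) - d
  share_in <- sweep(a, 2L, inflow, "/") * 100
  share_out <- sweep(a, 1L, outflow, "/") * 100
  share_in[, inflow == 0] <- NA_real_
  share_out[outflow == 0, ] <- NA_real_
  diag(share_in) <- NA_real_
  diag(share_out) <- NA_real_
  classes <- data.frame(
    class = tm$labels,
    area_t0_hm2 = rowSums(a),
    area_t1_hm2 = colSums(a),
    inflow_hm2 = inflow,
    outflow_hm2 = outflow,
    row.names = NULL
  )
  structure(list(classes = classes, share_of_inflow = share_in,
                 share_of_outflow = share_out, period = tm$period),
            class = "flow_stats")
}

#' @export
print.flow_stats <- function(x, ...) {
  cat(sprintf("flow_stats %s -> %s\n", x$period[1], x$period[2]))
  print(x$classes)
  cat("share of destination inflow (%):\n")
  print(round(x$share_of_inflow, 2))
  invisible(x)
}

#' Per-date class areas from a series of transfer matrices
#'
#' Each matrix contributes its row marginal at the first date of its period;
#' the final matrix also contributes its column marginal at the last date.
#' Areas are reported in hm2 and km2.
#'
#' @param tms List of `transfer_matrix` objects with consistent labels,
#'   ordered in time.
#' @return Data frame with columns `date`, `class`, `area_hm2`, `area_km2`.
#'   A warning reports any disagreement in grand totals across periods.
#' @export
area_series <- function(tms) {
  if (inherits(tms, "transfer_matrix")) tms <- list(tms)
  labels <- tms[[1]]$labels
  for (tm in tms)
    if (!identical(tm$labels, labels)) stop("inconsistent class labels across matrices")
  totals <- vapply(tms, function(tm) sum(tm$areas), numeric(1))
  if (diff(range(totals)) > 0)
    warning(sprintf("grand totals differ across periods by up to %.6g hm2",
                    diff(range(totals))))
  rows <- lapply(tms, function(tm)
    data.frame(date = tm$period[1], class = labels,
               area_hm2 = unname(rowSums(tm$areas))))
  last <- tms[[length(tms)]]
  rows <- c(rows, list(
    data.frame(date = last$period[2], class = labels,
               area_hm2 = unname(colSums(last$areas)))))
  out <- do.call(rbind, rows)
  out$area_km2 <- out$area_hm2 * 0.01
  out
}

#' Absolute and percent change of class areas between two dates
#'
#' @param series Output of [area_series()].
#' @param from,to Date labels present in `series`.
#' @return Data frame with change in hm2, km2 and percent (relative to the
#'   `from` area; NA when the `from` area is zero).
#' @export
area_change <- function(series, from, to) {
  a0 <- series[series$date == from, c("class", "area_hm2")]
  a1 <- series[series$date == to, c("class", "area_hm2")]
  if (!nrow(a0) || !nrow(a1)) stop("date label not present in series")
  m <- merge(a0, a1, by = "class", suffixes = c("_from", "_to"), sort = FALSE)
  m$change_hm2 <- m$area_hm2_to - m$area_hm2_from
  m$change_km2 <- m$change_hm2 * 0.01
  m$change_pct <- ifelse(m$area_hm2_from > 0,
                         100 * m$change_hm2 / m$area_hm2_from, NA_real_)
  m
}

#' Round half away from zero
#'
#' Presentation rounding for percentages (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ---- CSV IO and the printed-table fixture -----------------------------------

#' Write a transfer matrix as CSV
#' @param tm A `transfer_matrix`.
#' @param path Output path.
#' @param totals Append a Total row and column.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(tm, path, totals = TRUE) {
  a <- tm$areas
  df <- data.frame(from = rownames(a), a, check.names = FALSE)
  if (totals) {
    df <- rbind(df, data.frame(from = "Total", t(colSums(a)), check.names = FALSE))
    df$Total <- c(rowSums(a), sum(a))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a transfer matrix from CSV
#'
#' Expects a `from` column plus one column per class; optional Total
#' row/column are dropped.
#'
#' @param path CSV path.
#' @param period Date labels.
#' @return A `transfer_matrix`.
#' @export
read_transfer_csv <- function(path, period = c("t0", "t1")) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[tolower(df[[1]]) != "total", , drop = FALSE]
  labels <- df[[1]]
  a <- as.matrix(df[, setdiff(names(df), c(names(df)[1], "Total")), drop = FALSE])
  rownames(a) <- labels
  transfer_matrix(a[, labels, drop = FALSE], period = period, labels = labels)
}

#' Published land-use transfer matrices for the study area
#'
#' The five printed inter-date transfer matrices (hm2) for the crocodile
#' lizard study region, transcribed verbatim from the published table
#' (including its small internal rounding inconsistencies). Periods:
#' 1995-2000, 2000-2010, 2010-2015, 2015-2020 and the summary 1995-2020.
#'
#' @param period Length-2 character vector choosing the block, e.g.
#'   `c("1995", "2020")`.
#' @return A `transfer_matrix`.
#' @export
landuse_transfer_fixture <- function(period = c("1995", "2020")) {
  path <- system.file("extdata", "landuse_transfer_matrix.csv",
                      package = "habiq", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  blk <- df[df$t0 == period[1] & df$t1 == period[2], , drop = FALSE]
  if (!nrow(blk)) stop("no fixture block for period ", period[1], "-", period[2])
  labels <- aggregate_classes()
  a <- as.matrix(blk[match(labels, blk$from), labels])
  rownames(a) <- labels
  transfer_matrix(a, period = period)
}
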