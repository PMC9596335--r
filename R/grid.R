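# Grid conventions used throughout the package:
#  * row-major matrices, origin at the top-left corner, row index increasing
#    southward;
#  * cell_size and origin coordinates are in km; one 1x1 km cell = 100 hm2;
#  * distances between cells are Euclidean distances between cell CENTERS;
#  * nodata cells carry the integer sentinel `nodata_code` (categorical) or
#    NA (continuous) and are excluded from every statistic.

#' Aggregate land-use classes
#'
#' The six aggregate land-cover classes used by the transfer-matrix and
#' simulation modules, in their canonical order. Aggregate-coded grids store
#' the position in this vector (1 = arable, ..., 6 = unused).
#'
#' @return Character vector of the six class labels.
#' @export
aggregate_classes <- function() {
  c("arable", "woodland", "grassland", "water", "construction", "unused")
}

#' Grid geometry
#'
#' Describes the regular lattice shared by all raster layers of an analysis:
#' dimensions, cell size (km), the coordinate of the top-left corner (km) and
#' the integer nodata sentinel used by categorical layers.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Side length of a square cell in km.
#' @param origin_x,origin_y Coordinates of the top-left corner in km.
#'   `origin_y` defaults to `n_rows * cell_size` so that the lower-left
#'   corner sits at y = 0.
#' @param nodata_code Integer sentinel marking cells outside the study area.
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 1,
                          origin_x = 0, origin_y = NULL,
                          nodata_code = -9999L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one row and column")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y,
         nodata_code = as.integer(nodata_code)),
    class = "grid_geometry"
  )
}

#' Area of one grid cell in hm2
#'
#' 1 km2 = 100 hm2 (hectares), so a cell of side `cell_size` km covers
#' `cell_size^2 * 100` hm2.
#'
#' @param geometry A `grid_geometry`.
#' @return Cell area in hm2.
#' @export
cell_area_hm2 <- function(geometry) geometry$cell_size^2 * 100

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "cell_size")],
                   unclass(b)[c("n_rows", "n_cols", "cell_size")]))
}

#' Categorical (integer-coded) raster
#'
#' @param codes Integer matrix of land-use codes (`n_rows x n_cols`); cells
#'   equal to the geometry's `nodata_code` are treated as outside the study
#'   area.
#' @param geometry A `grid_geometry` matching the matrix dimensions.
#' @param level Either `"detailed"` (14-code scheme) or `"aggregate"`
#'   (six-class codes 1..6).
#' @return A `categorical_grid` object.
#' @export
categorical_grid <- function(codes, geometry, level = c("detailed", "aggregate")) {
  level <- match.arg(level)
  codes <- as.matrix(codes)
  if (!all(dim(codes) == c(geometry$n_rows, geometry$n_cols)))
    stop("codes matrix does not match geometry (",
         geometry$n_rows, "x", geometry$n_cols, ")")
  if (any(!is.finite(codes)))
    stop("categorical grid contains non-finite codes; use the nodata sentinel")
  if (any(codes != round(codes)))
    stop("categorical grid contains non-integer codes")
  storage.mode(codes) <- "integer"
  structure(list(geometry = geometry, codes = codes, level = level),
            class = "categorical_grid")
}

#' Continuous raster
#'
#' @param values Numeric matrix; NA marks nodata cells.
#' @param geometry A `grid_geometry` matching the matrix dimensions.
#' @return A `continuous_grid` object.
#' @export
continuous_grid <- function(values, geometry) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(geometry$n_rows, geometry$n_cols)))
    stop("values matrix does not match geometry")
  if (any(is.infinite(values)))
    stop("continuous grid contains non-finite (infinite) values")
  storage.mode(values) <- "double"
  structure(list(geometry = geometry, values = values),
            class = "continuous_grid")
}

#' Logical mask of nodata cells
#' @param grid A `categorical_grid` or `continuous_grid`.
#' @return Logical matrix, TRUE where the cell is nodata.
#' @export
is_nodata <- function(grid) {
  if (inherits(grid, "categorical_grid"))
    grid$codes == grid$geometry$nodata_code
  else
    is.na(grid$values)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d rows x %d cols, cell %.3g km (%.4g hm2/cell), nodata %d\n",
              x$n_rows, x$n_cols, x$cell_size, cell_area_hm2(x), x$nodata_code))
  invisible(x)
}

#' @export
print.categorical_grid <- function(x, ...) {
  nd <- sum(is_nodata(x))
  cat(sprintf("categorical_grid (%s): %d x %d cells, %d nodata\n",
              x$level, x$geometry$n_rows, x$geometry$n_cols, nd))
  tab <- table(x$codes[!is_nodata(x)])
  if (length(tab)) print(tab)
  invisible(x)
}

#' @export
print.continuous_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("continuous_grid: %d x %d cells, %d nodata",
              x$geometry$n_rows, x$geometry$n_cols, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("; range [%.4g, %.4g], mean %.4g", min(v), max(v), mean(v)))
  cat("\n")
  invisible(x)
}

# ---- ESRI ASCII grid IO -----------------------------------------------------
# Header coordinates/cellsize are in metres (the format's usual map unit for
# projected 1-km land-cover products); they are converted to km on read and
# back to metres on write.

parse_ascii_header <- function(lines) {
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2L])))) break
    key <- tolower(parts[1L])
    if (!key %in% keys) break
    hdr[[key]] <- as.numeric(parts[2L])
    i <- i + 1L
    if (i >= 6L) break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]]))
      stop("malformed ESRI ASCII header: missing '", req, "'")
  hdr$n_header_lines <- i
  hdr
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header (coordinates in metres) followed by row-major cell values, top row
#' first.
#'
#' @param path Path to an `.asc` file.
#' @param type `"categorical"` (integer codes required), `"continuous"`, or
#'   `"auto"` (categorical iff all non-nodata values are integral).
#' @param level Passed to [categorical_grid()] when categorical.
#' @return A `categorical_grid` or `continuous_grid`.
#' @export
read_ascii_grid <- function(path, type = c("auto", "categorical", "continuous"),
                            level = "detailed") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_ascii_header(lines)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[-seq_len(hdr$n_header_lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("malformed ESRI ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " cells, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  geom <- grid_geometry(hdr$nrows, hdr$ncols,
                        cell_size = hdr$cellsize / 1000,
                        origin_x = hdr$xllcorner / 1000,
                        origin_y = hdr$yllcorner / 1000 + hdr$nrows * hdr$cellsize / 1000,
                        nodata_code = as.integer(round(nodata)))
  live <- m != nodata
  if (type == "auto")
    type <- if (all(m[live] == round(m[live]))) "categorical" else "continuous"
  if (type == "categorical") {
    if (any(m[live] != round(m[live])))
      stop("non-integer cell values in a grid requested as categorical")
    categorical_grid(m, geom, level = level)
  } else {
    m[!live] <- NA_real_
    continuous_grid(m, geom)
  }
}

#' Write a grid as an ESRI ASCII file
#'
#' Inverse of [read_ascii_grid()]; integer codes round-trip bit-exactly.
#'
#' @param grid A `categorical_grid` or `continuous_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  g <- grid$geometry
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x * 1000),
    sprintf("yllcorner %.10g", (g$origin_y - g$n_rows * g$cell_size) * 1000),
    sprintf("cellsize %.10g", g$cell_size * 1000),
    sprintf("NODATA_value %d", g$nodata_code)
  )
  m <- if (inherits(grid, "categorical_grid")) grid$codes else grid$values
  if (inherits(grid, "continuous_grid")) m[is.na(m)] <- g$nodata_code
  body <- apply(m, 1L, function(row) paste(format(row, trim = TRUE, scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- class scheme -----------------------------------------------------------

#' Land-use classification scheme
#'
#' Maps the 14 detailed land-use codes of the Chinese land-cover monitoring
#' classification to names and to the six aggregate classes used in change
#' accounting: arable (1), woodland (21--24), grassland (3), water (41--46),
#' construction (51--53) and unused (6).
#'
#' @param df Optional data.frame with columns `code`, `name`, `aggregate`
#'   overriding the built-in table.
#' @return A `class_scheme` data.frame with columns `code` (integer), `name`
#'   and `aggregate` (one of [aggregate_classes()]).
#' @export
class_scheme <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      code = c(1L, 3L, 6L, 21L, 22L, 23L, 24L, 41L, 43L, 45L, 46L, 51L, 52L, 53L),
      name = c("Arable land", "Grasslands", "Unused lands", "Woodlands",
               "Bush forests", "Sparse woodlands", "Other woodlands",
               "Canals", "Reservoir ponds", "Tidal flats", "Beaches",
               "Urban lands", "Rural settlements", "Construction land"),
      aggregate = c("arable", "grassland", "unused", rep("woodland", 4),
                    rep("water", 4), rep("construction", 3)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("code", "name", "aggregate") %in% names(df)))
  bad <- setdiff(df$aggregate, aggregate_classes())
  if (length(bad)) stop("unknown aggregate class(es): ", paste(bad, collapse = ", "))
  df$code <- as.integer(df$code)
  if (anyDuplicated(df$code)) stop("duplicate codes in class scheme")
  class(df) <- c("class_scheme", "data.frame")
  df
}

#' Read a class scheme from CSV (columns code,name,aggregate)
#' @param path CSV path.
#' @return A `class_scheme`.
#' @export
read_class_scheme <- function(path) {
  class_scheme(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate that all codes of a grid are covered by a scheme
#'
#' @param grid A detailed `categorical_grid`.
#' @param scheme A `class_scheme`.
#' @return `TRUE` invisibly; otherwise an error listing every offending code.
#' @export
validate_codes <- function(grid, scheme = class_scheme()) {
  codes <- unique(grid$codes[!is_nodata(grid)])
  bad <- sort(setdiff(codes, scheme$code))
  if (length(bad))
    stop("grid contains code(s) absent from the class scheme: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Reclassify a detailed grid onto the six aggregate classes
#'
#' Every non-nodata detailed code is replaced by the index (1..6) of its
#' aggregate class in [aggregate_classes()]; nodata cells are preserved, and
#' the number of non-nodata cells is conserved.
#'
#' @param grid A detailed `categorical_grid`.
#' @param scheme A `class_scheme` covering every code present.
#' @return An aggregate-coded `categorical_grid`.
#' @export
reclassify <- function(grid, scheme = class_scheme()) {
  validate_codes(grid, scheme)
  agg_idx <- match(scheme$aggregate, aggregate_classes())
  nd <- is_nodata(grid)
  out <- matrix(grid$geometry$nodata_code,
                grid$geometry$n_rows, grid$geometry$n_cols)
  out[!nd] <- agg_idx[match(grid$codes[!nd], scheme$code)]
  categorical_grid(out, grid$geometry, level = "aggregate")
}
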