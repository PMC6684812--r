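#' Anthrome class raster
#'
#' A regular lat/lon grid of anthropogenic-biome (anthrome) class codes in
#' the layout of an ESRI ASCII grid: row 1 is the northernmost row and the
#' origin (`xllcorner`, `yllcorner`) is the lower-left corner.
#'
#' @param codes integer matrix (`nrows` x `ncols`) of class codes, row 1 =
#'   northernmost.
#' @param xllcorner,yllcorner lower-left corner, degrees.
#' @param cellsize cell size in degrees (> 0).
#' @param nodata integer code marking unclassified cells.
#' @param valid_codes integer vector of admissible class codes; defaults to
#'   the Anthromes v2 code set (see [default_anthrome_mapping()]).
#' @return An object of class `anthrome_grid`.
#' @export
anthrome_grid <- function(codes, xllcorner, yllcorner, cellsize,
                          nodata = -9999L,
                          valid_codes = anthrome_codes()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!is.finite(cellsize) || cellsize <= 0) stop("'cellsize' must be > 0")
  nrows <- nrow(codes); ncols <- ncol(codes)
  xur <- xllcorner + ncols * cellsize
  yur <- yllcorner + nrows * cellsize
  if (xllcorner < -180 - 1e-9 || xur > 180 + 1e-9 ||
      yllcorner < -90 - 1e-9 || yur > 90 + 1e-9)
    stop("grid bounds must lie within [-180, 180] x [-90, 90]")
  bad <- setdiff(unique(as.vector(codes)), c(valid_codes, nodata))
  if (length(bad) > 0)
    stop("invalid anthrome codes in grid: ",
         paste(sort(bad), collapse = ", "))
  structure(list(ncols = ncols, nrows = nrows,
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = as.integer(nodata),
                 codes = codes),
            class = "anthrome_grid")
}

#' @export
print.anthrome_grid <- function(x, ...) {
  cat(sprintf(paste0("<anthrome_grid> %d x %d cells of %g deg, ",
                     "origin (%g, %g), nodata %d\n"),
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner,
              x$nodata))
  invisible(x)
}

#' Anthromes v2 class codes and aggregate groups
#'
#' The default code-to-group mapping follows the Anthromes v2
#' classification: 11-12 Settlements, 21-24 Villages, 31-34 Croplands,
#' 41-43 Rangelands, 51-54 Seminatural, 61-63 Wildlands.
#'
#' @return `default_anthrome_mapping()`: a named character vector mapping
#'   code (as name) to group; `anthrome_codes()`: the integer codes;
#'   `anthrome_groups()`: the six group names in conventional order.
#' @export
default_anthrome_mapping <- function() {
  codes <- c(11, 12, 21, 22, 23, 24, 31, 32, 33, 34, 41, 42, 43,
             51, 52, 53, 54, 61, 62, 63)
  groups <- c(rep("Settlements", 2), rep("Villages", 4),
              rep("Croplands", 4), rep("Rangelands", 3),
              rep("Seminatural", 4), rep("Wildlands", 3))
  stats::setNames(groups, codes)
}

#' @rdname default_anthrome_mapping
#' @export
anthrome_codes <- function() {
  as.integer(names(default_anthrome_mapping()))
}

#' @rdname default_anthrome_mapping
#' @export
anthrome_groups <- function() {
  c("Settlements", "Villages", "Croplands", "Rangelands", "Seminatural",
    "Wildlands")
}

#' Build a toy anthrome grid from rectangular blocks
#'
#' Constructs a small raster in which rectangular blocks of cells carry
#' given anthrome codes; cells not covered by any block are nodata. Blocks
#' must not overlap.
#'
#' @param nrows,ncols grid dimensions.
#' @param class_layout list of blocks, each a list with elements `rows`
#'   (row indices, 1 = northernmost), `cols` (column indices) and `code`.
#' @param cellsize cell size in degrees.
#' @param xllcorner,yllcorner lower-left corner, degrees.
#' @param nodata nodata code.
#' @return An [anthrome_grid()].
#' @examples
#' g <- make_toy_anthrome_grid(2, 3, list(
#'   list(rows = 1:2, cols = 1:2, code = 31),
#'   list(rows = 1:2, cols = 3, code = 41)))
#' @export
make_toy_anthrome_grid <- function(nrows, ncols, class_layout,
                                   cellsize = 0.5,
                                   xllcorner = 0, yllcorner = 0,
                                   nodata = -9999L) {
  codes <- matrix(as.integer(nodata), nrows, ncols)
  covered <- matrix(FALSE, nrows, ncols)
  for (blk in class_layout) {
    if (!all(c("rows", "cols", "code") %in% names(blk)))
      stop("each block needs 'rows', 'cols' and 'code'")
    r <- blk$rows; c <- blk$cols
    if (any(r < 1 | r > nrows) || any(c < 1 | c > ncols))
      stop("block exceeds grid dimensions")
    if (any(covered[r, c]))
      stop("overlapping blocks in 'class_layout'")
    covered[r, c] <- TRUE
    codes[r, c] <- as.integer(blk$code)
  }
  anthrome_grid(codes, xllcorner, yllcorner, cellsize, nodata)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' `ncols` integers, northernmost row first.
#'
#' @param path file path.
#' @inheritParams anthrome_grid
#' @return An [anthrome_grid()].
#' @export
read_anthrome_grid <- function(path, valid_codes = anthrome_codes()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7) stop("not an ESRI ASCII grid: fewer than 7 lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed header at line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0)
    stop("missing header fields: ", paste(miss, collapse = ", "))
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  if (length(body) != nrows)
    stop("expected ", nrows, " data rows, found ", length(body))
  codes <- matrix(NA_integer_, nrows, ncols)
  for (r in seq_len(nrows)) {
    vals <- suppressWarnings(
      as.integer(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(vals) != ncols || anyNA(vals))
      stop("malformed data row ", r, " (line ", r + 6, "): expected ",
           ncols, " integers")
    codes[r, ] <- vals
  }
  anthrome_grid(codes, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                as.integer(hdr$nodata_value), valid_codes = valid_codes)
}

#' Write an ESRI ASCII grid
#'
#' @param grid an [anthrome_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_anthrome_grid <- function(grid, path) {
  stopifnot(inherits(grid, "anthrome_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xllcorner, scientific = FALSE)),
    paste("yllcorner", format(grid$yllcorner, scientific = FALSE)),
    paste("cellsize", format(grid$cellsize, scientific = FALSE)),
    paste("NODATA_value", grid$nodata)), con)
  writeLines(apply(grid$codes, 1, paste, collapse = " "), con)
  invisible(path)
}

# cell lookup by the half-open floor rule; returns row/col (1-based) or NA
grid_cell_of <- function(grid, lat, lon) {
  ytop <- grid$yllcorner + grid$nrows * grid$cellsize
  row <- floor((ytop - lat) / grid$cellsize) + 1
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1
  bad <- row < 1 | row > grid$nrows | col < 1 | col > grid$ncols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}
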