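## Canopy height model container, plain-text raster I/O, and the image
## operations (pit closing, smoothing, local maxima) feeding segmentation.

#' Canopy height model raster
#'
#' A light container for a single-band height raster: a numeric matrix with
#' row 1 at the northern (top) edge, a cell size in metres, and the (x, y)
#' of the lower-left corner. Cell `(r, c)` has its centre at
#' `x = xll + (c - 0.5) * cellsize`, `y = yll + (nrow - r + 0.5) * cellsize`.
#'
#' @param values numeric matrix of heights (m above ground, >= 0 or nodata).
#' @param cellsize cell edge length, m (> 0).
#' @param xll,yll lower-left corner coordinates, m.
#' @param nodata nodata marker (default -9999).
#' @return object of class `chm_raster`.
#' @export
chm_raster <- function(values, cellsize = 0.25, xll = 0, yll = 0,
                       nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (cellsize <= 0) stop("`cellsize` must be positive", call. = FALSE)
  if (any(values != nodata & values < 0, na.rm = TRUE))
    stop("heights must be >= 0 (or nodata)", call. = FALSE)
  structure(list(values = values, cellsize = cellsize,
                 xll = xll, yll = yll, nodata = nodata),
            class = "chm_raster")
}

#' @export
print.chm_raster <- function(x, ...) {
  cat(sprintf("<chm_raster> %d x %d cells at %.3g m (%.4g-%.4g m)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              min(x$values[x$values != x$nodata]),
              max(x$values[x$values != x$nodata])))
  invisible(x)
}

## world (x, y) -> (row, col); clamped to the raster
chm_cell_of <- function(chm, x, y) {
  nr <- nrow(chm$values)
  col <- pmin(ncol(chm$values), pmax(1L, floor((x - chm$xll) / chm$cellsize) + 1L))
  row <- pmin(nr, pmax(1L, nr - floor((y - chm$yll) / chm$cellsize)))
  cbind(row = as.integer(row), col = as.integer(col))
}

## (row, col) -> cell-centre (x, y)
chm_xy_of <- function(chm, row, col) {
  nr <- nrow(chm$values)
  cbind(x = chm$xll + (col - 0.5) * chm$cellsize,
        y = chm$yll + (nr - row + 0.5) * chm$cellsize)
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south). Used in
#' place of GeoTIFF, for which no reader is available in this toolchain.
#'
#' @param path file path.
#' @param chm a `chm_raster` (for writing).
#' @param digits significant digits written.
#' @return `read_ascii_grid()` returns a `chm_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1L]); val <- as.numeric(kv[, 2L])
  get <- function(k, default = NA) if (k %in% key) val[match(k, key)] else default
  nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
  nodata <- get("nodata_value", -9999)
  dat <- scan(path, skip = 6L, quiet = TRUE)
  if (length(dat) != nr * nc)
    stop("ASCII grid body has ", length(dat), " values, expected ", nr * nc,
         call. = FALSE)
  chm_raster(matrix(dat, nr, nc, byrow = TRUE),
             cellsize = get("cellsize"),
             xll = get("xllcorner", 0), yll = get("yllcorner", 0),
             nodata = nodata)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(chm, path, digits = 6) {
  v <- chm$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", chm$xll), paste("yllcorner", chm$yll),
               paste("cellsize", chm$cellsize),
               paste("NODATA_value", chm$nodata)), con)
  writeLines(apply(signif(v, digits), 1L, paste, collapse = " "), con)
  invisible(path)
}

## Rank filter (min/max) with a k x k square window, replicate-padded.
rank_filter <- function(m, k, fun = pmax) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  idx <- function(n, s) pmin(n, pmax(1L, seq_len(n) + s))
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    out <- fun(out, m[idx(nr, dr), idx(nc, dc), drop = FALSE])
  }
  out
}

#' Remove CHM pits by grayscale morphological closing
#'
#' Dilation (max filter) followed by erosion (min filter) with a square
#' `kernel_size x kernel_size` structuring element. Fills single-cell data
#' dropouts ("pits") while leaving plateaus and already-closed surfaces
#' unchanged; the output is cell-wise >= the input.
#'
#' @param chm a `chm_raster`.
#' @param kernel_size odd window size >= 3 (cells).
#' @return the closed `chm_raster`.
#' @export
close_pits <- function(chm, kernel_size = 3L) {
  if (kernel_size < 3 || kernel_size %% 2 == 0)
    stop("`kernel_size` must be an odd number >= 3", call. = FALSE)
  dil <- rank_filter(chm$values, kernel_size, pmax)
  ero <- rank_filter(dil, kernel_size, pmin)
  chm$values <- pmax(ero, chm$values)  # closing is extensive; guard borders
  chm
}

## Separable Gaussian blur, reflected edges; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(v[pmin(n, pmax(1L, r:1))], v, v[pmin(n, pmax(1L, n:(n - r + 1L)))])
    stats::filter(vp, k, sides = 2)[r + seq_len(n)]
  }
  m2 <- apply(m, 2L, pad_conv)
  t(apply(t(m2), 2L, pad_conv))
}

## Local maxima of a matrix over a (2r+1)^2 window, above min_height.
local_maxima <- function(m, r = 2L, min_height = 2) {
  mx <- rank_filter(m, 2L * r + 1L, pmax)
  which(m >= mx & m >= min_height, arr.ind = TRUE)
}
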