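#' Pyramidal tiled images
#'
#' A `tiled_image` is an in-memory multi-resolution raster: level 0 holds the
#' full-resolution pixels and every further level is the previous one
#' downsampled by block averaging with a fixed integer factor (4 by default,
#' the usual whole-slide convention).  Levels are addressed tile-wise with a
#' fixed tile size (512 by default); edge tiles may be partial.  Pixel values
#' are stored as floating point in \[0, 1\], quantized to the declared bit
#' depth (`uint8` or `uint16`) so that file round trips are exact.
#'
#' Coordinates are 0-based with x growing rightward and y downward; a tile is
#' addressed as `(tx, ty)` (column, row) and tiles are iterated row-major.
#'
#' @param base numeric matrix (grayscale) or height x width x channels array
#'   with values in \[0, 1\].
#' @param tile_size edge length of a tile in pixels.
#' @param factor integer downsampling factor between pyramid levels (>= 2).
#' @param channels optional character vector naming the channels (e.g.
#'   `c("R","G","B")` or fluorescence channel names).
#' @param pixel_type `"uint8"` or `"uint16"`; values are quantized to this
#'   bit depth on construction.
#' @return an object of class `tiled_image`.
#' @export
tiled_image <- function(base, tile_size = 512L, factor = 4L, channels = NULL,
                        pixel_type = c("uint8", "uint16")) {
  pixel_type <- match.arg(pixel_type)
  if (is.matrix(base)) base <- array(base, c(dim(base), 1L))
  if (length(dim(base)) != 3L) stop("`base` must be a matrix or 3-d array")
  if (prod(dim(base)) == 0L) stop("empty raster")
  if (factor < 2L) stop("`factor` must be >= 2")
  maxval <- if (pixel_type == "uint8") 255 else 65535
  base <- round(pmin(pmax(base, 0), 1) * maxval) / maxval
  if (is.null(channels)) {
    channels <- if (dim(base)[3] == 3L) c("R", "G", "B")
                else paste0("C", seq_len(dim(base)[3]))
  }
  levels <- list(base)
  while (max(dim(levels[[length(levels)]])[1:2]) >= tile_size) {
    levels[[length(levels) + 1L]] <-
      downsample_block(levels[[length(levels)]], factor)
  }
  structure(list(levels = levels, tile_size = as.integer(tile_size),
                 factor = as.integer(factor), channels = channels,
                 pixel_type = pixel_type, max_val = maxval),
            class = "tiled_image")
}

#' @rdname tiled_image
#' @export
build_pyramid <- function(base, tile_size = 512L, factor = 4L, ...)
  tiled_image(base, tile_size = tile_size, factor = factor, ...)

# Block-average downsampling with ceiling dimensions; partial edge blocks are
# averaged over the pixels they actually contain.
downsample_block <- function(arr, factor) {
  h <- dim(arr)[1]; w <- dim(arr)[2]; nc <- dim(arr)[3]
  nh <- ceiling(h / factor); nw <- ceiling(w / factor)
  ri <- rep(seq_len(nh), each = factor)[seq_len(h)]
  ci <- rep(seq_len(nw), each = factor)[seq_len(w)]
  cnt <- outer(tabulate(ri, nh), tabulate(ci, nw))
  out <- array(0, c(nh, nw, nc))
  for (ch in seq_len(nc)) {
    sums <- rowsum(arr[, , ch], ri)          # collapse rows
    sums <- t(rowsum(t(sums), ci))           # collapse cols
    out[, , ch] <- sums / cnt
  }
  out
}

#' @export
print.tiled_image <- function(x, ...) {
  d0 <- dim(x$levels[[1]])
  cat(sprintf("<tiled_image> %dx%d px, %d channel(s) [%s], %s\n",
              d0[2], d0[1], d0[3], paste(x$channels, collapse = ","),
              x$pixel_type))
  cat(sprintf("  %d level(s), factor %d, tile size %d\n",
              length(x$levels), x$factor, x$tile_size))
  for (l in seq_along(x$levels)) {
    d <- dim(x$levels[[l]])
    nt <- n_tiles(x, l - 1L)
    cat(sprintf("  level %d: %dx%d (%dx%d tiles)\n", l - 1L, d[2], d[1],
                nt[1], nt[2]))
  }
  invisible(x)
}

#' Image geometry helpers
#'
#' `image_dim` returns `c(width, height)` of a pyramid level; `n_tiles` the
#' tile-grid size `c(ntx, nty)`; `n_levels` the number of pyramid levels.
#'
#' @param image a [tiled_image].
#' @param level 0-based pyramid level.
#' @export
image_dim <- function(image, level = 0L) {
  check_level(image, level)
  d <- dim(image$levels[[level + 1L]])
  c(width = d[2], height = d[1])
}

#' @rdname image_dim
#' @export
n_tiles <- function(image, level = 0L) {
  d <- image_dim(image, level)
  c(ntx = ceiling(d[[1]] / image$tile_size),
    nty = ceiling(d[[2]] / image$tile_size))
}

#' @rdname image_dim
#' @export
n_levels <- function(image) length(image$levels)

check_level <- function(image, level) {
  if (level < 0L || level >= length(image$levels))
    stop(sprintf("level %d out of range [0, %d]", level,
                 length(image$levels) - 1L))
}

#' Read one tile, optionally with a mirrored halo
#'
#' Returns the pixels of tile `(tx, ty)` of the requested level, expanded by
#' `halo` pixels on each side.  Halo pixels beyond the image bounds are
#' mirror-padded (reflection without edge repetition), which avoids spurious
#' edge responses in windowed features.  `offset` locates the returned raster
#' in level coordinates: the raster's top-left pixel is at
#' `(tx*tile_size - halo, ty*tile_size - halo)`.
#'
#' @param image a [tiled_image].
#' @param level 0-based pyramid level.
#' @param tx,ty 0-based tile column / row.
#' @param halo non-negative halo width in pixels.
#' @return `list(raster = array, offset = c(x, y))`.
#' @export
read_tile <- function(image, level, tx, ty, halo = 0L) {
  check_level(image, level)
  if (halo < 0L) stop("halo must be >= 0")
  nt <- n_tiles(image, level)
  if (tx < 0L || tx >= nt[[1]] || ty < 0L || ty >= nt[[2]])
    stop(sprintf("tile (%d,%d) out of range for level %d grid %dx%d",
                 tx, ty, level, nt[[1]], nt[[2]]))
  ts <- image$tile_size
  d <- image_dim(image, level)
  arr <- image$levels[[level + 1L]]
  x0 <- tx * ts; y0 <- ty * ts
  x1 <- min(x0 + ts, d[[1]]) - 1L; y1 <- min(y0 + ts, d[[2]]) - 1L
  ci <- reflect_idx(seq.int(x0 - halo, x1 + halo), d[[1]])
  ri <- reflect_idx(seq.int(y0 - halo, y1 + halo), d[[2]])
  list(raster = arr[ri, ci, , drop = FALSE],
       offset = c(x = x0 - halo, y = y0 - halo))
}

#' Content-based image identifier
#'
#' A 32-hex-character md5 digest over the level-0 pixel bytes in row-major,
#' channel-interleaved order at the image's declared bit depth (16-bit values
#' little-endian).  Two images with identical level-0 content share an ID.
#'
#' @param image a [tiled_image].
#' @return character md5 digest.
#' @export
image_id <- function(image) {
  arr <- image$levels[[1]]
  vals <- as.integer(round(arr * image$max_val))
  # arr is [y, x, channel]; interleave channels within pixel, rows major:
  # order index = channel fastest, then x, then y
  vals <- aperm(array(vals, dim(arr)), c(3L, 2L, 1L))
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  if (image$pixel_type == "uint8") {
    writeBin(as.raw(as.vector(vals)), con)
  } else {
    writeBin(as.vector(vals), con, size = 2L, endian = "little")
  }
  close(con)
  unname(tools::md5sum(tf))
}

#' Read and write pyramidal images
#'
#' Images are stored as multi-page TIFF where page `l` is pyramid level `l`;
#' plain single-page TIFF or PNG files are accepted and pyramidized on read.
#' Writing then re-reading reproduces the level-0 pixels exactly (values are
#' quantized to the declared bit depth on construction).
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @param image a [tiled_image].
#' @param tile_size,factor pyramid geometry used when (re)constructing.
#' @export
read_wsi <- function(path, tile_size = 512L, factor = 4L) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L && dim(arr)[3] == 4L) arr <- arr[, , 1:3]
    return(tiled_image(arr, tile_size, factor))
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  base <- pages[[1]]
  bits <- attr(base, "bits.per.sample") %||% 8L
  tiled_image(base, tile_size, factor,
              pixel_type = if (isTRUE(bits == 16L)) "uint16" else "uint8")
}

#' @rdname read_wsi
#' @export
write_wsi <- function(image, path) {
  bits <- if (image$pixel_type == "uint8") 8L else 16L
  pages <- lapply(image$levels, function(a) if (dim(a)[3] == 1L) a[, , 1] else a)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

# Stitch all tiles of a level back into one raster (used by tests and by the
# refinement pipeline).
stitch_level <- function(image, level = 0L) image$levels[[level + 1L]]
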