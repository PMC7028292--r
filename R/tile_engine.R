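#' Tile-level map-reduce
#'
#' Every analysis in the package runs as a tile job: a pure `map_fn` is
#' applied to each tile (delivered with its requested halo already attached),
#' and `reduce_fn` folds the per-tile partial results.  Because `map_fn` is
#' pure and `reduce_fn` order-insensitive for all shipped analyses, the final
#' result is identical across worker counts and scheduling orders.
#'
#' @param image a [tiled_image].
#' @param level 0-based pyramid level the job runs on.
#' @param roi optional [effective_roi()] predicate restricting the tiles
#'   visited (in level-0 coordinates).
#' @param halo halo width in pixels passed to [read_tile()] for each tile.
#' @param map_fn `function(image, level, tx, ty, raster, offset) -> partial`.
#' @param reduce_fn `function(list_of_partials) -> result`.
#' @return a `tile_job` object for [run_map_reduce()].
#' @export
tile_job <- function(image, level = 0L, roi = NULL, halo = 0L,
                     map_fn, reduce_fn) {
  stopifnot(inherits(image, "tiled_image"), is.function(map_fn),
            is.function(reduce_fn))
  structure(list(image = image, level = as.integer(level), roi = roi,
                 halo = as.integer(halo), map_fn = map_fn,
                 reduce_fn = reduce_fn),
            class = "tile_job")
}

#' Enumerate the tiles a job must visit
#'
#' Returns, in deterministic row-major order (ty outer, tx inner), exactly the
#' tiles whose level-0 footprint intersects the ROI; all tiles when `roi` is
#' `NULL`.
#'
#' @inheritParams tile_job
#' @return data.frame with 0-based columns `tx`, `ty`.
#' @export
enumerate_tiles <- function(image, level = 0L, roi = NULL) {
  nt <- n_tiles(image, level)
  grid <- expand.grid(tx = seq_len(nt[[1]]) - 1L, ty = seq_len(nt[[2]]) - 1L)
  if (is.null(roi)) return(grid)
  scale <- image$factor^level
  ts <- image$tile_size * scale
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$tx[i] * ts; y0 <- grid$ty[i] * ts
    roi_intersects_rect(roi, x0, y0, ts, ts)
  }, logical(1))
  grid[keep, , drop = FALSE]
}

#' Execute a tile job
#'
#' Runs `map_fn` over the job's tiles with the local multi-threaded executor
#' (forked workers via the parallel package when `workers > 1`) and folds the
#' partial results with `reduce_fn`.  Partials are always reduced in tile
#' enumeration order, so the result is bit-identical for any worker count.
#' A failing tile aborts the whole job and reports its index.
#'
#' @param job a [tile_job()].
#' @param workers worker count for the local executor.
#' @return the reduced result.
#' @export
run_map_reduce <- function(job, workers = 1L) {
  stopifnot(inherits(job, "tile_job"))
  tiles <- enumerate_tiles(job$image, job$level, job$roi)
  if (nrow(tiles) == 0L) return(job$reduce_fn(list()))
  one <- function(i) {
    tx <- tiles$tx[i]; ty <- tiles$ty[i]
    tl <- read_tile(job$image, job$level, tx, ty, job$halo)
    tryCatch(
      job$map_fn(job$image, job$level, tx, ty, tl$raster, tl$offset),
      error = function(e) structure(
        list(tile = c(tx, ty), message = conditionMessage(e)),
        class = "tile_failure"))
  }
  partials <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(tiles)), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(tiles)), one)
  }
  for (p in partials) {
    if (inherits(p, "tile_failure"))
      stop(sprintf("map step failed at tile (%d,%d): %s",
                   p$tile[1], p$tile[2], p$message))
  }
  job$reduce_fn(partials)
}
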