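#' Fibre-tracing parameters
#'
#' Dual-threshold hysteresis segmentation of curvilinear structures: pixels
#' with response above `low` form candidate components, and a component is
#' kept only if it contains at least one pixel above `high` — dim tails stay
#' attached to bright cores, isolated dim clutter is discarded.  The response
#' is the configured channel's intensity, its inversion (dark fibres on
#' bright-field), or its gradient magnitude, optionally Gaussian-smoothed.
#'
#' @param response `"intensity"`, `"inverted"` or `"gradient"`.
#' @param low,high hysteresis thresholds, `0 <= low < high <= 1`.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (0 = none); the
#'   kernel is truncated at radius `ceiling(3*sigma)`.
#' @param channel 1-based channel the response is computed from.
#' @param d junction proximity distance in pixels (see
#'   [count_junction_crossings()]).
#' @export
fibre_params <- function(response = c("intensity", "inverted", "gradient"),
                         low = 0.3, high = 0.6, smooth_sigma = 1,
                         channel = 1L, d = 5) {
  response <- match.arg(response)
  if (!(low >= 0 && low < high && high <= 1))
    stop("thresholds must satisfy 0 <= low < high <= 1")
  structure(list(response = response, low = low, high = high,
                 smooth_sigma = smooth_sigma, channel = as.integer(channel),
                 d = d),
            class = "fibre_params")
}

# truncated separable Gaussian; shift-and-add so tile and whole-image
# computations are bitwise identical for the same pixel context
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- mirror_pad(mat, r)
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- 0
  for (i in seq_along(k))
    acc <- acc + k[i] * p[seq_len(nr) + i - 1L, , drop = FALSE]
  out <- 0
  for (i in seq_along(k))
    out <- out + k[i] * acc[, seq_len(nc) + i - 1L, drop = FALSE]
  out
}

fibre_halo <- function(params)
  as.integer(ceiling(3 * params$smooth_sigma) +
               if (params$response == "gradient") 1L else 0L)

# response over a (possibly haloed) single-channel matrix; the caller must
# provide `halo` >= fibre_halo(params) pixels of true context
fibre_response <- function(mat, params) {
  m <- switch(params$response,
              intensity = mat, inverted = 1 - mat, gradient = mat)
  m <- gauss_blur(m, params$smooth_sigma)
  if (params$response == "gradient") {
    p <- mirror_pad(m, 1L)
    nr <- nrow(m); nc <- ncol(m)
    gx <- (p[seq_len(nr) + 1L, seq_len(nc) + 2L] -
           p[seq_len(nr) + 1L, seq_len(nc)]) / 2
    gy <- (p[seq_len(nr) + 2L, seq_len(nc) + 1L] -
           p[seq_len(nr), seq_len(nc) + 1L]) / 2
    m <- sqrt(gx * gx + gy * gy)
  }
  m
}

new_fibre_fragment <- function(id, pixels, has_high, open, tile = c(0L, 0L)) {
  structure(list(id = id, pixels = pixels, has_high = has_high,
                 open = open, tile = tile, crossings = NULL),
            class = "fibre")
}

#' Hysteresis segmentation of one tile
#'
#' Labels 8-connected components of `response >= low` within the tile
#' footprint and flags components containing a pixel with `response >= high`.
#' Components without a high pixel are discarded unless they touch an
#' internal tile border — those are kept (flagged `open`) because their
#' cross-border partner may carry the high evidence; the final keep/discard
#' decision is re-evaluated by [connect_tile_border_segments()].  On a
#' whole-image call (no internal borders) all low-only components are
#' discarded, matching single-pass hysteresis.
#'
#' @param raster haloed channel data (matrix or h x w x c array) covering the
#'   footprint plus `fibre_halo(params)` context.
#' @param params a [fibre_params()].
#' @param origin global `c(x, y)` of the raster's top-left pixel.
#' @param footprint `c(x0, y0, w, h)` global tile footprint.
#' @param image_dim `c(width, height)` of the image.
#' @param tile provenance tile index.
#' @return list of `fibre` fragments with global pixel coordinates.
#' @export
hysteresis_segment <- function(raster, params, origin = c(0, 0),
                               footprint = NULL, image_dim = NULL,
                               tile = c(0L, 0L)) {
  mat <- if (length(dim(raster)) == 3L) raster[, , params$channel] else raster
  resp <- fibre_response(mat, params)
  footprint <- footprint %||% c(origin[1], origin[2], ncol(mat), nrow(mat))
  image_dim <- image_dim %||% c(footprint[1] + footprint[3],
                                footprint[2] + footprint[4])
  # crop response to the footprint
  rx <- footprint[1] - origin[1]; ry <- footprint[2] - origin[2]
  resp <- resp[ry + seq_len(footprint[4]), rx + seq_len(footprint[3]),
               drop = FALSE]
  lab <- label8(resp >= params$low)
  if (!any(lab > 0)) return(list())
  fx0 <- footprint[1]; fy0 <- footprint[2]
  fx1 <- fx0 + footprint[3] - 1L; fy1 <- fy0 + footprint[4] - 1L
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    ys <- (idx - 1L) %% nrow(lab) + fy0
    xs <- (idx - 1L) %/% nrow(lab) + fx0
    has_high <- any(resp[idx] >= params$high)
    open <- (any(xs == fx0) && fx0 > 0) ||
            (any(ys == fy0) && fy0 > 0) ||
            (any(xs == fx1) && fx1 < image_dim[1] - 1L) ||
            (any(ys == fy1) && fy1 < image_dim[2] - 1L)
    if (!has_high && !open) next
    out[[length(out) + 1L]] <-
      new_fibre_fragment(sprintf("f%dx%d_%d", tile[1], tile[2], k),
                         cbind(x = xs, y = ys), has_high, open, tile)
  }
  out
}

#' Reconnect fibre fragments across tile borders
#'
#' Fragments whose pixels are 8-adjacent across tile borders are unioned,
#' and the hysteresis keep/discard rule is re-evaluated on the merged
#' component: a low-only fragment survives exactly when some fragment it
#' merges with carries a high pixel.  With no border fragments this is the
#' identity.
#'
#' @param fragments list of `fibre` fragments from [hysteresis_segment()].
#' @return list of `fibre` objects.
#' @export
connect_tile_border_segments <- function(fragments) {
  if (!length(fragments)) return(fragments)
  open_idx <- which(vapply(fragments, `[[`, TRUE, "open"))
  parent <- uf_new(length(fragments))
  if (length(open_idx) > 1L) {
    W <- max(vapply(fragments, function(o) max(o$pixels[, 1]), numeric(1))) + 2
    keys <- lapply(open_idx, function(i)
      fragments[[i]]$pixels[, 1] + fragments[[i]]$pixels[, 2] * W)
    allkeys <- unlist(keys)
    owner <- rep(open_idx, vapply(keys, length, 1L))
    for (ii in seq_along(open_idx)) {
      i <- open_idx[ii]
      px <- fragments[[i]]$pixels
      for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
        nk <- (px[, 1] + off[1]) + (px[, 2] + off[2]) * W
        hit <- match(nk, allkeys)
        hit <- hit[!is.na(hit)]
        for (o in unique(owner[hit]))
          if (o != i) parent <- uf_union(parent, i, o)
      }
    }
  }
  roots <- uf_roots(parent)
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (!any(vapply(fragments[members], `[[`, TRUE, "has_high"))) next
    px <- unique(do.call(rbind, lapply(fragments[members], `[[`, "pixels")))
    fb <- new_fibre_fragment(fragments[[members[1]]]$id, px,
                             has_high = TRUE, open = FALSE)
    out[[length(out) + 1L]] <- fb
  }
  out
}

#' Trace fibres over a whole image
#'
#' Runs [hysteresis_segment()] as a tile map-reduce job (each tile with the
#' smoothing halo attached) and reconnects fragments across tile borders;
#' the result equals single-pass hysteresis on the unpartitioned image.
#'
#' @param image a [tiled_image].
#' @param params a [fibre_params()].
#' @param roi optional ROI predicate restricting the tiles visited.
#' @param workers tile-executor worker count.
#' @return list of `fibre` objects.
#' @export
trace_fibres <- function(image, params, roi = NULL, workers = 1L) {
  d <- image_dim(image, 0L)
  ts <- image$tile_size
  halo <- fibre_halo(params)
  map_fn <- function(img, level, tx, ty, raster, offset) {
    x0 <- tx * ts; y0 <- ty * ts
    w <- min(ts, d[[1]] - x0); h <- min(ts, d[[2]] - y0)
    hysteresis_segment(raster, params, origin = offset,
                       footprint = c(x0, y0, w, h), image_dim = d,
                       tile = c(tx, ty))
  }
  job <- tile_job(image, 0L, roi, halo, map_fn,
                  reduce_fn = function(parts) do.call(c, c(parts, list(list()))))
  connect_tile_border_segments(run_map_reduce(job, workers = workers))
}

#' Count junction-line crossings per fibre
#'
#' Implements the intraepidermal-nerve-fibre-density style readout: fibres
#' farther than `d` pixels from the annotated junction polyline are dropped;
#' for each remaining fibre, every 8-connected component of its intersection
#' with the polyline buffered by 1 pixel counts as a crossing when its pixels
#' lie strictly on both sides of the line (side taken from the nearest
#' segment's signed normal, terminal segments extended).  The summary
#' density is total crossings per millimetre of junction when `pixel_size`
#' (micrometre per pixel) is supplied, else per kilopixel.
#'
#' @param fibres list of `fibre` objects.
#' @param junction a `junction_line` [annotation()] (or bare polyline matrix).
#' @param d proximity distance in pixels.
#' @param pixel_size optional micrometres per pixel.
#' @return `list(fibres, per_fibre, total, junction_length, density,
#'   density_unit)`; `fibres` is the kept subset with `$crossings` filled in.
#' @export
count_junction_crossings <- function(fibres, junction, d = 5,
                                     pixel_size = NULL) {
  if (is.null(junction)) stop("a junction_line annotation is required")
  line <- if (inherits(junction, "annotation")) junction$coords else
    as.matrix(junction)
  if (inherits(junction, "annotation") && junction$type != "junction_line")
    stop("junction annotation must have type 'junction_line'")
  kept <- list(); counts <- integer(0)
  for (fb in fibres) {
    cx <- fb$pixels[, 1] + 0.5; cy <- fb$pixels[, 2] + 0.5
    dist <- points_polyline_distance(cx, cy, line)
    if (min(dist) > d) next
    ncross <- 0L
    near <- which(dist <= 1)
    if (length(near)) {
      # components of the buffered intersection, within this fibre
      px <- fb$pixels[near, , drop = FALSE]
      x0 <- min(px[, 1]); y0 <- min(px[, 2])
      m <- matrix(FALSE, max(px[, 2]) - y0 + 1L, max(px[, 1]) - x0 + 1L)
      m[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)] <- TRUE
      lab <- label8(m)
      sides <- polyline_side(px[, 1] + 0.5, px[, 2] + 0.5, line)
      comp <- lab[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)]
      for (k in seq_len(max(lab))) {
        s <- sides[comp == k]
        if (any(s > 0) && any(s < 0)) ncross <- ncross + 1L
      }
    }
    fb$crossings <- ncross
    counts <- c(counts, ncross)
    kept[[length(kept) + 1L]] <- fb
  }
  len <- sum(sqrt(rowSums((line[-1, , drop = FALSE] -
                           line[-nrow(line), , drop = FALSE])^2)))
  total <- sum(counts)
  if (!is.null(pixel_size)) {
    density <- total / (len * pixel_size / 1000)
    unit <- "crossings/mm"
  } else {
    density <- total / (len / 1000)
    unit <- "crossings/kilopixel"
  }
  list(fibres = kept, per_fibre = counts, total = total,
       junction_length = len, density = density, density_unit = unit)
}

# signed side of the nearest polyline segment (terminal segments extended):
# > 0 on one side, < 0 on the other, 0 on the line
polyline_side <- function(px, py, line) {
  nseg <- nrow(line) - 1L
  best <- rep(Inf, length(px)); seg <- rep(1L, length(px))
  for (e in seq_len(nseg)) {
    ax <- line[e, 1]; ay <- line[e, 2]
    bx <- line[e + 1L, 1]; by <- line[e + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      ((px - ax) * vx + (py - ay) * vy) / len2
    tc <- pmin(1, pmax(0, t))
    # terminal segments extend to infinity
    if (e == 1L) tc <- ifelse(t < 0, t, tc)
    if (e == nseg) tc <- ifelse(t > 1, t, tc)
    dx <- px - (ax + tc * vx); dy <- py - (ay + tc * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best
    best[upd] <- d2[upd]; seg[upd] <- e
  }
  ax <- line[seg, 1]; ay <- line[seg, 2]
  bx <- line[seg + 1L, 1]; by <- line[seg + 1L, 2]
  sign((bx - ax) * (py - ay) - (by - ay) * (px - ax))
}
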