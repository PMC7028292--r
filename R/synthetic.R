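#' Synthetic whole-slide scenes
#'
#' The generator renders controlled microscopy-like scenes — textured tissue
#' regions, disc-shaped "cells", curvilinear "fibres" with bright cores and
#' dim tails, and ring-plus-interior composite objects — over a noisy
#' background, and returns pixel-accurate ground truth (label masks, object
#' counts, outlines, per-fibre polylines) alongside the rendered image.
#' Generation is a pure function of the spec: the same spec and seed produce
#' byte-identical images and ground truth.
#'
#' @param width,height canvas size in pixels.
#' @param seed integer seed driving every random choice in the render.
#' @param background background mean intensity in \[0,1\].
#' @param noise_sd standard deviation of the additive background noise.
#' @param channels number of image channels.
#' @param elements list of element descriptors built with [el_texture_region()],
#'   [el_blob_field()], [el_fibre_set()] or [el_composite()].
#' @return `scene_spec` returns a spec object; `generate_synthetic_wsi`
#'   returns `list(image = tiled_image, truth = list)`, where `truth$elements`
#'   holds per-element ground truth.
#' @export
scene_spec <- function(width, height, seed = 1L, background = 0.15,
                       noise_sd = 0.01, channels = 1L, elements = list()) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed), background = background,
                 noise_sd = noise_sd, channels = as.integer(channels),
                 elements = elements),
            class = "scene_spec")
}

#' Scene elements
#'
#' Descriptors for the synthetic-scene generator.  All geometry is in level-0
#' pixel coordinates; `rect = c(x, y, w, h)` places an element in a canvas
#' sub-window.
#'
#' @param rect region `c(x, y, w, h)` the element occupies / is placed in.
#' @param mean,amplitude,freq texture mean intensity, sinusoid amplitude and
#'   spatial frequency (cycles per pixel).
#' @param channel 1-based channel the element is drawn on.
#' @param class_name label recorded in the ground truth.
#' @export
el_texture_region <- function(rect, mean = 0.5, amplitude = 0.1, freq = 0.1,
                              grain_sd = NULL, channel = 1L,
                              class_name = "texture") {
  list(kind = "texture_region", rect = rect, mean = mean,
       amplitude = amplitude, freq = freq,
       grain_sd = grain_sd %||% (amplitude * 0.15),
       channel = as.integer(channel), class_name = class_name)
}

#' @rdname el_texture_region
#' @param n number of objects.
#' @param radius `c(min, max)` disc radius range in pixels.
#' @param intensity scalar intensity, or vector sampled per blob.
#' @param overlap allow discs to overlap; if `FALSE` placement is rejection
#'   sampled and an error is raised when the region cannot hold them.
#' @param straddle number of discs deliberately centred on internal tile
#'   borders of a `tile_size` grid (placed along edges, away from corners).
#' @param tile_size tile grid used for `straddle` placement.
#' @export
el_blob_field <- function(n, radius = c(8, 14), intensity = 0.8,
                          rect = NULL, overlap = FALSE, straddle = 0L,
                          tile_size = 512L, channel = 1L,
                          class_name = "blob") {
  list(kind = "blob_field", n = as.integer(n), radius = radius,
       intensity = intensity, rect = rect, overlap = overlap,
       straddle = as.integer(straddle), tile_size = as.integer(tile_size),
       channel = as.integer(channel), class_name = class_name)
}

#' @rdname el_texture_region
#' @param core_intensity,tail_intensity intensity of the fibre core and of
#'   the terminal dim tail.
#' @param tail_frac fraction (by arc length) of each fibre drawn at
#'   `tail_intensity`.
#' @param fibre_width stroke width in pixels.
#' @param length approximate fibre arc length in pixels.
#' @param curviness sd of the per-step heading change (radians).
#' @export
el_fibre_set <- function(n, core_intensity = 0.9, tail_intensity = 0.45,
                         tail_frac = 0.25, fibre_width = 3, length = 120,
                         curviness = 0.25, rect = NULL, channel = 1L,
                         class_name = "fibre") {
  list(kind = "fibre_set", n = as.integer(n), core_intensity = core_intensity,
       tail_intensity = tail_intensity, tail_frac = tail_frac,
       fibre_width = fibre_width, length = length, curviness = curviness,
       rect = rect, channel = as.integer(channel), class_name = class_name)
}

#' @rdname el_texture_region
#' @param rim_width,rim_intensity width and intensity of the outer ring of a
#'   composite ("glomerulus-like") object.
#' @param interior_mean,interior_amplitude,interior_freq interior texture.
#' @export
el_composite <- function(n, radius = c(25, 40), rim_width = 4,
                         rim_intensity = 0.85, interior_mean = 0.55,
                         interior_amplitude = 0.15, interior_freq = 0.15,
                         rect = NULL, overlap = FALSE, straddle = 0L,
                         tile_size = 512L, channel = 1L,
                         class_name = "composite") {
  list(kind = "composite_object", n = as.integer(n), radius = radius,
       rim_width = rim_width, rim_intensity = rim_intensity,
       interior_mean = interior_mean, interior_amplitude = interior_amplitude,
       interior_freq = interior_freq, rect = rect, overlap = overlap,
       straddle = as.integer(straddle), tile_size = as.integer(tile_size),
       channel = as.integer(channel), class_name = class_name)
}

#' @rdname scene_spec
#' @param spec a `scene_spec`.
#' @param tile_size,factor pyramid geometry of the returned image.
#' @export
generate_synthetic_wsi <- function(spec, tile_size = 512L, factor = 4L) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  with_seed(spec$seed, {
    canvas <- array(spec$background, c(h, w, spec$channels))
    canvas <- canvas + array(stats::rnorm(h * w * spec$channels, 0, spec$noise_sd),
                             c(h, w, spec$channels))
    truth <- list(width = w, height = h, elements = vector("list",
                                                           length(spec$elements)))
    for (i in seq_along(spec$elements)) {
      el <- spec$elements[[i]]
      res <- switch(el$kind,
        texture_region   = render_texture_region(canvas, el),
        blob_field       = render_blob_field(canvas, el, w, h),
        fibre_set        = render_fibre_set(canvas, el, w, h),
        composite_object = render_composite(canvas, el, w, h),
        stop("unknown element kind: ", el$kind))
      canvas <- res$canvas
      truth$elements[[i]] <- res$truth
    }
    canvas <- pmin(pmax(canvas, 0), 1)
    list(image = tiled_image(canvas, tile_size = tile_size, factor = factor),
         truth = truth)
  })
}

# deterministic band-limited texture: mean + amplitude * product of sinusoids
# with a seeded phase, plus a small seeded grain so windows are never constant
texture_patch <- function(hh, ww, x0, y0, mean, amplitude, freq, grain_sd) {
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  xs <- matrix(rep(x0 + seq_len(ww) - 1, each = hh), hh, ww)
  ys <- matrix(rep(y0 + seq_len(hh), ww), hh, ww)
  tx <- sin(2 * pi * freq * xs + ph1) * sin(2 * pi * freq * ys + ph2)
  mean + amplitude * tx + matrix(stats::rnorm(hh * ww, 0, grain_sd), hh, ww)
}

render_texture_region <- function(canvas, el) {
  r <- round(el$rect)
  rows <- (r[2] + 1):(r[2] + r[4]); cols <- (r[1] + 1):(r[1] + r[3])
  canvas[rows, cols, el$channel] <-
    texture_patch(r[4], r[3], r[1], r[2], el$mean, el$amplitude, el$freq,
                  el$grain_sd %||% (el$amplitude * 0.15))
  mask <- matrix(FALSE, dim(canvas)[1], dim(canvas)[2])
  mask[rows, cols] <- TRUE
  list(canvas = canvas,
       truth = list(kind = "texture_region", class_name = el$class_name,
                    rect = r, mask = mask,
                    polygon = rect_polygon(r)))
}

rect_polygon <- function(r)
  cbind(x = c(r[1], r[1] + r[3], r[1] + r[3], r[1]),
        y = c(r[2], r[2], r[2] + r[4], r[2] + r[4]))

# rejection-sampled disc centres; straddlers are pinned to internal tile
# border lines, away from corners (see vignette for why corners are avoided)
place_discs <- function(n, radius, rect, overlap, straddle, tile_size, w, h) {
  rect <- rect %||% c(0, 0, w, h)
  rmax <- max(radius)
  centres <- matrix(NA_real_, n, 2)
  radii <- stats::runif(n, radius[1], max(radius))
  vlines <- setdiff(seq(0, w, by = tile_size), c(0, w))
  hlines <- setdiff(seq(0, h, by = tile_size), c(0, h))
  ok_pos <- function(cx, cy, r, k) {
    if (cx - r < rect[1] + 1 || cx + r > rect[1] + rect[3] - 1 ||
        cy - r < rect[2] + 1 || cy + r > rect[2] + rect[4] - 1) return(FALSE)
    if (overlap || k == 1) return(TRUE)
    prev <- seq_len(k - 1)
    all((centres[prev, 1] - cx)^2 + (centres[prev, 2] - cy)^2 >
          (radii[prev] + r + 2)^2)
  }
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(4000)) {
      if (k <= straddle && (length(vlines) || length(hlines))) {
        corner_margin <- tile_size / 4
        if (length(vlines) && (try %% 2 == 0 || !length(hlines))) {
          cx <- sample(vlines, 1)
          cy <- stats::runif(1, rect[2] + corner_margin,
                             rect[2] + rect[4] - corner_margin)
          cy <- cy + (corner_margin - cy %% tile_size) *
            (cy %% tile_size < corner_margin)
        } else {
          cy <- sample(hlines, 1)
          cx <- stats::runif(1, rect[1] + corner_margin,
                             rect[1] + rect[3] - corner_margin)
          cx <- cx + (corner_margin - cx %% tile_size) *
            (cx %% tile_size < corner_margin)
        }
      } else {
        cx <- stats::runif(1, rect[1] + rmax + 1, rect[1] + rect[3] - rmax - 1)
        cy <- stats::runif(1, rect[2] + rmax + 1, rect[2] + rect[4] - rmax - 1)
      }
      if (ok_pos(cx, cy, radii[k], k)) {
        centres[k, ] <- c(cx, cy); placed <- TRUE; break
      }
    }
    if (!placed) stop("cannot place ", n, " non-overlapping objects in region")
  }
  list(centres = centres, radii = radii)
}

disc_pixels <- function(cx, cy, r, w, h) {
  x0 <- max(0, floor(cx - r - 1)); x1 <- min(w - 1, ceiling(cx + r + 1))
  y0 <- max(0, floor(cy - r - 1)); y1 <- min(h - 1, ceiling(cy + r + 1))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs + 0.5, each = length(ys)), length(ys))
  gy <- matrix(rep(ys + 0.5, length(xs)), length(ys))
  sel <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  cbind(x = gx[sel], y = gy[sel]) - 0.5
}

render_blob_field <- function(canvas, el, w, h) {
  pl <- place_discs(el$n, el$radius, el$rect, el$overlap, el$straddle,
                    el$tile_size, w, h)
  label <- matrix(0L, h, w)
  ints <- if (length(el$intensity) == 1L) rep(el$intensity, el$n)
          else sample(el$intensity, el$n, replace = TRUE)
  for (k in seq_len(el$n)) {
    px <- disc_pixels(pl$centres[k, 1], pl$centres[k, 2], pl$radii[k], w, h)
    idx <- cbind(px[, 2] + 1, px[, 1] + 1)
    label[idx] <- k
    canvas[cbind(idx, el$channel)] <- ints[k] +
      stats::rnorm(nrow(idx), 0, 0.01)
  }
  list(canvas = canvas,
       truth = list(kind = "blob_field", class_name = el$class_name,
                    count = el$n, centres = pl$centres, radii = pl$radii,
                    intensities = ints, label = label))
}

random_polyline <- function(rect, len, curviness, step = 4) {
  x <- stats::runif(1, rect[1] + 20, rect[1] + rect[3] - 20)
  y <- stats::runif(1, rect[2] + 20, rect[2] + rect[4] - 20)
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(c(x, y), 1)
  travelled <- 0
  while (travelled < len) {
    theta <- theta + stats::rnorm(1, 0, curviness)
    nx <- x + step * cos(theta); ny <- y + step * sin(theta)
    # reflect heading at the region boundary
    if (nx < rect[1] + 5 || nx > rect[1] + rect[3] - 5) {
      theta <- pi - theta; nx <- x + step * cos(theta); ny <- y + step * sin(theta)
    }
    if (ny < rect[2] + 5 || ny > rect[2] + rect[4] - 5) {
      theta <- -theta; nx <- x + step * cos(theta); ny <- y + step * sin(theta)
    }
    x <- nx; y <- ny
    pts <- rbind(pts, c(x, y))
    travelled <- travelled + step
  }
  pts
}

render_fibre_set <- function(canvas, el, w, h) {
  rect <- el$rect %||% c(0, 0, w, h)
  fibres <- vector("list", el$n)
  label <- matrix(0L, h, w)
  for (k in seq_len(el$n)) {
    line <- random_polyline(rect, el$length, el$curviness)
    # arc length position of each vertex, for the dim-tail profile
    seglen <- sqrt(rowSums((line[-1, , drop = FALSE] -
                            line[-nrow(line), , drop = FALSE])^2))
    arc <- c(0, cumsum(seglen)); total <- arc[length(arc)]
    x0 <- max(0, floor(min(line[, 1]) - el$fibre_width - 1))
    x1 <- min(w - 1, ceiling(max(line[, 1]) + el$fibre_width + 1))
    y0 <- max(0, floor(min(line[, 2]) - el$fibre_width - 1))
    y1 <- min(h - 1, ceiling(max(line[, 2]) + el$fibre_width + 1))
    xs <- x0:x1; ys <- y0:y1
    gx <- as.vector(matrix(rep(xs + 0.5, each = length(ys)), length(ys)))
    gy <- as.vector(matrix(rep(ys + 0.5, length(xs)), length(ys)))
    dist <- points_polyline_distance(gx, gy, line)
    sel <- dist <= el$fibre_width / 2
    if (!any(sel)) next
    # nearest-vertex arc position decides core vs tail intensity
    vi <- apply(cbind(gx[sel], gy[sel]), 1, function(p)
      which.min((line[, 1] - p[1])^2 + (line[, 2] - p[2])^2))
    inten <- ifelse(arc[vi] / total > 1 - el$tail_frac,
                    el$tail_intensity, el$core_intensity)
    px <- cbind(gy[sel] - 0.5 + 1, gx[sel] - 0.5 + 1)
    label[px] <- k
    canvas[cbind(px, el$channel)] <- inten
    fibres[[k]] <- list(polyline = line, length = total)
  }
  list(canvas = canvas,
       truth = list(kind = "fibre_set", class_name = el$class_name,
                    count = el$n, fibres = fibres, label = label))
}

render_composite <- function(canvas, el, w, h) {
  pl <- place_discs(el$n, el$radius, el$rect, el$overlap, el$straddle,
                    el$tile_size, w, h)
  label <- matrix(0L, h, w)
  polys <- vector("list", el$n)
  for (k in seq_len(el$n)) {
    cx <- pl$centres[k, 1]; cy <- pl$centres[k, 2]; r <- pl$radii[k]
    px <- disc_pixels(cx, cy, r, w, h)
    idx <- cbind(px[, 2] + 1, px[, 1] + 1)
    label[idx] <- k
    d <- sqrt((px[, 1] + 0.5 - cx)^2 + (px[, 2] + 0.5 - cy)^2)
    rim <- d > r - el$rim_width
    ph <- stats::runif(2, 0, 2 * pi)
    interior <- el$interior_mean + el$interior_amplitude *
      sin(2 * pi * el$interior_freq * px[, 1] + ph[1]) *
      sin(2 * pi * el$interior_freq * px[, 2] + ph[2])
    vals <- ifelse(rim, el$rim_intensity, interior)
    canvas[cbind(idx, el$channel)] <- vals
    ang <- seq(0, 2 * pi, length.out = 65)[-65]
    polys[[k]] <- cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
  }
  list(canvas = canvas,
       truth = list(kind = "composite_object", class_name = el$class_name,
                    count = el$n, centres = pl$centres, radii = pl$radii,
                    label = label, polygons = polys))
}

#' Persist scene specs and ground truth
#'
#' Specs serialize to JSON; ground-truth label masks are written as 16-bit
#' TIFF and element outlines as a GeoJSON FeatureCollection.
#'
#' @param spec a [scene_spec].
#' @param path output file.
#' @export
write_scene_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  els <- lapply(x$elements, function(el)
    lapply(el, function(v) if (is.list(v)) unlist(v) else v))
  scene_spec(x$width, x$height, x$seed, x$background, x$noise_sd,
             x$channels, els)
}
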