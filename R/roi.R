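#' Effective region of interest
#'
#' Combines annotations (and an optional low-resolution exclusion class map)
#' into a single membership predicate over level-0 coordinates.  A point is in
#' the effective ROI iff (a) it lies in the union of all `roi` polygons (the
#' whole image when there are none), and (b) it is not excluded — where
#' excluded means inside an `exclusion` polygon or inside an exclusion-flagged
#' class of the upsampled exclusion mask — unless (c) it lies inside an
#' `inclusion` polygon, which always overrules exclusion.  Manual annotations
#' therefore have priority over the exclusion model, and inclusion has the
#' highest priority of all.
#'
#' The measured ROI area is the exact count of level-0 pixels (pixel-centre
#' rule, boundary pixels inside) where the predicate holds; classification or
#' segmentation masks applied downstream never change it.
#'
#' @param annotations list of [annotation()] objects (plain and junction
#'   annotations are ignored here).
#' @param width,height level-0 image size in pixels.
#' @param exclusion_mask optional `list(map, scale, exclude)`: an integer
#'   class map produced at a low-resolution level, the level-0 pixels per map
#'   pixel (`factor^level`), and the class indices flagged as exclusion.
#' @return a `region_predicate` object.
#' @export
effective_roi <- function(annotations = list(), width, height,
                          exclusion_mask = NULL) {
  ids <- unique(unlist(lapply(annotations, function(a) a$image_id)))
  if (length(ids) > 1L)
    stop("annotations reference more than one image: ",
         paste(ids, collapse = ", "))
  pick <- function(t) lapply(Filter(function(a) a$type == t, annotations),
                             function(a) a$coords)
  structure(list(width = as.integer(width), height = as.integer(height),
                 roi_polys = pick("roi"), excl_polys = pick("exclusion"),
                 incl_polys = pick("inclusion"),
                 exclusion_mask = exclusion_mask,
                 cache = new.env(parent = emptyenv())),
            class = "region_predicate")
}

#' @export
print.region_predicate <- function(x, ...) {
  cat(sprintf(
    "<region_predicate> %dx%d px; %d roi / %d exclusion / %d inclusion polygon(s)%s\n",
    x$width, x$height, length(x$roi_polys), length(x$excl_polys),
    length(x$incl_polys),
    if (is.null(x$exclusion_mask)) "" else "; exclusion model attached"))
  invisible(x)
}

#' Evaluate a region predicate
#'
#' `roi_contains` tests arbitrary points; `roi_mask` rasterizes the predicate
#' over a pixel block (used tile-wise by analyses); `roi_area` returns the
#' exact measured level-0 area.
#'
#' @param roi a `region_predicate` (or `NULL`, meaning everywhere active).
#' @param x,y numeric vectors of level-0 pixel coordinates (pixel indices;
#'   the pixel-centre at `+0.5` is tested).
#' @export
roi_contains <- function(roi, x, y) {
  if (is.null(roi)) return(rep(TRUE, length(x)))
  px <- x + 0.5; py <- y + 0.5
  any_poly <- function(polys) {
    out <- rep(FALSE, length(px))
    for (p in polys) out <- out | points_in_polygon(px, py, p)
    out
  }
  in_roi <- if (length(roi$roi_polys)) any_poly(roi$roi_polys)
            else rep(TRUE, length(px))
  in_roi <- in_roi & px >= 0 & px <= roi$width & py >= 0 & py <= roi$height
  excl <- any_poly(roi$excl_polys)
  if (!is.null(roi$exclusion_mask)) {
    m <- roi$exclusion_mask
    mi <- pmin(floor(y / m$scale) + 1L, nrow(m$map))
    mj <- pmin(floor(x / m$scale) + 1L, ncol(m$map))
    excl <- excl | (m$map[cbind(mi, mj)] %in% m$exclude)
  }
  incl <- any_poly(roi$incl_polys)
  in_roi & (incl | !excl)
}

#' @rdname roi_contains
#' @param origin 0-based `c(x, y)` of the block's top-left pixel (level-0).
#' @param width,height block size in pixels.
#' @export
roi_mask <- function(roi, origin = c(0, 0), width = NULL, height = NULL) {
  if (is.null(roi)) return(matrix(TRUE, height, width))
  width <- width %||% roi$width
  height <- height %||% roi$height
  rast <- function(polys) {
    out <- matrix(FALSE, height, width)
    for (p in polys) out <- out | rasterize_polygon(p, width, height, origin)
    out
  }
  in_roi <- if (length(roi$roi_polys)) rast(roi$roi_polys)
            else matrix(TRUE, height, width)
  # clip to image bounds
  xs <- origin[1] + seq_len(width) - 1L
  ys <- origin[2] + seq_len(height) - 1L
  in_roi[, xs < 0 | xs >= roi$width] <- FALSE
  in_roi[ys < 0 | ys >= roi$height, ] <- FALSE
  excl <- rast(roi$excl_polys)
  if (!is.null(roi$exclusion_mask)) {
    m <- roi$exclusion_mask
    mi <- pmin(pmax(floor(ys / m$scale), 0L) + 1L, nrow(m$map))
    mj <- pmin(pmax(floor(xs / m$scale), 0L) + 1L, ncol(m$map))
    excl <- excl | matrix(m$map[cbind(rep(mi, length(mj)),
                                      rep(mj, each = length(mi)))] %in%
                            m$exclude, height, width)
  }
  incl <- rast(roi$incl_polys)
  in_roi & (incl | !excl)
}

#' @rdname roi_contains
#' @export
roi_area <- function(roi) {
  if (is.null(roi)) stop("roi_area needs a region_predicate")
  if (!is.null(roi$cache$area)) return(roi$cache$area)
  area <- 0
  step <- 512L
  for (y0 in seq.int(0L, roi$height - 1L, by = step)) {
    hh <- min(step, roi$height - y0)
    area <- area + sum(roi_mask(roi, c(0L, y0), roi$width, hh))
  }
  roi$cache$area <- area
  area
}

# Does any active pixel of the predicate fall inside the given level-0 rect?
roi_intersects_rect <- function(roi, x0, y0, w, h) {
  if (is.null(roi)) return(TRUE)
  w <- min(w, roi$width - x0); h <- min(h, roi$height - y0)
  if (w <= 0 || h <= 0) return(FALSE)
  any(roi_mask(roi, c(x0, y0), w, h))
}

#' Pick the pyramid level for an exclusion model
#'
#' Exclusion models classify a low-resolution rendering of the slide of
#' roughly one megapixel; this returns the pyramid level whose total pixel
#' count is closest to 2^20, preferring the higher-resolution level on ties.
#'
#' @param image a [tiled_image].
#' @param target pixel-count target (default `2^20`).
#' @return 0-based level index.
#' @export
select_exclusion_level <- function(image, target = 2^20) {
  counts <- vapply(image$levels, function(a) prod(dim(a)[1:2]), numeric(1))
  which.min(abs(counts - target)) - 1L  # which.min takes the first (higher-res) tie
}

#' Nearest-neighbour mask upsampling
#'
#' Maps a low-resolution class map to a higher resolution; each full-
#' resolution pixel inherits the class of exactly one low-resolution pixel.
#'
#' @param mask integer class-map matrix.
#' @param scale integer upsampling factor.
#' @param width,height optional target size (defaults to `scale * dim(mask)`).
#' @export
upsample_mask <- function(mask, scale, width = NULL, height = NULL) {
  height <- height %||% (nrow(mask) * scale)
  width <- width %||% (ncol(mask) * scale)
  ri <- pmin(floor((seq_len(height) - 1L) / scale) + 1L, nrow(mask))
  ci <- pmin(floor((seq_len(width) - 1L) / scale) + 1L, ncol(mask))
  mask[ri, ci, drop = FALSE]
}
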