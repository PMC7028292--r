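# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Mirror (reflect-without-repeat) index lookup: 0-based index i into a
# dimension of size n, reflected with period 2n-2 so index -1 maps to 1 and
# index n maps to n-2.  Returns 1-based indices for R subsetting.
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  r <- i %% p
  r <- ifelse(r >= n, p - r, r)
  as.integer(r) + 1L
}

# Mirror-pad a matrix by `s` pixels on every side.
mirror_pad <- function(mat, s) {
  if (s == 0L) return(mat)
  ri <- reflect_idx(seq.int(-s, nrow(mat) - 1L + s), nrow(mat))
  ci <- reflect_idx(seq.int(-s, ncol(mat) - 1L + s), ncol(mat))
  mat[ri, ci, drop = FALSE]
}

# --- union-find over 1..n ----------------------------------------------------

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

# Flatten union-find roots for all elements.
uf_roots <- function(parent) {
  for (i in seq_along(parent)) parent[i] <- parent[parent[i]]
  # iterate until fixed point (paths are short after the loop above)
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  parent
}

# 8-connected labelling of a binary matrix.  EBImage::bwlabel is 4-connected;
# labels that touch diagonally are merged afterwards.
label8 <- function(bitmap) {
  lab <- EBImage::bwlabel(bitmap != 0)
  lab <- matrix(as.integer(round(lab)), nrow(bitmap), ncol(bitmap))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- uf_new(n)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (r, c) vs (r+1, c+1) and (r+1, c) vs (r, c+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs)))
      parent <- uf_union(parent, pairs[k, 1], pairs[k, 2])
  }
  roots <- uf_roots(parent)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# --- windowed statistics via integral images ---------------------------------

# Box-filter sums over a (2s+1)^2 window with mirror padding, as a separable
# shift-and-add (fixed offset order), so a pixel's window sum is the same
# float regardless of where the surrounding tile was cut.
box_sum <- function(mat, s) {
  if (s == 0L) return(mat)
  p <- mirror_pad(mat, s)
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- 0
  for (dy in 0:(2L * s))
    acc <- acc + p[seq_len(nr) + dy, , drop = FALSE]
  out <- 0
  for (dx in 0:(2L * s))
    out <- out + acc[, seq_len(nc) + dx, drop = FALSE]
  out
}

# Running min / max over the same window (separable, via shifted comparisons
# on the mirror-padded matrix).
window_extreme <- function(mat, s, op = c("min", "max")) {
  op <- match.arg(op)
  if (s == 0L) return(mat)
  p <- mirror_pad(mat, s)
  f <- if (op == "min") pmin else pmax
  nr <- nrow(mat); nc <- ncol(mat)
  # rows pass
  acc <- NULL
  for (dy in 0:(2L * s)) {
    sl <- p[seq_len(nr) + dy, , drop = FALSE]
    acc <- if (is.null(acc)) sl else f(acc, sl)
  }
  out <- NULL
  for (dx in 0:(2L * s)) {
    sl <- acc[, seq_len(nc) + dx, drop = FALSE]
    out <- if (is.null(out)) sl else f(out, sl)
  }
  out
}

# --- polygon rasterization ---------------------------------------------------

# Rasterize a simple polygon (n x 2 matrix of x,y vertices, level-0 continuous
# coordinates) onto a pixel block of size width x height whose top-left pixel
# is `origin` (0-based x,y).  Pixel (x, y) has centre (x + 0.5, y + 0.5);
# even-odd rule with half-open vertical spans so shared edges are not double
# counted, boundary pixels count as inside.
rasterize_polygon <- function(coords, width, height, origin = c(0, 0)) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  if (is.null(coords) || nrow(coords) < 3L) return(out)
  xs <- coords[, 1]; ys <- coords[, 2]
  n <- length(xs)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  keep <- ys != y2
  if (!any(keep)) return(out)
  ex1 <- xs[keep]; ey1 <- ys[keep]; ex2 <- x2[keep]; ey2 <- y2[keep]
  ylo <- pmin(ey1, ey2); yhi <- pmax(ey1, ey2)
  for (row in seq_len(height)) {
    yc <- origin[2] + row - 0.5
    hit <- ylo <= yc & yc < yhi
    if (!any(hit)) next
    xi <- ex1[hit] + (yc - ey1[hit]) * (ex2[hit] - ex1[hit]) / (ey2[hit] - ey1[hit])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      x0 <- ceiling(xi[k] - 0.5 - origin[1])
      x1 <- floor(xi[k + 1] - 0.5 - origin[1])
      x0 <- max(x0, 0); x1 <- min(x1, width - 1)
      if (x0 <= x1) out[row, (x0 + 1):(x1 + 1)] <- TRUE
    }
  }
  out
}

# Even-odd point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, coords) {
  xs <- coords[, 1]; ys <- coords[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_along(xs)) {
    if (ys[e] == y2[e]) next
    ylo <- min(ys[e], y2[e]); yhi <- max(ys[e], y2[e])
    hit <- ylo <= py & py < yhi
    if (!any(hit)) next
    xi <- xs[e] + (py[hit] - ys[e]) * (x2[e] - xs[e]) / (y2[e] - ys[e])
    inside[hit] <- xor(inside[hit], px[hit] <= xi)
  }
  inside
}

# Distance from points to a polyline (n x 2 vertex matrix), vectorized over
# points.  Returns the minimum distance over all segments.
points_polyline_distance <- function(px, py, line) {
  d2 <- rep(Inf, length(px))
  for (e in seq_len(nrow(line) - 1L)) {
    ax <- line[e, 1]; ay <- line[e, 2]
    bx <- line[e + 1L, 1]; by <- line[e + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
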