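# Internal geometry and raster helpers.
#
# Raster convention used throughout the package: images are numeric matrices
# m[y, x] with y (row) increasing downward and x (column) increasing
# rightward; pixel centers sit at integer coordinates, origin (1, 1) at the
# top-left pixel center.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(theta) c(cos(theta), sin(theta))

## Evaluate an expression with a temporary RNG state.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed and a stream index,
## kept inside the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483587)
}

## Coordinate grids for a height x width raster (pixel centers).
coord_grid <- function(height, width) {
  list(
    x = matrix(rep(seq_len(width), each = height), height, width),
    y = matrix(rep(seq_len(height), times = width), height, width)
  )
}

## Distance of every pixel center from a point (cx, cy).
radial_dist <- function(height, width, cx, cy) {
  dx <- seq_len(width) - cx
  dy <- seq_len(height) - cy
  sqrt(outer(dy^2, dx^2, `+`))
}

## Strip EBImage's Image class down to a plain matrix.
as_plain_matrix <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

## 8-neighbor count of foreground pixels in a logical/0-1 matrix.
neighbor_count <- function(m) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  n <- as_plain_matrix(EBImage::filter2(m, k, boundary = 0))
  round(n)
}

## Arc length of a polyline given as an n x 2 matrix (x, y).
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

## Moving-average smoothing of a polyline, window w (odd), ends shrunk.
smooth_polyline <- function(p, w) {
  n <- nrow(p)
  if (w <= 1 || n < 3) return(p)
  half <- floor(w / 2)
  out <- p
  cx <- c(0, cumsum(p[, 1])); cy <- c(0, cumsum(p[, 2]))
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    out[i, 1] <- (cx[b + 1] - cx[a]) / (b - a + 1)
    out[i, 2] <- (cy[b + 1] - cy[a]) / (b - a + 1)
  }
  # keep true endpoints so chords are unaffected
  out[1, ] <- p[1, ]
  out[n, ] <- p[n, ]
  out
}

## 8-connected component labelling. EBImage::bwlabel is 4-connected; here
## its components are merged across diagonal adjacencies with a union-find
## over component ids, giving exact 8-connectivity.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  l4 <- as_plain_matrix(EBImage::bwlabel(m))
  nl <- max(l4)
  if (nl <= 1) return(l4)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  h <- nrow(m); w <- ncol(m)
  for (d in list(c(-1, -1), c(-1, 1))) {
    a <- l4[max(1, 1 + d[1]):min(h, h + d[1]),
            max(1, 1 + d[2]):min(w, w + d[2])]
    b <- l4[max(1, 1 - d[1]):min(h, h - d[1]),
            max(1, 1 - d[2]):min(w, w - d[2])]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      prs <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(prs))) {
        ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- l4
  out[l4 > 0] <- compact[l4[l4 > 0]]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
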