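# Shared fixtures. Heavy scenes are built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

## Default synthetic scene at full scale (the segmentation-gate fixture).
gate_scene <- function() {
  if (is.null(.fixture_env$gate)) {
    .fixture_env$gate <- default_scene(seed = 0, size = 1024,
                                       noise_level = 0.02)
  }
  .fixture_env$gate
}

## Reduced-scale scene for cheaper structural tests.
small_scene <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- default_scene(seed = seed, size = 512,
                                         noise_level = 0.02)
  }
  .fixture_env[[key]]
}

## Horizontal band mask of given radius around row y0 (continuous band:
## pixel centers within `radius` of the centerline).
band_mask <- function(height, width, y0, radius) {
  yy <- matrix(seq_len(height), height, width)
  abs(yy - y0) <= radius
}

## Straight-vessel segment list for the rasterizer.
straight_segment <- function(x1, y1, x2, y2, radius, label = "artery",
                             step = 0.5) {
  n <- max(2, ceiling(sqrt((x2 - x1)^2 + (y2 - y1)^2) / step))
  t <- seq(0, 1, length.out = n)
  list(id = 1L, points = cbind(x1 + t * (x2 - x1), y1 + t * (y2 - y1)),
       radius = rep(radius, n), label = label, nodes = c(1L, 2L),
       flagged = FALSE)
}

## Y-shaped mask: parent from below into (cx, cy), daughters at +-half_deg
## around the upward parent axis, Murray-tapered calibers.
y_mask <- function(half_deg, r_parent = 5, size = 400, len = 130) {
  cx <- size / 2; cy <- size * 0.65
  r_child <- r_parent / 2^(1 / 3)
  a <- half_deg * pi / 180
  segs <- list(
    straight_segment(cx, cy + len * 0.9, cx, cy, r_parent),
    straight_segment(cx, cy, cx - len * sin(a), cy - len * cos(a), r_child),
    straight_segment(cx, cy, cx + len * sin(a), cy - len * cos(a), r_child)
  )
  rasterize_segments(segs, c(size, size))
}

## Semicircular polyline of radius r (arc/chord - 1 = pi/2 - 1).
semicircle_points <- function(r = 50, n = 2000) {
  t <- seq(0, pi, length.out = n)
  cbind(100 + r * cos(t), 100 + r * sin(t))
}

## Sierpinski triangle mask of side 2^k px.
sierpinski_mask <- function(k = 9) {
  n <- 2^k
  idx <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  keep <- bitwAnd(idx$y, idx$x) == 0
  m <- matrix(FALSE, n, n)
  m[cbind(idx$y[keep] + 1, idx$x[keep] + 1)] <- TRUE
  m
}
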