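## Raster rendering of synthetic fundus scenes.
##
## Vessels are rasterized as the exact set of pixel centers lying within the
## local radius of each segment's centerline polyline (per-edge point-to-
## segment distance with the radius interpolated along the edge). The truth
## masks are that set; image shading, illumination, and noise never touch
## the masks.

#' Merge several vessel graphs into one scene graph
#'
#' Node and segment ids are re-numbered to be unique; truth tables are
#' concatenated with the new ids.
#' @param graphs List of `vessel_graph` objects.
#' @return A single `vessel_graph`.
#' @export
merge_vessel_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  node_off <- 0L; seg_off <- 0L
  nodes <- list(); segments <- list(); st <- list(); bt <- list()
  for (g in graphs) {
    n <- g$nodes
    n$id <- n$id + node_off
    nodes[[length(nodes) + 1L]] <- n
    for (s in g$segments) {
      s$id <- s$id + seg_off
      s$nodes <- s$nodes + node_off
      segments[[s$id]] <- s
    }
    if (nrow(g$per_segment_truth)) {
      t1 <- g$per_segment_truth; t1$segment <- t1$segment + seg_off
      st[[length(st) + 1L]] <- t1
    }
    if (nrow(g$per_branch_truth)) {
      t2 <- g$per_branch_truth; t2$node <- t2$node + node_off
      bt[[length(bt) + 1L]] <- t2
    }
    node_off <- node_off + nrow(n)
    seg_off <- seg_off + length(g$segments)
  }
  structure(
    list(nodes = do.call(rbind, nodes), segments = segments,
         per_segment_truth = if (length(st)) do.call(rbind, st) else
           graphs[[1]]$per_segment_truth[0, ],
         per_branch_truth = if (length(bt)) do.call(rbind, bt) else
           graphs[[1]]$per_branch_truth[0, ]),
    class = "vessel_graph"
  )
}

## Rasterize a list of segments into a logical mask: pixel centers within
## the (linearly interpolated) local radius of any centerline edge.
rasterize_segments <- function(segments, dim) {
  h <- dim[1]; w <- dim[2]
  mask <- matrix(FALSE, h, w)
  for (s in segments) {
    p <- s$points; r <- s$radius
    if (any(r <= 0)) {
      stopf("rasterize: segment %s has a zero or negative radius", s$id)
    }
    n <- nrow(p)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      x1 <- p[i, 1]; y1 <- p[i, 2]; x2 <- p[i + 1, 1]; y2 <- p[i + 1, 2]
      r1 <- r[i]; r2 <- r[i + 1]; rmax <- max(r1, r2)
      xa <- max(1L, floor(min(x1, x2) - rmax)); xb <- min(w, ceiling(max(x1, x2) + rmax))
      ya <- max(1L, floor(min(y1, y2) - rmax)); yb <- min(h, ceiling(max(y1, y2) + rmax))
      if (xa > xb || ya > yb) next
      xs <- xa:xb; ys <- ya:yb
      X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      Y <- matrix(ys, length(ys), length(xs))
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx * vx + vy * vy
      t <- if (L2 > 0) clamp(((X - x1) * vx + (Y - y1) * vy) / L2, 0, 1) else 0
      dx <- X - (x1 + t * vx); dy <- Y - (y1 + t * vy)
      rl <- r1 + (r2 - r1) * t
      hit <- (dx * dx + dy * dy) <= rl * rl
      if (any(hit)) {
        sub <- mask[ys, xs, drop = FALSE]
        mask[ys, xs] <- sub | hit
      }
    }
  }
  mask
}

#' Render a synthetic fundus photograph with exact ground truth
#'
#' Stamps each tree's centerline into artery/vein masks (overlapping pixels
#' resolve to the vein, drawn on top), shades a disc-centered fundus image
#' (bright disc, brighter cup, darker vessels with veins darker than
#' arteries, smooth illumination gradient), adds Gaussian pixel noise, and
#' zeroes everything outside the visible fundus circle. The returned truth
#' is independent of the noise seed.
#'
#' @param trees Non-empty list of `vessel_graph` objects (artery and/or vein
#'   trees).
#' @param disc A [disc_spec()].
#' @param noise_level SD of additive Gaussian pixel noise on the 0–1 scale.
#' @param seed Seed for the pixel noise only.
#' @param frame `c(height, width)` of the raster.
#' @param eye `"OD"` or `"OS"` laterality metadata.
#' @param subject_id Identifier carried on the image.
#' @return `list(image = fundus_image, truth = ground_truth)`.
#' @export
render_fundus <- function(trees, disc, noise_level = 0.02, seed = 0L,
                          frame = c(1024, 1024), eye = "OD",
                          subject_id = "S1") {
  if (length(trees) == 0) stopf("render_fundus: empty tree list")
  stopifnot(inherits(disc, "disc_spec"))
  h <- frame[1]; w <- frame[2]
  graph <- merge_vessel_graphs(trees)

  art_segs <- Filter(function(s) s$label == "artery", graph$segments)
  vein_segs <- Filter(function(s) s$label == "vein", graph$segments)
  artery <- rasterize_segments(art_segs, frame)
  vein <- rasterize_segments(vein_segs, frame)
  artery <- artery & !vein            # vein drawn on top at crossings
  vessel <- artery | vein

  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  vis_r <- min(h, w) / 2
  dcen <- radial_dist(h, w, cx, cy)
  roi <- dcen <= vis_r

  ddisc <- radial_dist(h, w, disc$center[1], disc$center[2])
  in_disc <- ddisc <= disc$disc_radius
  in_cup <- ddisc <= disc$cup_radius

  gx <- matrix(seq_len(w), h, w, byrow = TRUE)
  illum <- 1 - 0.25 * (dcen / vis_r)^2 + 0.06 * (gx - cx) / w

  base <- list(R = 0.80, G = 0.52, B = 0.25)
  cols <- list(
    disc = c(0.93, 0.87, 0.60), cup = c(1.00, 0.96, 0.78),
    artery = c(0.72, 0.33, 0.18), vein = c(0.45, 0.15, 0.10)
  )
  chan <- list(R = matrix(base$R, h, w), G = matrix(base$G, h, w),
               B = matrix(base$B, h, w))
  for (k in 1:3) {
    nm <- c("R", "G", "B")[k]
    chan[[nm]][in_disc] <- cols$disc[k]
    chan[[nm]][in_cup] <- cols$cup[k]
    chan[[nm]][artery] <- cols$artery[k]
    chan[[nm]][vein] <- cols$vein[k]
    chan[[nm]] <- chan[[nm]] * illum
  }
  with_rng(seed, {
    for (nm in c("R", "G", "B")) {
      if (noise_level > 0) {
        chan[[nm]] <- chan[[nm]] +
          matrix(stats::rnorm(h * w, 0, noise_level), h, w)
      }
      chan[[nm]] <- clamp(chan[[nm]], 0, 1)
      chan[[nm]][!roi] <- 0
    }
  })
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- chan$R; px[, , 2] <- chan$G; px[, , 3] <- chan$B

  image <- structure(
    list(pixels = px, pixel_pitch = disc$pixel_pitch, eye = eye,
         subject_id = subject_id),
    class = "fundus_image"
  )
  truth <- structure(
    list(vessel_mask = vessel, artery_mask = artery, vein_mask = vein,
         disc = disc, graph = graph,
         per_segment_truth = graph$per_segment_truth,
         per_branch_truth = graph$per_branch_truth),
    class = "ground_truth"
  )
  list(image = image, truth = truth)
}

#' Default synthetic fundus scene
#'
#' Eight-tree (four artery, four vein) disc-centered scene emulating the
#' superior/inferior temporal arcades and nasal radial vessels of a
#' 45-degree fundus photograph. `size` scales the whole geometry (disc
#' radius, trunk lengths and calibers in px) while the pixel pitch scales
#' inversely, so physical (µm / mm²) truth is size-invariant.
#'
#' @param seed Scene seed (tree geometry and image noise derive from it).
#' @param size Frame side in px (default 1024).
#' @param noise_level Pixel noise SD.
#' @param eye `"OD"` or `"OS"`; flips the nasal side.
#' @param tree Optional [tree_spec()] overriding the default tree
#'   parameters (calibers are interpreted at `size = 1024` scale).
#' @param disc Optional [disc_spec()] overriding the default disc.
#' @param subject_id Identifier carried on the image.
#' @return `list(image, truth)` as [render_fundus()].
#' @export
default_scene <- function(seed = 0L, size = 1024, noise_level = 0.02,
                          eye = "OD", tree = NULL, disc = NULL,
                          subject_id = "S1") {
  sc <- size / 1024
  mirror <- if (eye == "OD") 1 else -1
  disc <- disc %||% disc_spec(
    center = c((size + 1) / 2 + mirror * 0.10 * size, (size + 1) / 2),
    disc_radius = 87 * sc, cup_radius = 42.5 * sc, pixel_pitch = 10 / sc
  )
  tree <- tree %||% tree_spec(
    trunk_caliber_artery = 10 * sc, trunk_caliber_vein = 13 * sc,
    tortuosity_amplitude = 3 * sc, tortuosity_wavelength = 60 * sc,
    min_caliber = 2.6 * sc
  )
  # temporal arcades (up/down) and nasal radials; temporal is opposite the
  # nasal side, which is +x for OD and -x for OS
  base_angles <- c(-2.45, 2.45, -0.75, 0.75)
  if (mirror < 0) base_angles <- pi - base_angles
  trees <- list(); k <- 0L
  for (i in seq_along(base_angles)) {
    for (kind in c("vein", "artery")) {
      k <- k + 1L
      off <- if (kind == "artery") 0.22 else -0.22
      sp <- tree
      sp$seed <- child_seed(seed, k)
      trees[[k]] <- generate_tree(sp, disc, kind,
                                  root_angle = base_angles[i] + off,
                                  frame = c(size, size))
    }
  }
  render_fundus(trees, disc, noise_level = noise_level,
                seed = child_seed(seed, 999), frame = c(size, size),
                eye = eye, subject_id = subject_id)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %dx%d px, pitch %.3g um/px, eye %s, %s>\n",
              d[2], d[1], x$pixel_pitch, x$eye, x$subject_id))
  invisible(x)
}
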