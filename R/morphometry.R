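## The nine morphometric parameters measured from a vessel graph, masks,
## and disc geometry: VDf, VC, VT, VD, VBA, AVR, disc area, cup area, C/D.

#' Vessel caliber of one segment (µm)
#'
#' Width at each interior centerline point is twice the local radius; the
#' segment caliber is the mean width times the pixel pitch. Points within
#' `node_excl` px of the segment ends (where the distance transform is
#' contaminated by the junction) are excluded, as are points outside
#' `region` when one is given.
#'
#' @param segment A segment of a `vessel_graph`.
#' @param pitch Pixel pitch in µm/px.
#' @param region Optional logical matrix restricting qualifying points.
#' @param node_excl Exclusion distance from the segment ends (px).
#' @return Caliber in µm, or `NA` (with a message) if fewer than 3 points
#'   qualify.
#' @export
measure_caliber <- function(segment, pitch, region = NULL, node_excl = 2) {
  p <- segment$points; r <- segment$radius
  n <- nrow(p)
  if (n < 3) return(NA_real_)
  d_start <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
  d_end <- sqrt((p[, 1] - p[n, 1])^2 + (p[, 2] - p[n, 2])^2)
  keep <- d_start > node_excl & d_end > node_excl
  if (!is.null(region)) {
    iy <- clamp(round(p[, 2]), 1, nrow(region))
    ix <- clamp(round(p[, 1]), 1, ncol(region))
    keep <- keep & region[cbind(iy, ix)]
  }
  if (sum(keep) < 3) {
    message(sprintf("caliber: segment %s skipped (%d qualifying points)",
                    segment$id, sum(keep)))
    return(NA_real_)
  }
  mean(2 * r[keep]) * pitch
}

#' Vessel tortuosity of one segment
#'
#' Arc length over chord length minus one; 0 for a straight path. On exact
#' polylines the ratio is computed directly. For raster-traced centerlines
#' the digitization staircase inflates the arc length by far more than the
#' true tortuosity signal; `lowpass` applies a sharp spectral low-pass
#' (cut-off wavelength in px, even-extension FFT of both coordinates as
#' functions of arc length) that removes sub-resolution wiggle without
#' attenuating resolvable curvature, and the ratio is then computed on the
#' filtered curve. Alternatively `smooth` applies a plain moving average.
#'
#' @param segment Segment of a `vessel_graph`, or an n x 2 point matrix.
#' @param smooth Moving-average window (points); 0 disables.
#' @param lowpass Spectral cut-off wavelength (px); 0 disables. Takes
#'   precedence over `smooth`.
#' @return Dimensionless tortuosity (reported elsewhere as x 10^-3), or
#'   `NA` for a degenerate (closed) segment.
#' @export
measure_tortuosity <- function(segment, smooth = 0, lowpass = 0) {
  p <- if (is.matrix(segment)) segment else segment$points
  if (nrow(p) < 3) return(NA_real_)
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord < 1e-9) {
    message("tortuosity: zero chord (closed segment) skipped")
    return(NA_real_)
  }
  if (lowpass > 0) {
    # a segment cannot carry resolvable wiggle longer than half its length
    p <- .lowpass_curve(p, min(lowpass, polyline_length(p) / 2))
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    if (chord < 1e-9) return(NA_real_)
  } else if (smooth > 1) {
    p <- smooth_polyline(p, smooth)
  }
  polyline_length(p) / chord - 1
}

## Sharp low-pass of a polyline: resample to ~1 px spacing in arc length,
## even-extend both coordinates, zero Fourier components with wavelength
## below lam_c, invert.
.lowpass_curve <- function(p, lam_c) {
  n0 <- nrow(p)
  d <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                   p[-n0, , drop = FALSE])^2))))
  keep <- c(TRUE, diff(d) > 1e-9)
  p <- p[keep, , drop = FALSE]; d <- d[keep]
  L <- d[length(d)]
  if (L < 4 || nrow(p) < 4) return(p)
  n <- max(32, ceiling(L))
  s <- seq(0, L, length.out = n)
  filt <- function(v) {
    vi <- stats::approx(d, v, xout = s)$y
    ve <- c(vi, rev(vi)); m <- length(ve)
    V <- stats::fft(ve)
    freq <- pmin(0:(m - 1), m - (0:(m - 1)))
    lam <- (2 * L) / pmax(freq, 1e-9)
    V[freq > 0 & lam < lam_c] <- 0
    Re(stats::fft(V, inverse = TRUE))[1:n] / m
  }
  cbind(filt(p[, 1]), filt(p[, 2]))
}

#' Vascular branching angle at a bifurcation (degrees)
#'
#' At a degree-3 node a least-squares line is fitted to each incident
#' branch's centerline points within `fit_radius` px of the node, oriented
#' away from the node; the two daughters are the pair of branches whose
#' directions enclose the smallest mutual angle (the parent runs roughly
#' opposite both daughters at a vascular bifurcation), and the branching
#' angle is the angle between the two daughter lines. Points inside the
#' junction blob itself (closer to the node than the local vessel radius
#' plus one pixel) are excluded from the fits: there the medial skeleton
#' bends between the daughters and carries no direction information.
#' Crossings (degree >= 4) and under-sampled branches are excluded.
#'
#' @param graph A `vessel_graph`.
#' @param node_id Node id of the bifurcation.
#' @param disc Optional [disc_spec()] or disc ellipse; when given, only
#'   bifurcations within 2 PD of the disc center qualify.
#' @param fit_radius Fit neighborhood around the node (px).
#' @param min_pts Minimum centerline points per daughter within the
#'   neighborhood.
#' @param max_pd Peripapillary limit in PD units (bifurcations farther
#'   from the disc center are skipped); `Inf` disables the limit.
#' @return Angle in degrees in (0, 180], or `NA` if the node does not
#'   qualify.
#' @export
measure_branch_angle <- function(graph, node_id, disc = NULL,
                                 fit_radius = 10, min_pts = 3, max_pd = 2) {
  nd <- graph$nodes[graph$nodes$id == node_id, ]
  if (nrow(nd) != 1 || nd$degree != 3) return(NA_real_)
  if (!is.null(disc) && is.finite(max_pd)) {
    ctr <- if (inherits(disc, "disc_spec")) disc$center else
      c(disc$cx, disc$cy)
    pd <- if (inherits(disc, "disc_spec")) 2 * disc$disc_radius else
      disc_diameter_pd(disc)
    if (sqrt(sum((c(nd$x, nd$y) - ctr)^2)) > max_pd * pd) return(NA_real_)
  }
  inc <- Filter(function(s) any(s$nodes == node_id), graph$segments)
  if (length(inc) != 3) return(NA_real_)
  dirs <- lapply(inc, function(s) {
    p <- s$points
    d <- sqrt((p[, 1] - nd$x)^2 + (p[, 2] - nd$y)^2)
    # radius at the node end of this branch = junction blob half-width
    r_node <- s$radius[which.min(d)]
    lo <- r_node + 1
    near <- p[d > lo & d <= lo + fit_radius, , drop = FALSE]
    if (nrow(near) < min_pts) return(NULL)
    .fit_direction(near, c(nd$x, nd$y))
  })
  if (any(vapply(dirs, is.null, logical(1)))) return(NA_real_)
  dots <- c(sum(dirs[[1]] * dirs[[2]]), sum(dirs[[1]] * dirs[[3]]),
            sum(dirs[[2]] * dirs[[3]]))
  widths <- vapply(inc, function(s) mean(s$radius), numeric(1))
  rk <- order(widths, decreasing = TRUE)
  if (widths[rk[1]] >= 1.15 * widths[rk[2]]) {
    # Murray taper makes the parent distinctly wider at near-symmetric
    # splits; trust the widths (works at arbitrarily wide branch angles)
    pair <- rk[2:3]
  } else {
    # arcade-style splits leave parent and main daughter near-equal; the
    # daughters are then the pair with the smallest mutual angle
    pair <- list(c(1, 2), c(1, 3), c(2, 3))[[which.max(dots)]]
  }
  parent <- dirs[[setdiff(1:3, pair)]]
  # sanity: at a real bifurcation the parent runs against both daughters;
  # merged junction clusters and crossings fail this and are skipped
  if (sum(parent * dirs[[pair[1]]]) > 0 ||
        sum(parent * dirs[[pair[2]]]) > 0) {
    return(NA_real_)
  }
  rad2deg(acos(clamp(sum(dirs[[pair[1]]] * dirs[[pair[2]]]), -1, 1)))
}

## Principal direction of points, oriented away from the node.
.fit_direction <- function(p, node) {
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  C <- crossprod(pc) / nrow(p)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(v * (ctr - node)) < 0) v <- -v
  v
}

#' Vascular density in a region
#'
#' Fraction of region pixels occupied by vessel mask pixels.
#' @param mask Logical vessel mask.
#' @param region Logical region matrix (same dim); `NULL` = whole frame.
#' @return Density in `[0, 1]`.
#' @export
vessel_density <- function(mask, region = NULL) {
  if (is.null(region)) region <- matrix(TRUE, nrow(mask), ncol(mask))
  np <- sum(region)
  if (np == 0) stopf("vessel_density: empty region")
  sum(mask & region) / np
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes of the region-clipped mask at dyadic box sizes and
#' returns the negative slope of the least-squares line of `log N(s)` vs
#' `log s`. The grid is anchored at the raster origin (deterministic; no
#' multi-offset averaging).
#'
#' @param mask Logical mask.
#' @param region Optional logical region clip.
#' @param sizes Box sizes (px); default dyadic `2, 4, ...` up to a quarter
#'   of the smaller image side.
#' @return Fractal dimension (about 1 for a curve, 2 for a filled region).
#' @export
fractal_dimension <- function(mask, region = NULL, sizes = NULL) {
  m <- mask
  if (!is.null(region)) m <- m & region
  if (is.null(sizes)) {
    smax <- min(dim(m)) / 4
    sizes <- 2^(1:floor(log2(smax)))
  }
  sizes <- sizes[sizes >= 2 & sizes <= min(dim(m))]
  if (length(sizes) < 3) stopf("fractal_dimension: insufficient scales")
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("fractal_dimension: empty mask")
  counts <- vapply(sizes, function(s) {
    by <- (idx[, 1] - 1) %/% s
    bx <- (idx[, 2] - 1) %/% s
    length(unique(by * (ncol(m) %/% s + 2) + bx))
  }, numeric(1))
  if (counts[which.max(sizes)] < 2) {
    stopf("fractal_dimension: fewer than 2 occupied boxes at the largest scale")
  }
  fit <- stats::lm.fit(cbind(1, log(sizes)), log(counts))
  -unname(fit$coefficients[2])
}

#' Arteriole-to-venule ratio
#'
#' Length-weighted mean artery caliber over length-weighted mean vein
#' caliber; weighting is by centerline points (uniform spacing), with the
#' same interior-point exclusion as [measure_caliber()].
#'
#' @param graph Labelled `vessel_graph`.
#' @param pitch Pixel pitch (µm/px); cancels in the ratio but keeps the
#'   intermediate calibers in reported units.
#' @param region Optional logical region restriction.
#' @param min_len Minimum segment arc length (px) to contribute.
#' @return AVR, or `NA` (with a message) if either class is absent.
#' @export
arteriole_venule_ratio <- function(graph, pitch = 1, region = NULL,
                                   min_len = 10) {
  acc <- list(artery = c(sum = 0, n = 0), vein = c(sum = 0, n = 0))
  for (s in graph$segments) {
    if (!s$label %in% c("artery", "vein")) next
    if (polyline_length(s$points) < min_len) next
    w <- .interior_widths(s, region)
    if (length(w) == 0) next
    acc[[s$label]]["sum"] <- acc[[s$label]]["sum"] + sum(w)
    acc[[s$label]]["n"] <- acc[[s$label]]["n"] + length(w)
  }
  if (acc$artery["n"] == 0 || acc$vein["n"] == 0) {
    message("AVR undefined: missing artery or vein segments")
    return(NA_real_)
  }
  unname((acc$artery[["sum"]] / acc$artery[["n"]]) /
           (acc$vein[["sum"]] / acc$vein[["n"]]))
}

.interior_widths <- function(s, region = NULL, node_excl = 2) {
  p <- s$points; r <- s$radius; n <- nrow(p)
  if (n < 3) return(numeric(0))
  d_start <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
  d_end <- sqrt((p[, 1] - p[n, 1])^2 + (p[, 2] - p[n, 2])^2)
  keep <- d_start > node_excl & d_end > node_excl
  if (!is.null(region)) {
    iy <- clamp(round(p[, 2]), 1, nrow(region))
    ix <- clamp(round(p[, 1]), 1, ncol(region))
    keep <- keep & region[cbind(iy, ix)]
  }
  2 * r[keep]
}

#' Optic disc and cup areas and cup-to-disc ratio
#'
#' Ellipse areas converted to mm² via the pixel pitch; C/D is the area
#' ratio.
#' @param disc_ellipse,cup_ellipse Ellipses `list(cx, cy, a, b, theta)`
#'   (semi-axes px).
#' @param pitch Pixel pitch in µm/px.
#' @return Named vector `disc_area_mm2`, `cup_area_mm2`, `cdr`.
#' @export
disc_cup_metrics <- function(disc_ellipse, cup_ellipse, pitch) {
  if (!.ellipse_contained(cup_ellipse, disc_ellipse)) {
    stopf("disc_cup_metrics: cup ellipse not contained in disc ellipse")
  }
  f <- (pitch / 1000)^2
  da <- pi * disc_ellipse$a * disc_ellipse$b * f
  ca <- pi * cup_ellipse$a * cup_ellipse$b * f
  c(disc_area_mm2 = da, cup_area_mm2 = ca, cdr = ca / da)
}

## Sampled-boundary containment with a small numerical tolerance.
.ellipse_contained <- function(inner, outer, tol = 0.02, n = 90) {
  tt <- seq(0, 2 * pi, length.out = n)
  px <- inner$cx + inner$a * cos(tt) * cos(inner$theta) -
    inner$b * sin(tt) * sin(inner$theta)
  py <- inner$cy + inner$a * cos(tt) * sin(inner$theta) +
    inner$b * sin(tt) * cos(inner$theta)
  dx <- px - outer$cx; dy <- py - outer$cy
  u <- dx * cos(outer$theta) + dy * sin(outer$theta)
  v <- -dx * sin(outer$theta) + dy * cos(outer$theta)
  all((u / outer$a)^2 + (v / outer$b)^2 <= (1 + tol)^2)
}

#' Compute all nine parameters for one eye, per scope
#'
#' Evaluates the morphometric parameters globally (within the fundus ROI)
#' and in the four peripapillary annuli and four quadrants. Disc metrics
#' are global-only; branching angles additionally respect the 2-PD limit
#' around the disc.
#'
#' @param masks List with `vessel_mask` (and optionally `artery_mask`,
#'   `vein_mask`).
#' @param graph Labelled `vessel_graph`.
#' @param disc_ellipse,cup_ellipse Fitted ellipses (px).
#' @param pitch Pixel pitch in µm/px.
#' @param eye `"OD"` or `"OS"` (orients the nasal/temporal quadrants).
#' @param roi_mask Optional logical fundus ROI (global scope); defaults to
#'   the full frame.
#' @param min_seg_len Minimum segment length (px) entering caliber and
#'   tortuosity.
#' @param tort_lowpass Spectral cut-off wavelength (px) for raster
#'   tortuosity (see [measure_tortuosity()]).
#' @return Data frame, one row per scope (`global`, annuli, quadrants) with
#'   columns `vdf`, `vc_um`, `vt`, `vd`, `vba_deg`, `avr`, `disc_area_mm2`,
#'   `cup_area_mm2`, `cdr` (`NA` where undefined).
#' @export
compute_metrics <- function(masks, graph, disc_ellipse, cup_ellipse, pitch,
                            eye = "OD", roi_mask = NULL, min_seg_len = 10,
                            tort_lowpass = 20) {
  mask <- masks$vessel_mask
  dimm <- dim(mask)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dimm[1], dimm[2])
  zones <- peripapillary_zones(disc_ellipse, eye, dimm)
  scopes <- c(list(global = roi_mask), zones)

  # per-segment quantities computed once
  segs <- Filter(function(s) polyline_length(s$points) >= min_seg_len,
                 graph$segments)
  seg_tort <- vapply(segs, function(s) {
    t <- suppressMessages(measure_tortuosity(s, lowpass = tort_lowpass))
    if (is.na(t)) -1 else t
  }, numeric(1))
  bif_ids <- graph$nodes$id[graph$nodes$degree == 3]

  dc <- tryCatch(disc_cup_metrics(disc_ellipse, cup_ellipse, pitch),
                 error = function(e) c(disc_area_mm2 = NA_real_,
                                       cup_area_mm2 = NA_real_,
                                       cdr = NA_real_))

  rows <- lapply(names(scopes), function(nm) {
    reg <- scopes[[nm]]
    vd <- if (sum(reg) > 0) vessel_density(mask, reg) else NA_real_
    vdf <- tryCatch(fractal_dimension(mask, reg), error = function(e) NA_real_)
    # caliber: interior widths restricted to the region
    wsum <- 0; wn <- 0
    tsum <- 0; tlen <- 0
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      wts <- .interior_widths(s, reg)
      if (length(wts)) { wsum <- wsum + sum(wts); wn <- wn + length(wts) }
      if (seg_tort[k] >= 0) {
        # weight = arc length of the portion inside the region
        iy <- clamp(round(s$points[, 2]), 1, dimm[1])
        ix <- clamp(round(s$points[, 1]), 1, dimm[2])
        lin <- sum(reg[cbind(iy, ix)])
        if (lin > 1) {
          tsum <- tsum + seg_tort[k] * lin
          tlen <- tlen + lin
        }
      }
    }
    vc <- if (wn >= 3) (wsum / wn) * pitch else NA_real_
    vt <- if (tlen > 0) tsum / tlen else NA_real_
    # branching angles with nodes inside the region (and within 2 PD)
    angs <- vapply(bif_ids, function(id) {
      nd <- graph$nodes[graph$nodes$id == id, ]
      iy <- clamp(round(nd$y), 1, dimm[1]); ix <- clamp(round(nd$x), 1, dimm[2])
      if (!reg[iy, ix]) return(NA_real_)
      measure_branch_angle(graph, id, disc = disc_ellipse)
    }, numeric(1))
    angs <- angs[!is.na(angs)]
    vba <- if (length(angs) > 0) mean(angs) else NA_real_
    avr <- suppressMessages(arteriole_venule_ratio(graph, pitch, reg,
                                                   min_len = min_seg_len))
    data.frame(scope = nm, vdf = vdf, vc_um = vc, vt = vt, vd = vd,
               vba_deg = vba, avr = avr,
               disc_area_mm2 = if (nm == "global") dc[["disc_area_mm2"]] else NA_real_,
               cup_area_mm2 = if (nm == "global") dc[["cup_area_mm2"]] else NA_real_,
               cdr = if (nm == "global") dc[["cdr"]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
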