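## Synthetic vascular tree generator.
##
## Trees are recursive bifurcating structures rooted at the optic disc
## border. Segment centerlines are straight base paths plus a windowed
## sinusoidal perpendicular perturbation whose displacement and slope vanish
## at both segment ends, so bifurcation positions and daughter take-off
## directions are exactly the base geometry while interior points carry a
## controlled, quadrature-computable tortuosity.

# internal constants of the arcade-style growth model: asymmetric Murray
# splits (a continuing main branch plus a side twig), child segment length
# scaling with flow share, so total vessel width per annulus declines
# outward as in real peripapillary vasculature
.tree_u_lo <- 0.12           # twig flow share, lower bound
.tree_u_hi <- 0.28           # twig flow share, upper bound
.tree_len_base <- 0.55       # child length = parent length * (base + gain * flow)
.tree_len_gain <- 0.55
.tree_seg_taper <- 0.95      # within-segment caliber factor (end / start)
.tree_min_seg <- 5           # px; drop truncated stubs shorter than this

#' Generate one synthetic vessel tree
#'
#' Grows a bifurcating artery or vein tree rooted on the optic disc border.
#' Daughter calibers obey the Murray-type conservation
#' `parent^e = c1^e + c2^e` exactly; the recorded truth angle at each
#' bifurcation equals the angle between the daughter take-off directions.
#'
#' @param spec A [tree_spec()].
#' @param disc A [disc_spec()]; the root sits on the disc border.
#' @param kind `"artery"` or `"vein"` (selects the trunk caliber).
#' @param root_angle Direction (radians, y downward) in which the trunk
#'   leaves the disc; default radially outward to the image's temporal side.
#' @param frame Raster frame `c(height, width)` in px; segments leaving the
#'   visible fundus circle inscribed in the frame are truncated there,
#'   flagged, and excluded from the truth tables.
#' @return A `vessel_graph`: `nodes` (id, x, y, degree, kind), `segments`
#'   (ordered centerline points, per-point radius, label), plus truth tables
#'   `per_segment_truth` (true caliber and tortuosity of every unflagged
#'   segment) and `per_branch_truth` (true angle at every bifurcation).
#' @export
generate_tree <- function(spec, disc, kind = c("artery", "vein"),
                          root_angle = 0, frame = c(1024, 1024)) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "tree_spec"), inherits(disc, "disc_spec"))
  h <- frame[1]; w <- frame[2]
  if (disc$center[1] < 1 || disc$center[1] > w ||
        disc$center[2] < 1 || disc$center[2] > h) {
    stopf("generate_tree: disc center outside the image frame")
  }
  # visible region: fundus circle inscribed in the frame, small safety margin
  vis_c <- c((w + 1) / 2, (h + 1) / 2)
  vis_r <- min(h, w) / 2 - 2

  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$segments <- list()
  env$seg_truth <- list(); env$branch_truth <- list()
  env$next_node <- 1L; env$next_seg <- 1L

  trunk_cal <- if (kind == "artery") spec$trunk_caliber_artery else
    spec$trunk_caliber_vein
  trunk_len <- spec$trunk_length %||% (0.5 * disc$disc_radius)

  add_node <- function(x, y, kind) {
    id <- env$next_node; env$next_node <- id + 1L
    env$nodes[[id]] <- list(id = id, x = x, y = y, degree = 0L, kind = kind)
    id
  }
  with_rng(spec$seed, {
    root <- disc$center + disc$disc_radius * unit_vec(root_angle)
    root_id <- add_node(root[1], root[2], "endpoint")
    grow_branch(env, spec, kind, root, root_angle, trunk_len, trunk_cal,
                1L, root_id, vis_c, vis_r)
  })

  nodes <- do.call(rbind, lapply(env$nodes, function(n) {
    data.frame(id = n$id, x = n$x, y = n$y, degree = n$degree,
               kind = if (n$degree >= 3) "bifurcation" else "endpoint",
               stringsAsFactors = FALSE)
  }))
  seg_truth <- if (length(env$seg_truth)) {
    do.call(rbind, env$seg_truth)
  } else {
    data.frame(segment = integer(), label = character(),
               caliber_px = numeric(), tortuosity = numeric(),
               length_px = numeric())
  }
  branch_truth <- if (length(env$branch_truth)) {
    do.call(rbind, env$branch_truth)
  } else {
    data.frame(node = integer(), angle_deg = numeric(),
               label = character())
  }
  structure(
    list(nodes = nodes, segments = env$segments,
         per_segment_truth = seg_truth, per_branch_truth = branch_truth),
    class = "vessel_graph"
  )
}

## Recursive growth of one branch and its descendants.
grow_branch <- function(env, spec, kind, start, theta, len, caliber,
                        level, start_node, vis_c, vis_r) {
  # truncate the base path at the visible-circle boundary
  smax <- .visible_extent(start, theta, len, vis_c, vis_r)
  flagged <- smax < len
  if (smax < .tree_min_seg) return(invisible(NULL))
  len_eff <- smax

  phase <- stats::runif(1, 0, 2 * pi)
  pts <- .perturbed_path(start, theta, len_eff, spec$tortuosity_amplitude,
                         spec$tortuosity_wavelength, phase, step = 1)
  end <- pts[nrow(pts), ]
  end_id <- local({
    id <- env$next_node; env$next_node <- id + 1L
    env$nodes[[id]] <- list(id = id, x = end[1], y = end[2],
                            degree = 0L, kind = "endpoint")
    id
  })
  seg_id <- env$next_seg; env$next_seg <- seg_id + 1L
  # vessels taper continuously: caliber falls linearly to .tree_seg_taper
  # of its starting value over the segment
  cal_end <- caliber * (1 - (1 - .tree_seg_taper) * len_eff / len)
  radii <- seq(caliber, cal_end, length.out = nrow(pts)) / 2
  env$segments[[seg_id]] <- list(
    id = seg_id, points = pts, radius = radii,
    label = kind, nodes = c(start_node, end_id), flagged = flagged
  )
  env$nodes[[start_node]]$degree <- env$nodes[[start_node]]$degree + 1L
  env$nodes[[end_id]]$degree <- env$nodes[[end_id]]$degree + 1L

  if (!flagged) {
    # truth tortuosity by fine quadrature of the same perturbed path
    dense <- .perturbed_path(start, theta, len_eff,
                             spec$tortuosity_amplitude,
                             spec$tortuosity_wavelength, phase,
                             step = len_eff / 4000)
    tort <- polyline_length(dense) / len_eff - 1
    env$seg_truth[[length(env$seg_truth) + 1L]] <- data.frame(
      segment = seg_id, label = kind,
      caliber_px = (caliber + cal_end) / 2,   # mean of the linear profile
      tortuosity = tort, length_px = len_eff, stringsAsFactors = FALSE
    )
  }

  if (flagged || level >= spec$depth) return(invisible(NULL))

  # Murray split: flow fractions u (side twig) and 1-u (main branch) give
  # exact caliber conservation parent_end^e = c1^e + c2^e at the junction
  e <- spec$taper_exponent
  u <- stats::runif(1, .tree_u_lo, .tree_u_hi)
  c1 <- cal_end * u^(1 / e)
  c2 <- cal_end * (1 - u)^(1 / e)
  if (max(c1, c2) < spec$min_caliber) return(invisible(NULL))

  A <- deg2rad(clamp(stats::rnorm(1, spec$branch_angle_mean,
                                  spec$branch_angle_sd), 5, 175))
  side <- sample(c(-1, 1), 1)
  # wider daughter (larger flow share) deviates less from the parent axis
  d1 <- A * (1 - u); d2 <- A * u
  th1 <- theta + side * d1
  th2 <- theta - side * d2
  env$branch_truth[[length(env$branch_truth) + 1L]] <- data.frame(
    node = env$segments[[seg_id]]$nodes[2], angle_deg = rad2deg(A),
    label = kind, stringsAsFactors = FALSE
  )

  end_node <- env$segments[[seg_id]]$nodes[2]
  end <- env$segments[[seg_id]]$points[nrow(env$segments[[seg_id]]$points), ]
  for (br in list(list(th = th1, cal = c1, flow = u),
                  list(th = th2, cal = c2, flow = 1 - u))) {
    if (br$cal >= spec$min_caliber) {
      child_len <- len * (.tree_len_base + .tree_len_gain * br$flow)
      grow_branch(env, spec, kind, end, br$th, child_len, br$cal,
                  level + 1L, end_node, vis_c, vis_r)
    }
  }
  invisible(NULL)
}

## Largest s in [0, len] with start + s * u inside the visible circle.
.visible_extent <- function(start, theta, len, vis_c, vis_r) {
  u <- unit_vec(theta)
  p0 <- start - vis_c
  # |p0 + s u|^2 = vis_r^2  =>  s^2 + 2 (p0.u) s + |p0|^2 - r^2 = 0
  b <- sum(p0 * u); c0 <- sum(p0^2) - vis_r^2
  if (c0 >= 0) return(0)            # starts outside
  disc <- b^2 - c0
  s_exit <- -b + sqrt(disc)         # positive root
  min(len, s_exit)
}

## Base straight path plus windowed sinusoidal perpendicular perturbation.
## The sin^4 window zeroes the displacement and keeps it negligible over
## the first ~15 px at both ends, so endpoints and take-off directions are
## the base geometry not just instantaneously but over the neighborhood a
## branch-angle fit uses.
.perturbed_path <- function(start, theta, len, amplitude, wavelength,
                            phase, step) {
  s <- unique(c(seq(0, len, by = step), len))
  u <- unit_vec(theta)
  nrm <- c(-u[2], u[1])
  off <- if (amplitude > 0) {
    amplitude * sin(2 * pi * s / wavelength + phase) * sin(pi * s / len)^4
  } else rep(0, length(s))
  cbind(start[1] + s * u[1] + off * nrm[1],
        start[2] + s * u[2] + off * nrm[2])
}

#' @export
print.vessel_graph <- function(x, ...) {
  nb <- sum(x$nodes$degree >= 3)
  cat(sprintf("<vessel_graph: %d nodes (%d bifurcations), %d segments>\n",
              nrow(x$nodes), nb, length(x$segments)))
  invisible(x)
}
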