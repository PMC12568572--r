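## Vessel graph construction from a skeleton + mask, and JSON round trip.

#' Build a centerline graph from a skeleton and its mask
#'
#' Nodes are placed at skeleton pixels with one neighbor (endpoints) or
#' three and more neighbors (bifurcation clusters, merged to their
#' centroid); segments are the ordered degree-two chains between nodes.
#' The per-point radius is the Euclidean distance-transform value of the
#' vessel mask at the centerline, minus half a pixel (the distance is
#' measured to the first background pixel *center*).
#'
#' @param skeleton Logical skeleton matrix from [skeletonize()].
#' @param mask Logical vessel mask the skeleton came from.
#' @param labels Optional `list(artery_mask, vein_mask)`; each segment is
#'   labelled by majority vote of the underlying label masks.
#' @return A `vessel_graph` with `nodes` (id, x, y, degree, kind) and
#'   `segments` (ordered points, per-point radius, label, incident nodes).
#'   An empty skeleton yields an empty graph.
#' @export
build_graph <- function(skeleton, mask, labels = NULL) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  empty <- structure(
    list(nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                            degree = integer(), kind = character()),
         segments = list()),
    class = "vessel_graph"
  )
  if (!any(skeleton)) return(empty)
  dm <- as_plain_matrix(EBImage::distmap(matrix(as.numeric(mask), h, w)))
  # local 3x3 maximum: the traced skeleton can sit a pixel off the true
  # medial axis, where the distance transform under-reads the radius
  dmx <- dm
  for (dy in -1:1) for (dx in -1:1) {
    if (dy || dx) dmx <- pmax(dmx, .shift_mat(dm, dy, dx))
  }
  # -0.25: the ridge of the distance transform overshoots the half-width of
  # a random-offset continuous band by ~0.25 px on average
  radius_at <- function(iy, ix) pmax(dmx[cbind(iy, ix)] - 0.25, 0.5)

  cn <- crossing_number(skeleton)
  junc <- skeleton & cn >= 3
  # merge junction pixels within 2 px into one node: raster Y-junctions
  # frequently split into two nearby junction pixels
  jd <- as_plain_matrix(
    EBImage::dilate(matrix(as.numeric(junc), h, w), EBImage::makeBrush(3, "box"))
  ) > 0
  jlab_d <- label8(jd)
  jlab <- matrix(0L, h, w)
  jlab[junc] <- jlab_d[junc]
  jlab[junc] <- match(jlab[junc], sort(unique(jlab[junc])))
  njunc <- if (any(junc)) max(jlab) else 0L

  nodes <- list()
  add_node <- function(x, y, kind) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, x = x, y = y, degree = 0L, kind = kind)
    id
  }
  jnode <- integer(njunc)
  jpos <- matrix(0, max(njunc, 1), 2)  # (y, x) centroid per junction cluster
  for (j in seq_len(njunc)) {
    px <- which(jlab == j, arr.ind = TRUE)
    jpos[j, ] <- c(mean(px[, 1]), mean(px[, 2]))
    jnode[j] <- add_node(jpos[j, 2], jpos[j, 1], "bifurcation")
  }

  offs <- cbind(dy = c(-1, 1, 0, 0, -1, -1, 1, 1),
                dx = c(0, 0, -1, 1, -1, 1, -1, 1))  # 4-neighbors first
  adj_cluster <- function(y, x) {
    ny <- y + offs[, 1]; nx <- x + offs[, 2]
    ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
    js <- unique(jlab[cbind(ny[ok], nx[ok])])
    js[js > 0]
  }

  chain <- skeleton & !junc
  visited <- matrix(FALSE, h, w)
  segments <- list()
  ep_node <- matrix(0L, h, w)   # endpoint node cache by pixel

  end_node_at <- function(y, x) {
    if (ep_node[y, x] == 0L) ep_node[y, x] <<- add_node(x, y, "endpoint")
    ep_node[y, x]
  }

  ## walk a chain starting at (y0, x0) coming from origin cluster j0 (0 if
  ## starting at an endpoint); returns the ordered path and terminal info
  walk <- function(y0, x0, j0) {
    path_y <- integer(0); path_x <- integer(0)
    cy <- y0; cx <- x0
    repeat {
      path_y <- c(path_y, cy); path_x <- c(path_x, cx)
      visited[cy, cx] <<- TRUE
      # terminal junction adjacency (ignore the origin until we moved away)
      js <- adj_cluster(cy, cx)
      js_term <- if (length(path_y) <= 2 && j0 > 0) setdiff(js, j0) else js
      if (length(js_term) > 0) {
        return(list(y = path_y, x = path_x, term = "junction",
                    j = js_term[1]))
      }
      ny <- cy + offs[, 1]; nx <- cx + offs[, 2]
      ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
      ny <- ny[ok]; nx <- nx[ok]
      cand <- which(chain[cbind(ny, nx)] & !visited[cbind(ny, nx)])
      if (length(cand) == 0) {
        return(list(y = path_y, x = path_x, term = "endpoint", j = 0L))
      }
      cy <- ny[cand[1]]; cx <- nx[cand[1]]   # 4-neighbors preferred
    }
  }

  emit_segment <- function(wk, j0) {
    ys <- wk$y; xs <- wk$x
    n1 <- if (j0 > 0) jnode[j0] else end_node_at(ys[1], xs[1])
    n2 <- if (wk$term == "junction") jnode[wk$j] else
      end_node_at(ys[length(ys)], xs[length(xs)])
    if (j0 > 0) { ys <- c(jpos[j0, 1], ys); xs <- c(jpos[j0, 2], xs) }
    if (wk$term == "junction") {
      ys <- c(ys, jpos[wk$j, 1]); xs <- c(xs, jpos[wk$j, 2])
    }
    r <- radius_at(round(ys), round(xs))
    label <- "unknown"
    if (!is.null(labels)) {
      pix <- cbind(wk$y, wk$x)
      na <- sum(labels$artery_mask[pix]); nv <- sum(labels$vein_mask[pix])
      if (na + nv > 0) label <- if (na >= nv) "artery" else "vein"
    }
    sid <- length(segments) + 1L
    segments[[sid]] <<- list(id = sid, points = cbind(xs, ys), radius = r,
                             label = label, nodes = c(n1, n2),
                             flagged = FALSE)
    nodes[[n1]]$degree <<- nodes[[n1]]$degree + 1L
    nodes[[n2]]$degree <<- nodes[[n2]]$degree + 1L
  }

  # 1) chains leaving junction clusters
  if (njunc > 0) {
    jpix <- which(junc, arr.ind = TRUE)
    for (k in seq_len(nrow(jpix))) {
      jy <- jpix[k, 1]; jx <- jpix[k, 2]
      j0 <- jlab[jy, jx]
      ny <- jy + offs[, 1]; nx <- jx + offs[, 2]
      ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
      ny <- ny[ok]; nx <- nx[ok]
      starts <- which(chain[cbind(ny, nx)] & !visited[cbind(ny, nx)])
      for (sidx in starts) {
        y0 <- ny[sidx]; x0 <- nx[sidx]
        if (visited[y0, x0]) next
        emit_segment(walk(y0, x0, j0), j0)
      }
    }
  }
  # 2) chains starting at free endpoints (no junction involved)
  ends <- which(chain & cn == 1 & !visited, arr.ind = TRUE)
  for (k in seq_len(nrow(ends))) {
    y0 <- ends[k, 1]; x0 <- ends[k, 2]
    if (visited[y0, x0]) next
    emit_segment(walk(y0, x0, 0L), 0L)
  }

  ndf <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, x = nd$x, y = nd$y, degree = nd$degree,
               kind = if (nd$degree >= 3) "bifurcation" else "endpoint",
               stringsAsFactors = FALSE)
  }))
  structure(list(nodes = ndf, segments = segments), class = "vessel_graph")
}

#' Mask/graph round trip: stamp a graph back into a mask
#'
#' Rasterizes disks of the per-point radius along every segment; on
#' synthetic scenes this recovers the great majority of the original mask
#' (a quality invariant of the graph stage).
#' @param graph A `vessel_graph`.
#' @param dim `c(height, width)`.
#' @param inflate Added to every radius before stamping; the default +0.25
#'   undoes the ridge-overshoot correction applied when radii were read off
#'   the distance transform.
#' @return Logical mask.
#' @export
stamp_graph <- function(graph, dim, inflate = 0.25) {
  segs <- lapply(graph$segments, function(s) {
    s$radius <- s$radius + inflate
    s
  })
  rasterize_segments(segs, dim)
}

#' Serialize a vessel graph to JSON
#'
#' Round-trips losslessly through [graph_from_json()] (numeric values are
#' written at full precision).
#' @param graph A `vessel_graph`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
graph_to_json <- function(graph, path = NULL) {
  payload <- list(
    nodes = graph$nodes,
    segments = lapply(graph$segments, function(s) {
      list(id = s$id, x = s$points[, 1], y = s$points[, 2],
           radius = s$radius, label = s$label, nodes = s$nodes,
           flagged = isTRUE(s$flagged))
    }),
    per_segment_truth = graph$per_segment_truth,
    per_branch_truth = graph$per_branch_truth
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname graph_to_json
#' @param json JSON string or file path produced by [graph_to_json()].
#' @export
graph_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  segments <- lapply(p$segments, function(s) {
    list(id = as.integer(s$id), points = cbind(xs = s$x, ys = s$y),
         radius = s$radius, label = s$label, nodes = as.integer(s$nodes),
         flagged = isTRUE(s$flagged))
  })
  g <- list(nodes = as.data.frame(p$nodes), segments = segments)
  if (!is.null(p$per_segment_truth)) {
    g$per_segment_truth <- as.data.frame(p$per_segment_truth)
  }
  if (!is.null(p$per_branch_truth)) {
    g$per_branch_truth <- as.data.frame(p$per_branch_truth)
  }
  structure(g, class = "vessel_graph")
}
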