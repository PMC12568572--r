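## End-to-end pipeline: simulate -> segment -> graph -> metrics -> zones ->
## statistics, driven by a single config with per-module blocks, plus
## validation of a run against its ground truth.

#' Default pipeline configuration
#'
#' One nested list holding every tunable parameter of every stage, with the
#' package defaults. It serializes to YAML and back unchanged.
#' @return Named list (`seed`, `mode`, `simulate`, `segmentation`, `graph`,
#'   `zones`, `stats`).
#' @export
default_config <- function() {
  list(
    seed = 0L,
    mode = "synthetic",
    simulate = list(
      n_per_group = 4L, eyes_per_subject = 2L, size = 640L,
      noise_level = 0.02,
      group_effects = list(vc_um = -4, vba_deg = -1.5,
                           disc_area_mm2 = 0.184, cup_area_mm2 = 0.068)
    ),
    segmentation = list(
      segmenter = "vesselness",       # or "truth" (synthetic mode only)
      scales = c(1.5, 2.5, 4, 6, 9),
      t_low = 0.05, t_high = 0.25, dark_gate = -0.01, min_area = 60L,
      width_cut = 9
    ),
    graph = list(prune = 5L, min_seg_len = 10L, tort_lowpass = 20),
    zones = list(band = c(0.5, 2.5)),
    stats = list(covariates = c("age", "sex", "axl_mm"),
                 subject_mean = FALSE, holm = FALSE)
  )
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## pixels within `margin` px of an ellipse boundary (radial approximation)
.ellipse_rim <- function(e, dimm, margin = 4) {
  gr <- coord_grid(dimm[1], dimm[2])
  dx <- gr$x - e$cx; dy <- gr$y - e$cy
  u <- dx * cos(e$theta) + dy * sin(e$theta)
  v <- -dx * sin(e$theta) + dy * cos(e$theta)
  q <- sqrt((u / e$a)^2 + (v / e$b)^2)
  r_eq <- sqrt(e$a * e$b)
  abs(q - 1) * r_eq <= margin
}

## circle -> ellipse representation
.circle_ellipse <- function(center, r) {
  list(cx = center[1], cy = center[2], a = r, b = r, theta = 0)
}

#' Measure one eye: segmentation through per-zone metrics
#'
#' Runs the measurement stages on a single image (optionally with ground
#' truth standing in for the segmenter) and returns the per-scope metric
#' rows plus the intermediate artifacts.
#'
#' @param image `fundus_image`.
#' @param config Pipeline config ([default_config()] shape).
#' @param truth Optional `ground_truth`; required when
#'   `config$segmentation$segmenter == "truth"`, otherwise used only for
#'   artery/vein label pass-through.
#' @return List with `metrics` (data frame), `mask`, `graph`, `ellipses`.
#' @export
measure_eye <- function(image, config = default_config(), truth = NULL) {
  sg <- config$segmentation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed for %s/%s: %s", name,
            image$subject_id, image$eye, conditionMessage(e))
    })
  }
  pre <- stage("preprocess", preprocess(image))
  if (identical(sg$segmenter, "truth")) {
    if (is.null(truth)) stopf("segmenter 'truth' requires ground truth")
    mask <- truth$vessel_mask
    labels <- list(artery_mask = truth$artery_mask,
                   vein_mask = truth$vein_mask)
    disc_e <- .circle_ellipse(truth$disc$center, truth$disc$disc_radius)
    cup_e <- .circle_ellipse(truth$disc$center, truth$disc$cup_radius)
  } else {
    mask <- stage("segment_vessels",
                  segment_vessels(pre, scales = sg$scales, t_low = sg$t_low,
                                  t_high = sg$t_high,
                                  dark_gate = sg$dark_gate,
                                  min_area = sg$min_area))
    ell <- stage("detect_disc_cup", detect_disc_cup(image))
    disc_e <- ell$disc; cup_e <- ell$cup
    # the bright disc rim reads as a dark ridge just outside its edge, and
    # the second-derivative lobes of the largest vesselness scale extend
    # about 2*sigma beyond it; drop mask pixels within that margin of the
    # fitted disc boundary
    rim <- 2.5 * max(sg$scales)
    mask <- mask & !.ellipse_rim(disc_e, dim(mask), rim)
    labels <- stage("classify_artery_vein",
                    classify_artery_vein(mask, pre, truth = truth,
                                         width_cut = sg$width_cut))
  }
  skel <- stage("skeletonize", skeletonize(mask, prune = config$graph$prune))
  graph <- stage("build_graph", build_graph(skel, mask, labels = labels))
  metrics <- stage("compute_metrics", compute_metrics(
    masks = c(list(vessel_mask = mask), labels),
    graph = graph, disc_ellipse = disc_e, cup_ellipse = cup_e,
    pitch = image$pixel_pitch, eye = image$eye,
    roi_mask = pre$roi_mask,
    min_seg_len = config$graph$min_seg_len,
    tort_lowpass = config$graph$tort_lowpass
  ))
  list(metrics = metrics, mask = mask, labels = labels, graph = graph,
       ellipses = list(disc = disc_e, cup = cup_e))
}

#' Run the full synthetic two-cohort pipeline
#'
#' Simulates the cohort, measures every eye, joins metrics with covariates,
#' and writes `metrics.csv`, `covariates.csv`, the three report tables, and
#' a manifest to `out_dir`. Identical config and seed give a byte-identical
#' `metrics.csv`.
#'
#' @param config Pipeline config; `config$seed` drives all randomness.
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output.
#' @param save_images Additionally write per-eye PNG images and masks.
#' @return Invisibly, a list with `metrics`, `cohort`, `reports`,
#'   `eyes` (per-eye artifacts), and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         save_images = FALSE) {
  if (!identical(config$mode, "synthetic")) {
    stopf("run_pipeline: only mode 'synthetic' is implemented; use measure_eye() on external images")
  }
  sim <- config$simulate
  spec <- cohort_spec(
    n_per_group = sim$n_per_group,
    group_effects = unlist(sim$group_effects),
    eyes_per_subject = sim$eyes_per_subject,
    seed = config$seed
  )
  gen <- generate_cohort(spec, render = TRUE, size = sim$size,
                         noise_level = sim$noise_level)
  eyes <- vector("list", nrow(gen$cohort))
  metrics_rows <- list()
  for (i in seq_len(nrow(gen$cohort))) {
    res <- measure_eye(gen$images[[i]], config, truth = gen$truths[[i]])
    eyes[[i]] <- res
    m <- res$metrics
    meta <- gen$cohort[i, c("subject_id", "eye", "group", "age", "sex",
                            "axl_mm")]
    metrics_rows[[i]] <- cbind(meta[rep(1, nrow(m)), , drop = FALSE], m)
  }
  names(eyes) <- names(gen$images)
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL
  reports <- report_tables(metrics, covariates = config$stats$covariates)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_table_csv(gen$cohort, file.path(out_dir, "covariates.csv"))
    write_table_csv(reports$global, file.path(out_dir, "report_global.csv"))
    write_table_csv(reports$annulus, file.path(out_dir, "report_annulus.csv"))
    write_table_csv(reports$quadrant,
                    file.path(out_dir, "report_quadrant.csv"))
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    manifest <- list(
      package = "retinavasc",
      version = as.character(utils::packageVersion("retinavasc")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      n_eyes = nrow(gen$cohort)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (save_images) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (nm in names(gen$images)) {
        write_fundus_png(gen$images[[nm]],
                         file.path(img_dir, paste0(nm, ".png")))
        write_mask_png(eyes[[nm]]$mask,
                       file.path(img_dir, paste0(nm, "_mask.png")))
      }
    }
  }
  invisible(list(metrics = metrics, cohort = gen$cohort, reports = reports,
                 eyes = eyes, truths = gen$truths, out_dir = out_dir))
}

## Rasterize the local truth radius along segments (max at overlaps).
radius_map <- function(segments, dim) {
  h <- dim[1]; w <- dim[2]
  rm <- matrix(0, h, w)
  for (s in segments) {
    p <- s$points; r <- s$radius
    n <- nrow(p)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      x1 <- p[i, 1]; y1 <- p[i, 2]; x2 <- p[i + 1, 1]; y2 <- p[i + 1, 2]
      r1 <- r[i]; r2 <- r[i + 1]; rmax <- max(r1, r2)
      xa <- max(1L, floor(min(x1, x2) - rmax))
      xb <- min(w, ceiling(max(x1, x2) + rmax))
      ya <- max(1L, floor(min(y1, y2) - rmax))
      yb <- min(h, ceiling(max(y1, y2) + rmax))
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
        sub <- rm[ys, xs, drop = FALSE]
        sub[hit] <- pmax(sub[hit], rl[hit])
        rm[ys, xs] <- sub
      }
    }
  }
  rm
}

#' Validate measured eyes against ground truth
#'
#' Quality-control comparison of a measured run with the generator's
#' truth: pixel sensitivity/specificity of the vessel mask, per-segment
#' caliber mean absolute error (px), branch-angle mean absolute error
#' (degrees, truth bifurcations matched to measured degree-3 nodes within
#' `match_radius` px), aggregate tortuosity relative error, and the zone
#' partition checks.
#'
#' @param eyes Named list of per-eye results from [measure_eye()] (fields
#'   `mask`, `graph`, `ellipses`).
#' @param truths Named list of `ground_truth` objects with matching names.
#' @param min_seg_len Minimum measured segment length (px) scored.
#' @param match_radius Node matching radius (px).
#' @return Data frame, one row per eye: `id`, `sensitivity`, `specificity`,
#'   `caliber_mae_px`, `angle_mae_deg`, `angle_match_frac`,
#'   `tortuosity_rel_err`, `zones_partition_ok`.
#' @export
validate_against_truth <- function(eyes, truths, min_seg_len = 10,
                                   match_radius = 3) {
  if (!setequal(names(eyes), names(truths)) || is.null(names(eyes))) {
    stopf("validate_against_truth: eye ids and truth ids do not match")
  }
  rows <- lapply(names(eyes), function(nm) {
    e <- eyes[[nm]]; tr <- truths[[nm]]
    dimm <- dim(tr$vessel_mask)
    q <- segmentation_quality(e$mask, tr$vessel_mask)
    rmap <- radius_map(tr$graph$segments, dimm)

    # caliber: measured segment mean width vs local truth width
    errs <- c()
    for (s in e$graph$segments) {
      if (polyline_length(s$points) < min_seg_len) next
      w <- .interior_widths(s)
      if (length(w) < 3) next
      p <- s$points
      n <- nrow(p)
      d1 <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
      d2 <- sqrt((p[, 1] - p[n, 1])^2 + (p[, 2] - p[n, 2])^2)
      keep <- d1 > 2 & d2 > 2
      iy <- clamp(round(p[keep, 2]), 1, dimm[1])
      ix <- clamp(round(p[keep, 1]), 1, dimm[2])
      rt <- rmap[cbind(iy, ix)]
      ok <- rt > 0
      if (sum(ok) < 3) next
      errs <- c(errs, abs(mean(w[ok]) - mean(2 * rt[ok])))
    }
    cal_mae <- if (length(errs)) mean(errs) else NA_real_

    # branch angles: truth bifurcations matched to cleanly recovered,
    # resolvable measured degree-3 nodes (all incident branches traced for
    # at least 12 px and at least ~2.5 px half-width: below that, diverging
    # daughters merge into one wedge-shaped blob and the take-off angle is
    # not present in the raster)
    bt <- tr$per_branch_truth
    aerr <- c(); merr <- c(); matched <- 0L
    if (nrow(bt) > 0) {
      tn <- tr$graph$nodes
      mn <- e$graph$nodes[e$graph$nodes$degree == 3, ]
      for (k in seq_len(nrow(bt))) {
        pos <- tn[tn$id == bt$node[k], c("x", "y")]
        if (nrow(mn) == 0) next
        dd <- sqrt((mn$x - pos$x)^2 + (mn$y - pos$y)^2)
        j <- which.min(dd)
        if (dd[j] > match_radius) next
        inc <- Filter(function(s) any(s$nodes == mn$id[j]),
                      e$graph$segments)
        if (length(inc) != 3) next
        if (any(vapply(inc, function(s) polyline_length(s$points),
                       numeric(1)) < 12)) next
        if (sort(vapply(inc, function(s) mean(s$radius), numeric(1)))[2] <
              2.5) next
        ang <- measure_branch_angle(e$graph, mn$id[j],
                                    disc = e$ellipses$disc, max_pd = Inf)
        if (is.na(ang)) next
        matched <- matched + 1L
        aerr <- c(aerr, abs(ang - bt$angle_deg[k]))
        merr <- c(merr, ang - bt$angle_deg[k])
      }
    }
    ang_mae <- if (length(aerr)) mean(aerr) else NA_real_

    # tortuosity: truth segments matched to measured segments by their
    # endpoint positions (topologically recovered segments only)
    st <- tr$per_segment_truth
    t_rel <- .tortuosity_recovery(e$graph, tr$graph, st,
                                  match_radius = 6, min_len = 20)

    zones_ok <- .zones_partition_ok(e$ellipses$disc, tr, dimm)

    data.frame(id = nm, sensitivity = unname(q["sensitivity"]),
               specificity = unname(q["specificity"]),
               caliber_mae_px = cal_mae, angle_mae_deg = ang_mae,
               angle_bias_deg = if (length(merr)) mean(merr) else NA_real_,
               angle_match_frac = if (nrow(bt) > 0) matched / nrow(bt) else NA,
               tortuosity_rel_err = t_rel,
               zones_partition_ok = zones_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Relative error of the length-weighted aggregate tortuosity over truth
## segments whose endpoints are both recovered (within match_radius px) by
## one measured segment. The aggregate (the per-eye VT statistic) is the
## compared quantity; per-segment raster noise largely averages out of it.
.tortuosity_recovery <- function(mgraph, tgraph, seg_truth,
                                 match_radius = 6, min_len = 40,
                                 lowpass = 20) {
  if (nrow(seg_truth) == 0 || length(mgraph$segments) == 0) return(NA_real_)
  m_ends <- lapply(mgraph$segments, function(s) {
    rbind(s$points[1, ], s$points[nrow(s$points), ])
  })
  err <- c(); tru <- c(); wt <- c()
  for (k in seq_len(nrow(seg_truth))) {
    if (seg_truth$length_px[k] < min_len) next
    ts <- Filter(function(s) s$id == seg_truth$segment[k],
                 tgraph$segments)[[1]]
    e1 <- ts$points[1, ]; e2 <- ts$points[nrow(ts$points), ]
    best <- NULL; best_d <- Inf
    for (j in seq_along(m_ends)) {
      me <- m_ends[[j]]
      d_f <- sqrt(sum((me[1, ] - e1)^2)) + sqrt(sum((me[2, ] - e2)^2))
      d_r <- sqrt(sum((me[1, ] - e2)^2)) + sqrt(sum((me[2, ] - e1)^2))
      d <- min(d_f, d_r)
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (is.null(best) || best_d > 2 * match_radius) next
    tv <- suppressMessages(
      measure_tortuosity(mgraph$segments[[best]], lowpass = lowpass)
    )
    if (is.na(tv) || seg_truth$tortuosity[k] <= 0) next
    err <- c(err, tv)
    tru <- c(tru, seg_truth$tortuosity[k])
    wt <- c(wt, seg_truth$length_px[k])
  }
  if (length(err) == 0) return(NA_real_)
  abs(sum(err * wt) / sum(tru * wt) - 1)
}

.zones_partition_ok <- function(disc_e, truth, dimm) {
  qs <- lapply(.quadrant_labels, function(q) {
    quadrant_region(disc_e, q, "OD", dimm)
  })
  band <- annulus_region(disc_e, 0.5, 2.5, dimm)
  tot <- Reduce(`+`, lapply(qs, function(m) matrix(as.numeric(m),
                                                   dimm[1], dimm[2])))
  all(tot[band] == 1) && all(tot[!band] == 0)
}

#' Truth-recovery benchmark over a batch of synthetic scenes
#'
#' Renders `n_scenes` default scenes, measures each from its ground-truth
#' vessel mask (isolating the graph and morphometry stages from the
#' segmenter, which has its own pixel gate), and pools recovery statistics
#' across the batch: per-segment caliber MAE in px, the error of the pooled
#' branching-angle mean over cleanly matched bifurcations in degrees, the
#' relative error of the pooled length-weighted tortuosity aggregate, and a
#' density check against direct pixel counting.
#'
#' @param n_scenes Number of scenes.
#' @param size Scene side in px.
#' @param seed Base seed; scene k uses `seed + k`.
#' @return List with `caliber_mae_px`, `angle_err_deg` (pooled-mean error),
#'   `angle_mae_deg` (per-bifurcation MAE, for reference), `tort_rel_err`,
#'   `density_exact` (logical), and the pooled counts.
#' @export
recovery_batch <- function(n_scenes = 20, size = 1024, seed = 1) {
  cal_err <- c()
  ang_m <- c(); ang_t <- c()
  tor_m <- c(); tor_t <- c(); tor_w <- c()
  density_exact <- TRUE
  for (k in seq_len(n_scenes)) {
    sc <- default_scene(seed = seed + k, size = size)
    tr <- sc$truth
    mask <- tr$vessel_mask
    dimm <- dim(mask)
    g <- build_graph(skeletonize(mask), mask)
    rmap <- radius_map(tr$graph$segments, dimm)

    for (s in g$segments) {
      if (polyline_length(s$points) < 20) next
      w <- .interior_widths(s)
      if (length(w) < 3) next
      p <- s$points; n <- nrow(p)
      d1 <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
      d2 <- sqrt((p[, 1] - p[n, 1])^2 + (p[, 2] - p[n, 2])^2)
      keep <- d1 > 2 & d2 > 2
      iy <- clamp(round(p[keep, 2]), 1, dimm[1])
      ix <- clamp(round(p[keep, 1]), 1, dimm[2])
      rt <- rmap[cbind(iy, ix)]
      ok <- rt > 0
      if (sum(ok) < 3) next
      cal_err <- c(cal_err, mean(w[ok]) - mean(2 * rt[ok]))
    }

    bt <- tr$per_branch_truth
    tn <- tr$graph$nodes
    mn <- g$nodes[g$nodes$degree == 3, ]
    for (j in seq_len(nrow(bt))) {
      pos <- tn[tn$id == bt$node[j], c("x", "y")]
      if (nrow(mn) == 0) next
      dd <- sqrt((mn$x - pos$x)^2 + (mn$y - pos$y)^2)
      jj <- which.min(dd)
      if (dd[jj] > 3) next
      inc <- Filter(function(s) any(s$nodes == mn$id[jj]), g$segments)
      if (length(inc) != 3) next
      if (any(vapply(inc, function(s) polyline_length(s$points),
                     numeric(1)) < 12)) next
      if (sort(vapply(inc, function(s) mean(s$radius), numeric(1)))[2] <
            2.5) next
      ang <- measure_branch_angle(g, mn$id[jj])
      if (is.na(ang)) next
      ang_m <- c(ang_m, ang); ang_t <- c(ang_t, bt$angle_deg[j])
    }

    st <- tr$per_segment_truth
    m_ends <- lapply(g$segments, function(s) {
      rbind(s$points[1, ], s$points[nrow(s$points), ])
    })
    for (j in seq_len(nrow(st))) {
      if (st$length_px[j] < 40) next
      ts <- Filter(function(s) s$id == st$segment[j], tr$graph$segments)[[1]]
      e1 <- ts$points[1, ]; e2 <- ts$points[nrow(ts$points), ]
      bd <- vapply(m_ends, function(me) {
        min(sqrt(sum((me[1, ] - e1)^2)) + sqrt(sum((me[2, ] - e2)^2)),
            sqrt(sum((me[1, ] - e2)^2)) + sqrt(sum((me[2, ] - e1)^2)))
      }, numeric(1))
      jj <- which.min(bd)
      if (bd[jj] > 12) next
      tv <- suppressMessages(measure_tortuosity(g$segments[[jj]],
                                                lowpass = 20))
      if (is.na(tv)) next
      tor_m <- c(tor_m, tv); tor_t <- c(tor_t, st$tortuosity[j])
      tor_w <- c(tor_w, st$length_px[j])
    }

    if (k == 1) {
      reg <- radial_dist(dimm[1], dimm[2], dimm[2] / 2, dimm[1] / 2) <=
        size / 4
      brute <- sum(mask & reg) / sum(reg)
      density_exact <- isTRUE(all.equal(vessel_density(mask, reg), brute))
    }
  }
  list(
    caliber_mae_px = mean(abs(cal_err)),
    angle_err_deg = abs(mean(ang_m) - mean(ang_t)),
    angle_mae_deg = mean(abs(ang_m - ang_t)),
    tort_rel_err = abs(sum(tor_m * tor_w) / sum(tor_t * tor_w) - 1),
    density_exact = density_exact,
    n_segments = length(cal_err),
    n_branches = length(ang_m),
    n_tort = length(tor_m)
  )
}
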