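## Classical segmentation stage.
##
## Stand-in for a learned segmenter, behind the same interface: preprocess
## -> vesselness -> hysteresis threshold -> labelled masks. Any model
## producing the same mask contract can replace `segment_vessels()`.

#' Preprocess a fundus photograph
#'
#' Extracts the circular fundus region of interest (ROI), takes the green
#' channel (highest vessel contrast), and removes the smooth illumination
#' field by subtracting a least-squares quadratic surface fitted over the
#' ROI. The surface subtraction is a linear projection, so the operation is
#' idempotent: preprocessing an already-preprocessed image changes nothing
#' beyond numerical round-off.
#'
#' @param image A `fundus_image`. Raw images carry an RGB array; a
#'   preprocessed image carries the normalized single-channel matrix plus
#'   the detected ROI and is returned after a no-op projection.
#' @return A `fundus_image` with `pixels` the normalized channel (matrix),
#'   `roi` (list `cx`, `cy`, `r`), `roi_mask`, and `preprocessed = TRUE`.
#' @export
preprocess <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  if (isTRUE(image$preprocessed)) {
    g <- image$pixels
    roi <- image$roi
    roi_mask <- image$roi_mask
  } else {
    px <- image$pixels
    lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    bright <- lum > 0.02
    if (mean(bright) < 0.10) {
      stopf("preprocess: fundus circle not detected (lit area %.1f%% < 10%% of frame)",
            100 * mean(bright))
    }
    idx <- which(bright, arr.ind = TRUE)
    roi <- list(cx = mean(idx[, 2]), cy = mean(idx[, 1]),
                r = sqrt(sum(bright) / pi))
    h <- nrow(lum); w <- ncol(lum)
    # one-pixel safety margin keeps the mask inside the lit circle
    roi_mask <- radial_dist(h, w, roi$cx, roi$cy) <= roi$r - 1
    g <- px[, , 2]
  }
  # quadratic illumination surface over the ROI (projection => idempotent)
  h <- nrow(g); w <- ncol(g)
  ii <- which(roi_mask)
  yy <- ((ii - 1) %% h + 1 - roi$cy) / roi$r
  xx <- ((ii - 1) %/% h + 1 - roi$cx) / roi$r
  X <- cbind(1, xx, yy, xx^2, xx * yy, yy^2)
  beta <- stats::.lm.fit(X, g[ii])$coefficients
  out <- matrix(0, h, w)
  out[ii] <- g[ii] - drop(X %*% beta)
  structure(
    list(pixels = out, pixel_pitch = image$pixel_pitch, eye = image$eye,
         subject_id = image$subject_id, roi = roi, roi_mask = roi_mask,
         raw = if (isTRUE(image$preprocessed)) image$raw else image$pixels,
         preprocessed = TRUE),
    class = "fundus_image"
  )
}

## Separable Gaussian second-derivative convolutions giving the
## scale-normalized Hessian (gamma = 2) at scale sigma.
.hessian_at_scale <- function(m, sigma) {
  k <- max(3L, ceiling(3.5 * sigma))
  x <- (-k):k
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 / sigma^2 - 1) / sigma^2 * g
  conv <- function(img, kx, ky) {
    as_plain_matrix(EBImage::filter2(img, outer(ky, kx), boundary = 0))
  }
  s2 <- sigma^2
  list(xx = s2 * conv(m, g2, g), yy = s2 * conv(m, g, g2),
       xy = s2 * conv(m, g1, g1))
}

#' Multiscale vesselness response
#'
#' Frangi-style ridge filter on the normalized channel: Hessian eigenvalues
#' at several Gaussian scales, blobness and structure terms combined, dark
#' ridges only (vessels are darker than the background), maximum over
#' scales. The response is normalized to its own maximum so thresholds are
#' transferable across images.
#'
#' @param image Preprocessed `fundus_image` (raw images are preprocessed
#'   first).
#' @param scales Gaussian scales (px), roughly vessel radius / sqrt(2).
#' @param beta Blobness sensitivity.
#' @return Matrix of vesselness values in `[0, 1]`, zero outside the ROI
#'   (eroded by twice the largest scale to suppress the aperture-rim
#'   response).
#' @export
vesselness <- function(image, scales = c(1.5, 2.5, 4, 6, 9), beta = 0.5) {
  img <- if (isTRUE(image$preprocessed)) image else preprocess(image)
  m <- img$pixels
  h <- nrow(m); w <- ncol(m)
  resp <- matrix(0, h, w)
  for (s in scales) {
    H <- .hessian_at_scale(m, s)
    tr <- H$xx + H$yy
    dd <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
    l_a <- (tr + dd) / 2; l_b <- (tr - dd) / 2
    big <- ifelse(abs(l_a) >= abs(l_b), l_a, l_b)
    small <- ifelse(abs(l_a) >= abs(l_b), l_b, l_a)
    S2 <- l_a^2 + l_b^2
    c2 <- 0.5 * max(S2)
    v <- exp(-(small / big)^2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[big <= 0] <- 0          # dark ridge: dominant eigenvalue positive
    v[is.na(v)] <- 0
    resp <- pmax(resp, v)
  }
  # erode by the support of the largest filter: the aperture edge is a
  # step whose second-derivative lobes reach ~2 sigma inward
  inner <- radial_dist(h, w, img$roi$cx, img$roi$cy) <=
    (img$roi$r - 2 * max(scales))
  resp[!inner] <- 0
  if (max(resp) > 0) resp <- resp / max(resp)
  resp
}

#' Segment retinal vessels
#'
#' Thresholds the multiscale vesselness response with hysteresis (weak
#' pixels are kept only in connected components that contain at least one
#' strong pixel), gates the result on the normalized intensity being dark
#' (vesselness rings slightly wider than the vessel; true vessel pixels are
#' darker than the illumination-corrected background), and removes small
#' components. Threshold defaults were set by maximizing Youden's index on
#' the default synthetic scene and live in [default_config()].
#'
#' @param image `fundus_image` (raw or preprocessed).
#' @param scales Vesselness scales (px).
#' @param t_low,t_high Hysteresis thresholds on the normalized response.
#' @param dark_gate Maximum normalized intensity (0–1 scale) a mask pixel
#'   may have; `NA` disables the gate.
#' @param min_area Minimum connected-component area (px) kept.
#' @param smooth_mask Regularize the mask boundary with a morphological
#'   opening + closing (3 px diamond); keeps centerline tracing from
#'   inheriting threshold roughness.
#' @return Logical vessel mask. An empty mask is a legal output.
#' @export
segment_vessels <- function(image, scales = c(1.5, 2.5, 4, 6, 9),
                            t_low = 0.05, t_high = 0.25,
                            dark_gate = -0.01, min_area = 60,
                            smooth_mask = TRUE) {
  img <- if (isTRUE(image$preprocessed)) image else preprocess(image)
  v <- vesselness(img, scales = scales)
  lo <- v >= t_low
  if (!any(lo)) return(lo)
  lab <- label8(lo)
  keep <- unique(lab[v >= t_high & lo])
  keep <- setdiff(keep, 0)
  if (length(keep) == 0) return(matrix(FALSE, nrow(v), ncol(v)))
  sizes <- tabulate(lab[lab > 0])
  keep <- keep[sizes[keep] >= min_area]
  mask <- matrix(lab %in% keep, nrow(v), ncol(v))
  if (!is.na(dark_gate)) mask <- mask & (img$pixels < dark_gate)
  if (smooth_mask && any(mask)) {
    br <- EBImage::makeBrush(3, "diamond")
    m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
    mask <- as_plain_matrix(EBImage::closing(EBImage::opening(m, br),
                                             br)) > 0
  }
  mask
}

#' Detect the optic disc and cup
#'
#' The disc is located as the dominant bright blob inside the ROI; an
#' ellipse is fitted to it from its second-order moments (for a filled
#' ellipse the semi-axes are twice the principal standard deviations). The
#' cup is the brighter inner region of the disc blob, fitted the same way
#' and shrunk, if necessary, to satisfy containment.
#'
#' @param image Raw `fundus_image` (RGB; brightness is needed).
#' @param min_area Minimum disc blob area in px.
#' @return `list(disc, cup)` of ellipses `list(cx, cy, a, b, theta)` with
#'   semi-axes `a >= b` in px.
#' @export
detect_disc_cup <- function(image, min_area = 300) {
  stopifnot(inherits(image, "fundus_image"))
  if (isTRUE(image$preprocessed)) {
    if (is.null(image$raw)) stopf("detect_disc_cup: original RGB image required")
    px <- image$raw
  } else px <- image$pixels
  lum <- (px[, , 1] + px[, , 2]) / 2
  h <- nrow(lum); w <- ncol(lum)
  roi_mask <- lum > 0.02
  vals <- lum[roi_mask]
  thr <- (stats::median(vals) + stats::quantile(vals, 0.999)) / 2
  cand <- lum > thr & roi_mask
  if (!any(cand)) stopf("disc not found")
  lab <- label8(cand)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) < min_area) stopf("disc not found")
  blob <- lab == which.max(sizes)
  disc <- .moment_ellipse(blob)
  dvals <- lum[blob]
  thr2 <- (stats::median(dvals) + stats::quantile(dvals, 0.999)) / 2
  cupm <- blob & lum > thr2
  if (sum(cupm) < 25) {
    # no resolvable bright core: nominal concentric cup at 45% linear scale
    cup <- disc; cup$a <- disc$a * 0.45; cup$b <- disc$b * 0.45
  } else {
    cup <- .moment_ellipse(cupm)
  }
  cup <- .shrink_into(cup, disc)
  list(disc = disc, cup = cup)
}

.moment_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  mu <- colMeans(xy)
  C <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  e <- eigen(C, symmetric = TRUE)
  list(cx = unname(mu[1]), cy = unname(mu[2]),
       a = 2 * sqrt(max(e$values[1], 1e-9)),
       b = 2 * sqrt(max(e$values[2], 1e-9)),
       theta = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

## Points of ellipse `inner` outside `outer` scale the inner axes down.
.shrink_into <- function(inner, outer, n = 90) {
  tt <- seq(0, 2 * pi, length.out = n)
  px <- inner$cx + inner$a * cos(tt) * cos(inner$theta) -
    inner$b * sin(tt) * sin(inner$theta)
  py <- inner$cy + inner$a * cos(tt) * sin(inner$theta) +
    inner$b * sin(tt) * cos(inner$theta)
  # outer-ellipse implicit value at the sampled boundary
  dx <- px - outer$cx; dy <- py - outer$cy
  u <- dx * cos(outer$theta) + dy * sin(outer$theta)
  v <- -dx * sin(outer$theta) + dy * cos(outer$theta)
  q <- sqrt((u / outer$a)^2 + (v / outer$b)^2)
  # also recentre slightly if the cup centre drifted outside
  if (max(q) > 1) {
    f <- 0.98 / max(q)
    inner$a <- inner$a * f; inner$b <- inner$b * f
  }
  inner
}

#' Label vessels as arteries or veins
#'
#' Tree-level labelling: each connected component of the vessel mask is
#' labelled as a whole (avoiding pixel-level speckle) by the mean intensity
#' of its central pixels — the darker class of a 2-means split is the vein.
#' A single tree falls back to a width cut. When ground truth is supplied
#' (synthetic mode) its label masks are passed through unchanged.
#'
#' @param mask Logical vessel mask.
#' @param image `fundus_image` supplying intensities.
#' @param truth Optional `ground_truth`; short-circuits to its masks.
#' @param width_cut Width (px) above which a lone tree is called a vein.
#' @return `list(artery_mask, vein_mask)`, disjoint subsets of `mask`.
#' @export
classify_artery_vein <- function(mask, image, truth = NULL, width_cut = 9) {
  if (!is.null(truth)) {
    return(list(artery_mask = truth$artery_mask, vein_mask = truth$vein_mask))
  }
  g <- if (isTRUE(image$preprocessed)) image$pixels else image$pixels[, , 2]
  art <- vein <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!any(mask)) return(list(artery_mask = art, vein_mask = vein))
  lab <- label8(mask)
  dm <- as_plain_matrix(EBImage::distmap(matrix(as.numeric(mask),
                                                nrow(mask), ncol(mask))))
  ntree <- max(lab)
  stats_tree <- data.frame(id = seq_len(ntree), int = NA_real_,
                           width = NA_real_)
  for (id in seq_len(ntree)) {
    inb <- lab == id
    central <- inb & dm >= stats::quantile(dm[inb], 0.6)
    stats_tree$int[id] <- mean(g[central])
    stats_tree$width[id] <- 2 * stats::quantile(dm[inb], 0.9)
  }
  if (ntree >= 2 && diff(range(stats_tree$int)) > 1e-9) {
    # exact two-class 1-D split (minimum within-class sum of squares over
    # all cut points); the darker class is the vein
    o <- order(stats_tree$int)
    x <- stats_tree$int[o]
    best <- 1L; best_ss <- Inf
    for (cut in seq_len(ntree - 1)) {
      lo <- x[1:cut]; hi <- x[(cut + 1):ntree]
      ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
      if (ss < best_ss) { best_ss <- ss; best <- cut }
    }
    is_vein <- logical(ntree)
    is_vein[o[1:best]] <- TRUE
  } else {
    is_vein <- stats_tree$width >= width_cut
  }
  for (id in seq_len(ntree)) {
    if (is_vein[id]) vein[lab == id] <- TRUE else art[lab == id] <- TRUE
  }
  list(artery_mask = art, vein_mask = vein)
}

#' Pixel-wise segmentation quality against ground truth
#'
#' @param pred Logical predicted mask.
#' @param truth_mask Logical ground-truth mask.
#' @param roi Optional logical evaluation region (e.g. the fundus circle);
#'   defaults to the full frame.
#' @return Named vector with `sensitivity` (TP rate) and `specificity`
#'   (TN rate).
#' @export
segmentation_quality <- function(pred, truth_mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pred), ncol(pred))
  p <- pred[roi]; t <- truth_mask[roi]
  c(sensitivity = sum(p & t) / sum(t),
    specificity = sum(!p & !t) / sum(!t))
}
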