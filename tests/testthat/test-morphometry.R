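test_that("caliber of an ideal band is 80 um at 10 um/px", {
  mask <- band_mask(60, 240, y0 = 30.5, radius = 4)
  g <- build_graph(skeletonize(mask), mask)
  s <- g$segments[[which.max(vapply(g$segments, function(s)
    nrow(s$points), numeric(1)))]]
  expect_lte(abs(measure_caliber(s, pitch = 10) - 80), 5)
})

test_that("a linearly tapering segment averages to its mid-width", {
  # truth tapers from width 10 px to 6 px
  n <- 201
  t <- seq(0, 1, length.out = n)
  seg <- list(id = 1L, points = cbind(20 + t * 200, rep(40, n)),
              radius = (10 - 4 * t) / 2, label = "artery",
              nodes = c(1L, 2L), flagged = FALSE)
  cal <- measure_caliber(seg, pitch = 1)
  expect_lt(abs(cal - 8), 0.5)
})

test_that("caliber is undefined for segments with too few usable points", {
  seg <- list(id = 1L, points = cbind(c(1, 2, 3), c(1, 1, 1)),
              radius = c(2, 2, 2), label = "artery", nodes = c(1L, 2L),
              flagged = FALSE)
  expect_message(v <- measure_caliber(seg, pitch = 10), "skipped")
  expect_true(is.na(v))
})

test_that("tortuosity analytics: straight, semicircle, sinusoid", {
  # straight: exactly zero
  p <- cbind(seq(0, 100, by = 0.5), rep(5, 201))
  expect_identical(measure_tortuosity(p), 0)
  # semicircle: pi/2 - 1
  expect_lt(abs(measure_tortuosity(semicircle_points()) - (pi / 2 - 1)),
            1e-3)
  # sinusoid vs independent quadrature of the arc-length integral
  a <- 3; lam <- 40; L <- 200
  x <- seq(0, L, length.out = 4001)
  y <- a * sin(2 * pi * x / lam)
  quad <- integrate(function(u) sqrt(1 + (a * 2 * pi / lam *
                                            cos(2 * pi * u / lam))^2),
                    0, L, subdivisions = 2000)$value
  expected <- quad / L - 1
  measured <- measure_tortuosity(cbind(x, y))
  expect_lt(abs(measured - expected) / expected, 0.01)
})

test_that("closed segments are excluded with a message", {
  t <- seq(0, 2 * pi, length.out = 100)
  loop <- cbind(50 + 10 * cos(t), 50 + 10 * sin(t))
  expect_message(v <- measure_tortuosity(loop), "zero chord")
  expect_true(is.na(v))
})

test_that("branch angle of symmetric raster Y junctions is recovered", {
  for (half in c(20, 30, 40)) {
    mask <- y_mask(half)
    g <- build_graph(skeletonize(mask), mask)
    bif <- g$nodes$id[g$nodes$degree == 3]
    expect_length(bif, 1)
    ang <- measure_branch_angle(g, bif[1])
    expect_lt(abs(ang - 2 * half), 4)
  }
})

test_that("near-collinear opposite daughters read as a straight angle", {
  mask <- y_mask(88)   # daughters 176 degrees apart
  g <- build_graph(skeletonize(mask), mask)
  bif <- g$nodes$id[g$nodes$degree == 3]
  ang <- measure_branch_angle(g, bif[1])
  expect_gt(ang, 168)
})

test_that("crossings (degree 4) are excluded from branch angles", {
  mask <- matrix(FALSE, 101, 101)
  mask[48:54, ] <- TRUE
  mask[, 48:54] <- TRUE
  g <- build_graph(skeletonize(mask), mask)
  deg4 <- g$nodes$id[g$nodes$degree >= 4]
  for (id in deg4) expect_true(is.na(measure_branch_angle(g, id)))
})

test_that("vessel density matches a brute-force double loop", {
  expect_equal(vessel_density(matrix(TRUE, 10, 10)), 1)
  m <- matrix(FALSE, 100, 100); m[46:55, ] <- TRUE
  expect_equal(vessel_density(m), 0.10)
  set.seed(3)
  m <- matrix(runif(50 * 40) < 0.3, 50, 40)
  reg <- matrix(runif(50 * 40) < 0.5, 50, 40)
  brute <- 0; tot <- 0
  for (i in 1:50) for (j in 1:40) {
    if (reg[i, j]) {
      tot <- tot + 1
      if (m[i, j]) brute <- brute + 1
    }
  }
  expect_equal(vessel_density(m, reg), brute / tot)
  expect_error(vessel_density(m, matrix(FALSE, 50, 40)), "empty region")
})

test_that("box-counting dimension recovers line, plane, and Sierpinski", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.05)
  square <- matrix(TRUE, 512, 512)
  expect_lt(abs(fractal_dimension(square) - 2), 0.05)
  sier <- sierpinski_mask(9)  # depth 9 self-similar pattern
  expect_lt(abs(fractal_dimension(sier) - log(3) / log(2)), 0.05)
})

test_that("fractal dimension demands enough scales and occupancy", {
  expect_error(fractal_dimension(matrix(TRUE, 6, 6)), "insufficient scales")
  one_px <- matrix(FALSE, 512, 512); one_px[1, 1] <- TRUE
  expect_error(fractal_dimension(one_px), "occupied boxes")
})

test_that("AVR follows the caliber ratio of labelled segments", {
  mk <- function(y, r, label, id) {
    s <- straight_segment(10, y, 200, y, radius = r, label = label)
    s$id <- id
    s
  }
  g <- structure(list(
    nodes = data.frame(id = 1:8, x = 0, y = 0, degree = 1,
                       kind = "endpoint"),
    segments = list(mk(20, 2, "artery", 1L), mk(40, 2, "artery", 2L),
                    mk(60, 2.5, "vein", 3L), mk(80, 2.5, "vein", 4L))
  ), class = "vessel_graph")
  expect_equal(arteriole_venule_ratio(g), 0.8, tolerance = 1e-9)
  # all-equal calibers give exactly 1
  g2 <- g
  for (k in 3:4) g2$segments[[k]]$radius[] <- 2
  expect_equal(arteriole_venule_ratio(g2), 1, tolerance = 1e-9)
  # missing class is undefined
  g3 <- g
  g3$segments <- g3$segments[1:2]
  expect_message(v <- arteriole_venule_ratio(g3), "missing")
  expect_true(is.na(v))
})

test_that("disc and cup areas convert to mm^2 with the pixel pitch", {
  disc_e <- list(cx = 0, cy = 0, a = 100, b = 100, theta = 0)
  cup_e <- list(cx = 0, cy = 0, a = 50, b = 50, theta = 0)
  m <- disc_cup_metrics(disc_e, cup_e, pitch = 10)
  expect_equal(unname(m["disc_area_mm2"]), pi, tolerance = 1e-9)
  expect_equal(unname(m["cdr"]), 0.25, tolerance = 1e-9)
  # containment violation errors
  big_cup <- list(cx = 60, cy = 0, a = 50, b = 50, theta = 0)
  expect_error(disc_cup_metrics(disc_e, big_cup, pitch = 10), "contained")
})

test_that("global metrics are invariant under a 90-degree scene rotation", {
  sc <- gate_scene()
  tr <- sc$truth
  rot90 <- function(m) t(m[nrow(m):1, ])       # counter-clockwise
  mask <- tr$vessel_mask
  g1 <- build_graph(skeletonize(mask), mask)
  mask_r <- rot90(mask)
  g2 <- build_graph(skeletonize(mask_r), mask_r)
  # density and fractal dimension on full frame
  expect_equal(vessel_density(mask_r), vessel_density(mask))
  expect_lt(abs(fractal_dimension(mask_r) - fractal_dimension(mask)), 0.03)
  # length-weighted tortuosity
  agg <- function(g) {
    num <- 0; den <- 0
    for (s in g$segments) {
      len <- polyline_length(s$points)
      if (len < 40 || mean(s$radius) < 2) next   # resolvable segments only
      tv <- suppressMessages(measure_tortuosity(s, lowpass = 20))
      if (is.na(tv)) next
      num <- num + tv * len; den <- den + len
    }
    num / den
  }
  expect_lt(abs(agg(g2) - agg(g1)) / agg(g1), 0.1)
})

test_that("physical calibers are preserved across a 2x pixel pitch change", {
  a <- default_scene(seed = 6, size = 1024, noise_level = 0)
  b <- default_scene(seed = 6, size = 512, noise_level = 0)
  vc <- function(sc) {
    mask <- sc$truth$vessel_mask
    g <- build_graph(skeletonize(mask), mask)
    wsum <- 0; wn <- 0
    for (s in g$segments) {
      if (polyline_length(s$points) < 8) next
      w <- .interior_widths(s)
      wsum <- wsum + sum(w); wn <- wn + length(w)
    }
    (wsum / wn) * sc$image$pixel_pitch
  }
  # px calibers halve while the um pitch doubles; um calibers agree
  vca <- vc(a); vcb <- vc(b)
  expect_lt(abs(vcb / vca - 1), 0.05)
})
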