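test_that("preprocessing a uniform fundus yields near-zero inside the ROI", {
  px <- array(0, dim = c(256, 256, 3))
  circ <- radial_dist(256, 256, 128.5, 128.5) <= 127
  for (k in 1:3) {
    ch <- matrix(0, 256, 256); ch[circ] <- 0.5
    px[, , k] <- ch
  }
  img <- structure(list(pixels = px, pixel_pitch = 10, eye = "OD",
                        subject_id = "u"), class = "fundus_image")
  pre <- preprocess(img)
  expect_lt(max(abs(pre$pixels[pre$roi_mask])), 1e-6)
})

test_that("preprocessing is idempotent and reduces background variance", {
  sc <- small_scene(1)
  pre1 <- preprocess(sc$image)
  pre2 <- preprocess(pre1)
  rng <- diff(range(pre1$pixels))
  expect_lt(max(abs(pre2$pixels - pre1$pixels)), 1e-3 * rng)
  # illumination removal: background variance strictly lower than in the
  # raw green channel (variances computed directly over background pixels)
  bg <- pre1$roi_mask & !sc$truth$vessel_mask
  expect_lt(var(pre1$pixels[bg]), var(sc$image$pixels[, , 2][bg]))
})

test_that("an image with no fundus circle is rejected by name", {
  px <- array(0.001, dim = c(128, 128, 3))
  img <- structure(list(pixels = px, pixel_pitch = 10, eye = "OD",
                        subject_id = "x"), class = "fundus_image")
  expect_error(preprocess(img), "fundus circle")
})

test_that("segmentation passes the recognition floors on the default scene", {
  sc <- gate_scene()
  pre <- preprocess(sc$image)
  mask <- segment_vessels(pre)
  q <- segmentation_quality(mask, sc$truth$vessel_mask, pre$roi_mask)
  expect_gte(q[["sensitivity"]], 0.85)
  expect_gte(q[["specificity"]], 0.96)
})

test_that("a blank fundus yields an empty vessel mask", {
  px <- array(0, dim = c(256, 256, 3))
  circ <- radial_dist(256, 256, 128.5, 128.5) <= 127
  base <- c(0.8, 0.52, 0.25)
  for (k in 1:3) {
    ch <- matrix(0, 256, 256); ch[circ] <- base[k]
    px[, , k] <- ch
  }
  img <- structure(list(pixels = px, pixel_pitch = 10, eye = "OD",
                        subject_id = "b"), class = "fundus_image")
  expect_equal(sum(segment_vessels(img)), 0)
})

test_that("adding coarser vesselness scales can only add vessel-body pixels", {
  sc <- small_scene(2)
  pre <- preprocess(sc$image)
  m_multi <- segment_vessels(pre, scales = c(2, 4, 8))
  m_single <- segment_vessels(pre, scales = 2)
  body <- sc$truth$vessel_mask
  expect_gte(sum(m_multi & body), sum(m_single & body))
})

test_that("disc and cup are localized and sized against truth", {
  sc <- gate_scene()
  fit <- detect_disc_cup(sc$image)
  d_true <- sc$truth$disc
  err <- sqrt((fit$disc$cx - d_true$center[1])^2 +
                (fit$disc$cy - d_true$center[2])^2)
  expect_lt(err, 5)
  area_fit <- pi * fit$disc$a * fit$disc$b
  area_true <- pi * d_true$disc_radius^2
  expect_lt(abs(area_fit / area_true - 1), 0.10)
  # cup containment invariant
  q <- seq(0, 2 * pi, length.out = 60)
  cx <- fit$cup$cx + fit$cup$a * cos(q) * cos(fit$cup$theta) -
    fit$cup$b * sin(q) * sin(fit$cup$theta)
  cy <- fit$cup$cy + fit$cup$a * cos(q) * sin(fit$cup$theta) +
    fit$cup$b * sin(q) * cos(fit$cup$theta)
  u <- (cx - fit$disc$cx) * cos(fit$disc$theta) +
    (cy - fit$disc$cy) * sin(fit$disc$theta)
  v <- -(cx - fit$disc$cx) * sin(fit$disc$theta) +
    (cy - fit$disc$cy) * cos(fit$disc$theta)
  expect_true(all((u / fit$disc$a)^2 + (v / fit$disc$b)^2 <= 1.05))
})

test_that("cup rendered at 0.3 of the disc radius is recovered near 0.09", {
  disc <- disc_spec(center = c(513, 513), disc_radius = 90,
                    cup_radius = 27, pixel_pitch = 10)
  sc <- default_scene(seed = 4, size = 1024, disc = disc)
  fit <- detect_disc_cup(sc$image)
  ratio <- (fit$cup$a * fit$cup$b) / (fit$disc$a * fit$disc$b)
  expect_lt(abs(ratio - 0.09), 0.05)
})

test_that("an image without a disc raises 'disc not found'", {
  px <- array(0, dim = c(256, 256, 3))
  circ <- radial_dist(256, 256, 128.5, 128.5) <= 127
  base <- c(0.8, 0.52, 0.25)
  for (k in 1:3) {
    ch <- matrix(0, 256, 256); ch[circ] <- base[k]
    px[, , k] <- ch
  }
  img <- structure(list(pixels = px, pixel_pitch = 10, eye = "OD",
                        subject_id = "nodisc"), class = "fundus_image")
  expect_error(detect_disc_cup(img), "disc not found")
})

test_that("artery/vein labels pass through ground truth unchanged", {
  sc <- small_scene(1)
  lab <- classify_artery_vein(sc$truth$vessel_mask, sc$image,
                              truth = sc$truth)
  expect_identical(lab$artery_mask, sc$truth$artery_mask)
  expect_identical(lab$vein_mask, sc$truth$vein_mask)
})

test_that("the intensity heuristic separates a dark-wide vein from an artery", {
  disc <- disc_spec(center = c(256, 256), disc_radius = 45,
                    cup_radius = 20, pixel_pitch = 20)
  sa <- straight_segment(100, 150, 420, 150, radius = 4, label = "artery")
  sv <- straight_segment(100, 350, 420, 350, radius = 5, label = "vein")
  sc <- render_fundus(list(
    structure(list(nodes = data.frame(id = 1:2, x = 0, y = 0, degree = 1,
                                      kind = "endpoint"),
                   segments = list(sa),
                   per_segment_truth = data.frame(),
                   per_branch_truth = data.frame()),
              class = "vessel_graph"),
    structure(list(nodes = data.frame(id = 1:2, x = 0, y = 0, degree = 1,
                                      kind = "endpoint"),
                   segments = list(sv),
                   per_segment_truth = data.frame(),
                   per_branch_truth = data.frame()),
              class = "vessel_graph")
  ), disc, frame = c(512, 512), noise_level = 0.01, seed = 2)
  lab <- classify_artery_vein(sc$truth$vessel_mask, preprocess(sc$image))
  # the heuristic must reproduce the rendered truth exactly on this scene
  expect_identical(lab$vein_mask, sc$truth$vein_mask)
  expect_identical(lab$artery_mask, sc$truth$artery_mask)
})

test_that("a single tree gets one empty and one non-empty label mask", {
  mask <- band_mask(128, 256, 64, 5)
  px <- array(0.5, dim = c(128, 256, 3))
  img <- structure(list(pixels = px, pixel_pitch = 10, eye = "OD",
                        subject_id = "one"), class = "fundus_image")
  lab <- classify_artery_vein(mask, img)
  n_art <- sum(lab$artery_mask); n_vein <- sum(lab$vein_mask)
  expect_true(xor(n_art == 0, n_vein == 0))
  expect_equal(n_art + n_vein, sum(mask))
})
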