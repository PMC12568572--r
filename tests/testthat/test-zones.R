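test_that("PD is the equal-area circle diameter", {
  expect_equal(disc_diameter_pd(list(cx = 0, cy = 0, a = 60, b = 60,
                                     theta = 0)), 120)
  expect_equal(disc_diameter_pd(list(cx = 0, cy = 0, a = 50, b = 72,
                                     theta = 0.3)), 2 * sqrt(50 * 72))
})

test_that("annulus membership and area match the per-pixel oracle", {
  disc_e <- list(cx = 200.5, cy = 200.5, a = 60, b = 60, theta = 0)
  reg <- annulus_region(disc_e, 0.5, 1.0, c(400, 400))
  # brute force: distance from center in [60 + 60, 60 + 120)
  cnt <- 0
  for (y in 1:400) {
    d <- sqrt((1:400 - 200.5)^2 + (y - 200.5)^2)
    cnt <- cnt + sum(d - 60 >= 60 & d - 60 < 120)
  }
  expect_equal(sum(reg), cnt)
  # analytic area within discretization error (~perimeter pixels)
  analytic <- pi * (180^2 - 120^2)
  expect_lt(abs(sum(reg) - analytic) / analytic, 0.02)
})

test_that("the zero-to-infinite annulus is the disc complement", {
  disc_e <- list(cx = 100, cy = 100, a = 30, b = 30, theta = 0)
  reg <- annulus_region(disc_e, 0, Inf, c(200, 200))
  d <- radial_dist(200, 200, 100, 100)
  expect_identical(reg, d >= 30)
})

test_that("default annulus labels match the reporting convention", {
  sc <- small_scene(1)
  zones <- peripapillary_zones(list(cx = 250, cy = 250, a = 40, b = 40,
                                    theta = 0), "OD", c(512, 512))
  expect_identical(names(zones)[1:4],
                   c("0.5–1.0 PD", "1.0–1.5 PD",
                     "1.5–2.0 PD", "2.0–2.5 PD"))
  expect_identical(names(zones)[5:8],
                   c("Superior", "Nasal", "Inferior", "Temporal"))
})

test_that("quadrant membership follows laterality and direction", {
  disc_e <- list(cx = 250, cy = 250, a = 40, b = 40, theta = 0)
  dimm <- c(512, 512)
  # a point straight above the disc center, 1 PD beyond the border
  y_up <- 250 - (40 + 80)
  sup <- quadrant_region(disc_e, "Superior", "OD", dimm)
  expect_true(sup[y_up, 250])
  inf <- quadrant_region(disc_e, "Inferior", "OD", dimm)
  expect_true(inf[250 + 120, 250])
  # nasal is +x for OD, -x for OS; superior unchanged by laterality
  nas_od <- quadrant_region(disc_e, "Nasal", "OD", dimm)
  nas_os <- quadrant_region(disc_e, "Nasal", "OS", dimm)
  tem_os <- quadrant_region(disc_e, "Temporal", "OS", dimm)
  expect_true(nas_od[250, 250 + 120])
  expect_false(nas_os[250, 250 + 120])
  expect_true(tem_os[250, 250 + 120])
  sup_os <- quadrant_region(disc_e, "Superior", "OS", dimm)
  expect_identical(sup, sup_os)
  expect_error(quadrant_region(disc_e, "Nasal", "XX", dimm), "laterality")
})

test_that("annuli are pairwise disjoint and quadrants partition the band", {
  disc_e <- list(cx = 230, cy = 260, a = 42, b = 38, theta = 0.4)
  dimm <- c(512, 512)
  zones <- peripapillary_zones(disc_e, "OD", dimm)
  ann <- zones[1:4]
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(any(ann[[i]] & ann[[j]]))
  }
  quads <- zones[5:8]
  total <- Reduce(`+`, lapply(quads, function(m) matrix(as.numeric(m),
                                                        dimm[1], dimm[2])))
  band <- annulus_region(disc_e, 0.5, 2.5, dimm)
  expect_true(all(total[band] == 1))
  expect_true(all(total[!band] == 0))
  # quadrant areas sum exactly to the band area
  expect_equal(sum(vapply(quads, sum, numeric(1))), sum(band))
})

test_that("annulus density and caliber decrease outward on default scenes", {
  vd_all <- matrix(0, 2, 4); vc_all <- matrix(0, 2, 4)
  for (i in 1:2) {
    sc <- default_scene(seed = 20 + i, size = 1024, noise_level = 0)
    tr <- sc$truth
    disc_e <- list(cx = tr$disc$center[1], cy = tr$disc$center[2],
                   a = tr$disc$disc_radius, b = tr$disc$disc_radius,
                   theta = 0)
    mask <- tr$vessel_mask
    g <- build_graph(skeletonize(mask), mask)
    for (z in 1:4) {
      reg <- annulus_region(disc_e, 0.5 + (z - 1) * 0.5, 1 + (z - 1) * 0.5,
                            dim(mask))
      vd_all[i, z] <- vessel_density(mask, reg)
      wsum <- 0; wn <- 0
      for (s in g$segments) {
        if (polyline_length(s$points) < 10) next
        w <- .interior_widths(s, reg)
        if (length(w)) { wsum <- wsum + sum(w); wn <- wn + length(w) }
      }
      vc_all[i, z] <- wsum / wn
    }
  }
  expect_true(all(diff(colMeans(vd_all)) <= 0))
  expect_true(all(diff(colMeans(vc_all)) <= 0))
})
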