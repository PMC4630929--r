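# Thresholding, component labeling, scene classification, calibration.

test_that("binary_mask thresholds above-level pixels and opens speckle", {
  img0 <- as_root_image(matrix(0, 30, 30))
  expect_false(any(binary_mask(img0, 0.5)$mask))

  # 10x10 block survives the 3x3 cross opening except its four corner
  # pixels, which no cross translate inside the block can cover
  m <- matrix(0, 40, 40); m[11:20, 11:20] <- 1
  bm <- binary_mask(as_root_image(m), 0.5)
  expect_identical(sum(bm$mask), 96L)
  expect_true(all(bm$mask[12:19, 12:19]))

  # brute-force oracle: same threshold + same opening, via EBImage on
  # the raw comparison (isolated speckle must vanish)
  set.seed(5)
  nz <- matrix(runif(60 * 60) * 0.4, 60, 60)
  nz[20:40, 25:35] <- 0.9
  nz[5, 5] <- 0.99                      # isolated speckle
  bm2 <- binary_mask(as_root_image(nz), 0.5)
  raw <- nz > 0.5
  opened <- EBImage::opening(raw * 1, EBImage::makeBrush(3, "diamond")) > 0.5
  expect_identical(bm2$mask, opened)
  expect_false(bm2$mask[5, 5])

  expect_error(binary_mask(img0, 1.5), class = "rootcrown_invalid_input")
})

test_that("calibration sweep matches per-threshold recomputation and is monotone", {
  set.seed(9)
  px <- matrix(runif(80 * 80), 80, 80)
  px[20:60, 30:50] <- 0.55              # mid-gray root
  img <- as_root_image(px)
  sw <- calibration_sweep(img, c(0.2, 0.5, 0.8))
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$fg_fraction) <= 0))

  # singleton sweep equals binary_mask
  sw1 <- calibration_sweep(img, 0.4)
  expect_identical(sw1$mask[[1]]$mask, binary_mask(img, 0.4)$mask)

  # summaries match independent recomputation
  for (i in seq_len(nrow(sw))) {
    m <- binary_mask(img, sw$threshold[i])$mask
    expect_equal(sw$fg_fraction[i], mean(m))
    expect_identical(sw$n_components[i], max(flood_label8(m)))
  }
  expect_error(calibration_sweep(img, numeric(0)),
               class = "rootcrown_invalid_input")

  # masks writable for visual inspection
  td <- withr::local_tempdir()
  paths <- write_sweep_masks(sw, td)
  expect_true(all(file.exists(paths)))
})

test_that("component labeling is 8-connected with flood-fill-equivalent labels", {
  # two disjoint 5x5 blocks
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:6] <- TRUE; m[20:24, 20:24] <- TRUE
  comp <- label_components(m)
  expect_identical(nrow(comp), 2L)
  expect_equal(comp$area, c(25, 25))

  # diagonal chain is a single component under 8-connectivity
  d <- matrix(FALSE, 12, 12); d[cbind(2:10, 2:10)] <- TRUE
  expect_identical(nrow(label_components(d)), 1L)

  # random blobs: partition identical to brute-force flood fill
  for (seed in c(3, 17, 31)) {
    b <- random_blob(40, seed)
    got <- attr(label_components(b), "labels")
    want <- flood_label8(b)
    # same partition (label ids may differ): cross-tabulation is a
    # permutation matrix
    tab <- table(got[b], want[b])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }

  # empty mask -> empty list
  expect_identical(nrow(label_components(matrix(FALSE, 5, 5))), 0L)

  # perimeter/circularity: 100x10 bar scores the isoperimetric quotient
  bar <- matrix(FALSE, 120, 30); bar[11:110, 11:20] <- TRUE
  cbar <- label_components(bar)
  expect_equal(cbar$circularity, 4 * pi * 1000 / 216^2, tolerance = 1e-6)
})

test_that("scene classification finds marker, tag and root", {
  cfg <- pipeline_config()
  px <- matrix(0.05, 400, 400)
  # disc marker
  rg <- row(px); cg <- col(px)
  px[(rg - 320)^2 + (cg - 60)^2 <= 40^2] <- 0.95
  # dense tag above the root
  px[20:60, 150:260] <- 0.95
  # branched blob (root) below the tag
  m <- matrix(FALSE, 400, 400)
  m <- draw_stroke(m, c(100, 200), c(330, 200), 12)
  m <- draw_stroke(m, c(180, 200), c(300, 120), 8)
  m <- draw_stroke(m, c(200, 200), c(320, 290), 8)
  px[m] <- 0.9
  img <- as_root_image(px)
  comp <- label_components(binary_mask(img, 0.5))
  scene <- classify_components(comp, img, cfg)

  mk <- scene$components[scene$components$label == scene$marker_label, ]
  expect_gte(mk$circularity, 0.7)
  expect_equal(mk$centroid_r, 320, tolerance = 2)
  tg <- scene$components[scene$components$label == scene$tag_label, ]
  expect_equal(tg$area, 41 * 111, tolerance = 20)
  rt <- scene$components[scene$components$label == scene$root_label, ]
  expect_identical(rt$label, comp$label[which.max(comp$area)])

  # permutation invariance of the component list
  set.seed(1)
  perm <- comp[sample(nrow(comp)), ]
  attr(perm, "labels") <- attr(comp, "labels")
  scene2 <- classify_components(perm, img, cfg)
  expect_identical(scene2$marker_label, scene$marker_label)
  expect_identical(scene2$tag_label, scene$tag_label)
  expect_identical(scene2$root_label, scene$root_label)

  # single blob only -> root, no marker, no tag
  px2 <- matrix(0.05, 100, 100); px2[30:70, 40:60] <- 0.9
  img2 <- as_root_image(px2)
  sc2 <- classify_components(label_components(binary_mask(img2, 0.5)), img2, cfg)
  expect_true(is.na(sc2$marker_label))
  expect_true(is.na(sc2$tag_label))

  # an elongated bar is never selected as marker (circularity ~0.27)
  px3 <- matrix(0.05, 200, 200)
  px3[50:149, 20:29] <- 0.95             # 100x10 bar
  px3[60:160, 120:140] <- 0.9            # elongated root
  img3 <- as_root_image(px3)
  sc3 <- classify_components(label_components(binary_mask(img3, 0.5)), img3, cfg)
  expect_true(is.na(sc3$marker_label))

  # empty scene -> no-root error
  blank <- as_root_image(matrix(0, 50, 50))
  expect_error(
    classify_components(label_components(binary_mask(blank, 0.5)), blank, cfg),
    class = "rootcrown_no_root")
})

test_that("marker calibration recovers pixels per mm within 2%", {
  # analytic disc area: radius 50 px, known diameter 20 mm -> 5 px/mm
  comp <- label_components(disc_mask(50))
  sc <- scale_from_marker(comp[1, ], 20)
  expect_equal(sc$pixels_per_mm, 5, tolerance = 0.02)
  # linearity in the known diameter
  sc2 <- scale_from_marker(comp[1, ], 100)
  expect_equal(sc2$pixels_per_mm, 1, tolerance = 0.02)
  expect_equal(sc$pixels_per_mm / sc2$pixels_per_mm, 5, tolerance = 1e-9)
  # invariant: pixels_per_mm * known_diameter = equivalent diameter
  expect_equal(sc$pixels_per_mm * sc$marker_known_diameter_mm,
               sc$marker_equivalent_diameter_px)

  # rasterization study: radii 20..100
  for (r in seq(20, 100, 20)) {
    comp <- label_components(disc_mask(r))
    d_px <- scale_from_marker(comp[1, ], 20)$marker_equivalent_diameter_px
    expect_lt(abs(d_px - 2 * r) / (2 * r), 0.02)
    # brute-force pixel-count oracle
    expect_equal(d_px, 2 * sqrt(sum(disc_mask(r)) / pi), tolerance = 1e-12)
  }

  expect_error(scale_from_marker(comp[1, ], -3),
               class = "rootcrown_invalid_input")
})

test_that("tag crop pads by 5 px and clips to the image", {
  cfg <- pipeline_config()
  px <- matrix(0.05, 500, 500)
  px[11:50, 11:200] <- 0.95            # tag at the corner-ish top
  px[100:400, 230:270] <- 0.9          # elongated root below
  img <- as_root_image(px)
  scene <- classify_components(label_components(binary_mask(img, 0.5)), img, cfg)
  crop <- crop_tag(scene, img)
  expect_identical(dim(crop), c(50L, 200L))   # 40+2*5 rows, 190+2*5 cols

  # no tag -> NULL
  px2 <- matrix(0.05, 100, 100); px2[40:80, 30:70] <- 0.9
  img2 <- as_root_image(px2)
  sc2 <- classify_components(label_components(binary_mask(img2, 0.5)), img2, cfg)
  expect_null(crop_tag(sc2, img2))

  # tag at the image corner: crop clipped to bounds
  px3 <- matrix(0.05, 300, 300)
  px3[1:40, 1:120] <- 0.95
  px3[100:280, 160:200] <- 0.9
  img3 <- as_root_image(px3)
  sc3 <- classify_components(label_components(binary_mask(img3, 0.5)), img3, cfg)
  crop3 <- crop_tag(sc3, img3)
  expect_identical(dim(crop3), c(45L, 125L))
})
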