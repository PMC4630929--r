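# Trait registry and the four trait families.

make_scene <- function(px, threshold = 0.5, cfg = pipeline_config()) {
  img <- as_root_image(px)
  classify_components(label_components(binary_mask(img, threshold)), img, cfg)
}

test_that("the registry has 78 unique traits across the four categories", {
  reg <- trait_registry()
  expect_identical(nrow(reg), 78L)
  expect_identical(anyDuplicated(reg$trait), 0L)
  counts <- table(reg$category)
  expect_identical(sort(names(counts)),
                   c("common", "dicot", "excised", "monocot"))
  expect_identical(as.integer(counts[c("common", "monocot", "dicot", "excised")]),
                   c(31L, 22L, 15L, 10L))
})

test_that("width profile records per-row extents (not counts)", {
  # 40-wide rectangle: every extent 40
  px <- matrix(0.05, 260, 100); px[31:230, 31:70] <- 0.9
  prof <- width_profile(make_scene(px))
  # the 3x3 cross opening clips the four rectangle corners, so the
  # first and last rows are 2 px narrower
  expect_true(all(prof$extent_px[2:199] == 40))
  expect_identical(nrow(prof), 200L)

  # triangle widening 1 -> 101 px over 101 rows: arithmetic sequence,
  # verified per-row against a brute-force scan of the mask
  px2 <- matrix(0.05, 160, 160)
  for (i in 0:100) {
    px2[30 + i, (80 - i / 2):(80 + i / 2)] <- 0.9
  }
  scene2 <- make_scene(px2)
  prof2 <- width_profile(scene2)
  rm <- root_mask_of(scene2)
  for (k in seq_len(nrow(prof2))) {
    cols <- which(rm[prof2$row[k], ])
    want <- if (length(cols) == 0) 0 else diff(range(cols)) + 1
    expect_identical(prof2$extent_px[k], as.numeric(want))
  }
  # sequence widens ~1 px per row overall
  expect_gte(stats::cor(prof2$row, prof2$extent_px), 0.99)

  # C-shape: extent spans the gap, by definition
  px3 <- matrix(0.05, 100, 100)
  px3[20:80, 20:30] <- 0.9   # left limb
  px3[20:30, 20:80] <- 0.9   # top limb
  px3[70:80, 20:80] <- 0.9   # bottom limb
  prof3 <- width_profile(make_scene(px3))
  mid <- prof3[prof3$row == 50, ]
  expect_identical(mid$extent_px, 11)        # extent of the left limb only
  top <- prof3[prof3$row == 25, ]
  expect_identical(top$extent_px, 61)        # spans the C opening
})

test_that("shape traits match closed-form values on a rectangle and a brute-force oracle", {
  px <- matrix(0.05, 260, 100); px[31:230, 31:70] <- 0.9
  scene <- make_scene(px)
  prof <- width_profile(scene)
  skel <- skeletonize(root_mask_of(scene))
  rec <- compute_shape_traits(prof, scene, skel, scale = NULL)
  v <- setNames(rec$value, rec$trait)
  expect_equal(v[["WIDTH_MED"]], 40)
  expect_equal(v[["WIDTH_MAX"]], 40)
  expect_equal(v[["AVG_DENSITY"]], 1, tolerance = 1e-3)  # opened corners
  expect_equal(v[["RDISTR_X"]], 0.5, tolerance = 1e-9)
  expect_equal(v[["RDISTR_Y"]], 0.5, tolerance = 1e-9)
  expect_equal(v[["AREA"]], 200 * 40 - 4)                # opened corners
  expect_equal(v[["D50"]], 0.5, tolerance = 1 / 200)

  # same rectangle at 4 px/mm: widths in mm
  sc4 <- structure(list(pixels_per_mm = 4), class = "scale_info")
  v4 <- with(compute_shape_traits(prof, scene, skel, sc4),
             setNames(value, trait))
  expect_equal(v4[["WIDTH_MED"]], 10)
  expect_equal(v4[["AREA"]], (200 * 40 - 4) / 16)

  # random blob: every trait equals independent brute-force recomputation
  set.seed(12)
  blob <- random_blob(60, 12, density = 0.8)
  pxb <- matrix(0.05, 60, 60); pxb[blob] <- 0.9
  sceneb <- make_scene(pxb)
  rmb <- root_mask_of(sceneb)
  profb <- width_profile(sceneb)
  recb <- compute_shape_traits(profb, sceneb, skeletonize(rmb), NULL)
  vb <- setNames(recb$value, recb$trait)
  idx <- which(rmb, arr.ind = TRUE)
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  ext <- vapply(rows[1]:rows[2], function(r) {
    cc <- idx[idx[, 1] == r, 2]
    if (length(cc) == 0) 0 else diff(range(cc)) + 1
  }, numeric(1))
  expect_equal(vb[["AREA"]], nrow(idx))
  expect_equal(vb[["WIDTH_MED"]], median(ext[ext > 0]))
  expect_equal(vb[["WIDTH_MAX"]], max(ext))
  expect_equal(vb[["AVG_DENSITY"]],
               nrow(idx) / ((diff(rows) + 1) * (diff(cols) + 1)))
  cum <- cumsum(ext) / sum(ext)
  H <- length(ext)
  for (x in seq(10, 90, 10)) {
    expect_equal(vb[[paste0("D", x)]], which(cum >= x / 100)[1] / H)
  }
})

test_that("stem diameter recovers drawn widths and scales with calibration", {
  # vertical bar, width 20, on its own: DIA_STM ~ 20, DIA_STM_SIMPLE = 20
  px <- matrix(0.05, 440, 120); px[21:420, 51:70] <- 0.9
  scene <- make_scene(px)
  cfg <- pipeline_config()
  rm <- root_mask_of(scene)
  skel <- skeletonize(rm)
  graph <- prune_spurs(build_skeleton_graph(skel), cfg$min_spur_len)
  paths <- root_tip_paths(graph, find_collar(graph, scene))
  prof <- width_profile(scene)
  rec <- compute_stem_traits(paths, prof, skel, NULL, cfg)
  v <- setNames(rec$value, rec$trait)
  expect_equal(v[["DIA_STM"]], 20, tolerance = 0.1)        # +-2 px
  expect_equal(v[["DIA_STM_SIMPLE"]], 20)
  expect_identical(v[["RTP_COUNT"]], 1)

  # halved when the scale doubles
  s2 <- structure(list(pixels_per_mm = 2), class = "scale_info")
  v2 <- with(compute_stem_traits(paths, prof, skel, s2, cfg),
             setNames(value, trait))
  expect_equal(v2[["DIA_STM"]], v[["DIA_STM"]] / 2)
  expect_equal(v2[["DIA_STM_SIMPLE"]], 10)

  # fans with stems drawn at widths 8..40: recovered within 10%
  for (w in c(8, 16, 28, 40)) {
    sc <- render_scene(synthetic_root_spec("monocot_fan", stem_width = w,
                                           seed = w))
    res <- process_image(sc$image, pipeline_config())
    tv <- sc$truth
    got <- res$record$value[res$record$trait == "DIA_STM"]
    want <- tv$value[tv$trait == "DIA_STM"]
    expect_lt(abs(got - want) / want, 0.1)
  }
})

test_that("top and bottom angles follow boundary geometry", {
  cfg <- pipeline_config()
  # vertical bar: both angles 90
  px <- matrix(0.05, 440, 120); px[21:420, 51:70] <- 0.9
  scene <- make_scene(px)
  rec <- compute_angle_traits(scene, width_profile(scene), cfg)
  v <- setNames(rec$value, rec$trait)
  expect_equal(v[["ANG_TOP"]], 90, tolerance = 1)
  expect_equal(v[["ANG_BTM"]], 90, tolerance = 1)

  # symmetric wedge with sides at 30 degrees from vertical:
  # boundary angle 60 degrees from horizontal on both bands
  px2 <- matrix(0.05, 400, 400)
  m <- matrix(FALSE, 400, 400)
  apex <- c(30, 200)
  for (a in c(-30, 30)) {
    th <- a * pi / 180
    m <- draw_stroke(m, apex, apex + 330 * c(cos(th), sin(th)), 7)
  }
  # fill the wedge so the outer strokes are the boundary
  px2[m] <- 0.9
  scene2 <- make_scene(px2)
  rec2 <- compute_angle_traits(scene2, width_profile(scene2), cfg)
  v2 <- setNames(rec2$value, rec2$trait)
  expect_equal(v2[["ANG_TOP"]], 60, tolerance = 3)

  # asymmetric wedge (20 and 40 degrees from vertical):
  # mean of side angles (70 + 50)/2 = 60
  m3 <- matrix(FALSE, 400, 400)
  for (a in c(-20, 40)) {
    th <- a * pi / 180
    m3 <- draw_stroke(m3, apex, apex + 330 * c(cos(th), sin(th)), 7)
  }
  px3 <- matrix(0.05, 400, 400); px3[m3] <- 0.9
  scene3 <- make_scene(px3)
  v3 <- with(compute_angle_traits(scene3, width_profile(scene3), cfg),
             setNames(value, trait))
  expect_equal(v3[["ANG_TOP"]], 60, tolerance = 3)
})

test_that("monocot angles, dominant bins and drop-off behave on constructed fans", {
  cfg <- pipeline_config()

  run_fan <- function(angles, widths = 7, depth = 310) {
    # stroke lengths equalized in depth so every path samples every
    # depth fraction; canvas wide enough for the shallowest stroke
    m <- matrix(FALSE, 430, 1100)
    apex <- c(60, 550)
    m <- draw_stroke(m, c(20, 550), apex, 9)
    for (a in angles) {
      th <- a * pi / 180
      m <- draw_stroke(m, apex, apex + depth / cos(th) * c(cos(th), sin(th)),
                       widths)
    }
    px <- matrix(0.05, 430, 1100); px[m] <- 0.9
    scene <- make_scene(px)
    rm <- fill_small_holes(root_mask_of(scene), cfg$max_hole_area)
    skel <- skeletonize(rm)
    graph <- prune_spurs(build_skeleton_graph(skel), cfg$min_spur_len)
    paths <- root_tip_paths(graph, find_collar(graph, scene))
    prof <- width_profile(scene)
    list(rec = compute_monocot_traits(paths, skel, prof, NULL, cfg),
         paths = paths, prof = prof)
  }

  # 10 strokes all at +-45 degrees from vertical: STA ~ 45 from horizontal
  ang45 <- rep(c(-45, 45), 5) + rep(c(0, 2, -2, 4, -4), each = 2)
  out <- run_fan(c(-45, -44, -43, 45, 44, 43, -46, 46, -42, 42))
  v <- setNames(out$rec$value, out$rec$trait)
  expect_equal(v[["STA_DOM_I"]], 45, tolerance = 5.01)  # bin centre 45
  expect_lte(v[["STA_RANGE"]], 15)
  expect_true(all(abs(c(v[["STA_50_I"]], v[["STA_50_II"]]) - 45) <= 5))

  # two clusters: 5 strokes near 35 deg from horizontal (55 from
  # vertical), 3 near 65 (25 from vertical)
  out2 <- run_fan(c(-57, -55, 57, 55, 53, -25, 27, 25))
  v2 <- setNames(out2$rec$value, out2$rec$trait)
  expect_true(abs(v2[["STA_DOM_I"]] - 35) <= 5.01)
  expect_true(abs(v2[["STA_DOM_II"]] - 65) <= 5.01)
  expect_identical(v2[["NR_RTP_SEG_I"]], 5)
  expect_identical(v2[["NR_RTP_SEG_II"]], 3)

  # rectangle: extent never drops -> DROP_50 = 1
  pxr <- matrix(0.05, 260, 100); pxr[31:230, 31:70] <- 0.9
  scener <- make_scene(pxr)
  rmr <- root_mask_of(scener)
  skelr <- skeletonize(rmr)
  graphr <- prune_spurs(build_skeleton_graph(skelr), cfg$min_spur_len)
  pathsr <- root_tip_paths(graphr, find_collar(graphr, scener))
  recr <- compute_monocot_traits(pathsr, skelr, width_profile(scener), NULL, cfg)
  expect_identical(recr$value[recr$trait == "DROP_50"], 1)

  # single path: second-population traits are not applicable
  expect_identical(recr$status[recr$trait == "STA_DOM_II"], "not-applicable")
  expect_identical(recr$status[recr$trait == "NR_RTP_SEG_II"], "not-applicable")
})

test_that("dicot branch classification, angles and frequencies match drawn laterals", {
  # synthetic taproot 430 px at 4 px/mm with laterals at known depths
  sc <- render_scene(synthetic_root_spec(
    "dicot_taproot", seed = 5,
    lateral_z = c(0.25, 0.4, 0.55, 0.7, 0.3, 0.45, 0.6, 0.75),
    lateral_angle = 60, lateral_side = c(1, 1, 1, 1, -1, -1, -1, -1),
    lateral_length = 100))
  res <- process_image(sc$image, pipeline_config(root_class = "dicot"))
  v <- setNames(res$record$value, res$record$trait)
  # 8 laterals over 430 px = 107.5 mm
  expect_lt(abs(v[["LT_BRA_FRQ"]] - 8 / 107.5) / (8 / 107.5), 0.1)
  expect_equal(v[["LT_AVG_ANG"]], 60, tolerance = 4)
  expect_equal(v[["LT_MIN_ANG"]], 60, tolerance = 5)
  expect_equal(v[["LT_MAX_ANG"]], 60, tolerance = 5)
  expect_equal(v[["LT_DIST_FIRST"]], 0.25 * 430 / 4, tolerance = 3)
  expect_equal(v[["LT_AVG_LEN"]], 25, tolerance = 3)
  # all laterals beyond the basal band
  expect_identical(v[["ADVT_COUNT"]], 0)
  expect_identical(v[["BASAL_COUNT"]], 0)
  expect_identical(res$record$status[res$record$trait == "ADVT_ANG"],
                   "not-applicable")
})

test_that("excised segment traits follow step-count arithmetic", {
  cfg <- pipeline_config()
  # three straight bars: skeleton lengths ~ drawn lengths
  sc <- render_scene(synthetic_root_spec("excised_segments", seed = 2,
                                         segment_lengths = c(100, 150, 200),
                                         segment_width = 9))
  res <- process_image(sc$image, pipeline_config(root_class = "excised"))
  v <- setNames(res$record$value, res$record$trait)
  s <- 4   # px per mm in the default synthetic scene
  expect_identical(v[["EXC_SEG_COUNT"]], 3)
  expect_identical(v[["EXC_TIP_COUNT"]], 6)
  expect_equal(v[["EXC_MAX_LEN"]] * s, 200, tolerance = 12)
  expect_equal(v[["EXC_TOT_LEN"]] * s, 450, tolerance = 36)
  expect_identical(v[["EXC_BRA_FRQ"]], 0)
  # uniform width 9 px -> diameter within a pixel
  expect_equal(v[["EXC_MED_DIA"]] * s, 9, tolerance = 1)

  # one segment with a side branch: 3 tips, branching frequency 1/length
  px <- matrix(0.05, 200, 300)
  m <- matrix(FALSE, 200, 300)
  m <- draw_stroke(m, c(100, 40), c(100, 260), 9)
  m <- draw_stroke(m, c(100, 150), c(40, 190), 7)
  px[m] <- 0.9
  img <- as_root_image(px)
  scene <- classify_components(label_components(binary_mask(img, 0.5)), img, cfg)
  rec <- compute_excised_traits(scene, NULL, cfg)
  vv <- setNames(rec$value, rec$trait)
  expect_identical(vv[["EXC_SEG_COUNT"]], 1)
  expect_identical(vv[["EXC_TIP_COUNT"]], 3)
  expect_equal(vv[["EXC_BRA_FRQ"]], 1 / vv[["EXC_TOT_LEN"]])
})

test_that("compute_all dispatches classes, contains failures, and is deterministic", {
  sc <- render_scene(synthetic_root_spec("monocot_fan", seed = 4))
  cfg <- pipeline_config(root_class = "monocot")
  img <- sc$image
  scene <- classify_components(label_components(binary_mask(img, 0.5)), img, cfg)
  rec <- compute_all(scene, cfg)
  expect_s3_class(rec, "trait_record")
  expect_identical(nrow(rec), 78L)
  # dicot and excised all not-applicable
  expect_true(all(rec$status[rec$category %in% c("dicot", "excised")] ==
                    "not-applicable"))
  expect_true(all(rec$status[rec$category == "common"] == "ok"))

  # trait selection narrows the computed set
  cfg2 <- pipeline_config(root_class = "all",
                          trait_selection = c("AREA", "WIDTH_MAX"))
  rec2 <- compute_all(scene, cfg2)
  expect_identical(sum(rec2$status == "ok"), 2L)

  # determinism: identical input twice -> identical record
  rec3 <- compute_all(scene, cfg)
  expect_identical(rec$value, rec3$value)
  expect_identical(rec$status, rec3$status)

  # tidy/glance accessors
  td <- tidy(rec)
  expect_identical(nrow(td), 78L)
  gl <- glance(rec)
  expect_identical(gl$n_ok + gl$n_not_applicable + gl$n_failed, 78L)
  expect_identical(gl$units, "mm")
})
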