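half_disc_mask <- function() {
  ## flat edge at the top (row 20), curved cap below, radius 30
  m <- matrix(0, 100, 100)
  inside <- outer((1:100 - 20)^2, (1:100 - 50)^2, "+") <= 900 &
    row(m) >= 20
  m[inside] <- 1
  m
}

test_that("key points sit on the mitral chord ends and the apex", {
  kp <- find_lv_keypoints(half_disc_mask())
  ## mitral points at the two ends of the flat top edge
  expect_equal(kp$mitral_a[1L], 20, tolerance = 1)
  expect_equal(kp$mitral_b[1L], 20, tolerance = 1)
  expect_setequal(round(sort(c(kp$mitral_a[2L], kp$mitral_b[2L]))),
                  c(20, 80))
  expect_equal(kp$mitral_mid[2L], 50, tolerance = 1)
  ## apex at the bottom extreme of the cap
  expect_equal(kp$apex[1L], 50, tolerance = 1.5)
  expect_equal(kp$apex[2L], 50, tolerance = 1.5)
})

test_that("ellipse key points recover the long axis geometry", {
  e <- echoseg:::ellipse_mask(240, 200, c(120, 100), 80, 45)
  kp <- find_lv_keypoints(e)
  expect_equal(kp$apex[2L], 100, tolerance = 1.5)     # on the long axis
  expect_equal(kp$mitral_mid[2L], 100, tolerance = 1.5)
  len_px <- sqrt(sum((kp$apex - kp$mitral_mid)^2))
  expect_equal(len_px, 160, tolerance = 0.02)
  ## mitral chord roughly perpendicular to the long axis
  chord <- kp$mitral_b - kp$mitral_a
  expect_lt(abs(chord[1L]) / max(abs(chord[2L]), 1), 0.35)
})

test_that("degenerate masks are rejected", {
  expect_error(find_lv_keypoints(matrix(0, 10, 10)), "empty mask")
  m <- matrix(0, 10, 10); m[5, 5] <- 1
  expect_error(find_lv_keypoints(m), "degenerate")
})

test_that("length, area and Simpson volume follow their formulas", {
  kp <- structure(list(apex = c(200, 64), mitral_a = c(40, 54),
                       mitral_b = c(40, 74), mitral_mid = c(40, 64)),
                  class = "lv_keypoints")
  expect_equal(lv_length(kp, 0.05), 8)
  expect_equal(lv_length(kp, 0.10), 16)  # linear in spacing
  kp$apex <- kp$mitral_mid
  expect_error(lv_length(kp, 0.05), "coincides")

  m <- matrix(0, 30, 30); m[3:12, 5:14] <- 1  # 100 pixels
  expect_equal(region_area(m, 0.05), 0.25)
  expect_equal(region_area(matrix(0, 5, 5), 0.05), 0)
  m2 <- matrix(0, 30, 30); m2[13:22, 15:24] <- 1  # translated copy
  expect_equal(region_area(m2, 0.05), region_area(m, 0.05))

  expect_equal(simpson_volume(30, 8), 8 * 900 / (3 * pi * 8))
  expect_equal(simpson_volume(60, 8), 4 * simpson_volume(30, 8))
  expect_equal(simpson_volume(30, 16), simpson_volume(30, 8) / 2)
  expect_error(simpson_volume(30, 0), "> 0")
})

test_that("ED/ES detection is argmax/argmin with earliest-frame ties", {
  expect_identical(detect_ed_es(c(80, 100, 60, 90)),
                   list(ed_index = 2L, es_index = 3L))
  expect_identical(detect_ed_es(c(100, 100, 50))$ed_index, 1L)
  expect_warning(out <- detect_ed_es(c(70, 70, 70)), "constant")
  expect_identical(out, list(ed_index = 1L, es_index = 1L))
})

test_that("ejection fraction follows its definition and guards", {
  expect_equal(ejection_fraction(100, 40), 60)
  expect_equal(ejection_fraction(100, 100), 0)
  expect_equal(ejection_fraction(100, 0), 100)
  expect_error(ejection_fraction(50, 60), "mislabel")
})

test_that("LV quantification recovers the phantom's analytic truth", {
  ps <- generate_phantom_sequence(rand_phantom_spec(7L))
  rep_ <- quantify_lv_sequence(ps$masks, ps$pixel_spacing)
  expect_identical(rep_$ed_index, ps$true_ed_index)
  expect_identical(rep_$es_index, ps$true_es_index)
  expect_lt(abs(rep_$ef - ps$true_ef), 2)
  ## internal consistency of the report
  expect_equal(rep_$edv, max(rep_$volume))
  expect_equal(rep_$esv, min(rep_$volume))
  expect_equal(rep_$ef, 100 * (rep_$edv - rep_$esv) / rep_$edv)
})

test_that("identical masks in every frame give EF 0", {
  m <- echoseg:::ellipse_mask(120, 120, c(60, 60), 40, 25)
  expect_warning(rep_ <- quantify_lv_sequence(rep(list(m), 4L), 0.05),
                 "constant")
  expect_equal(rep_$ef, 0)
})

test_that("empty-mask frames are flagged and interpolated", {
  ps <- generate_phantom_sequence(phantom_spec(n_frames = 8L, seed = 5L))
  masks <- ps$masks
  masks[[4L]] <- matrix(0, nrow(masks[[1L]]), ncol(masks[[1L]]))
  rep_ <- quantify_lv_sequence(masks, ps$pixel_spacing)
  expect_identical(rep_$empty_frames, 4L)
  expect_true(is.finite(rep_$volume[4L]))
  expect_error(quantify_lv_sequence(rep(list(matrix(0, 5, 5)), 3L), 1),
               "all masks")
})

test_that("RV quantification requires expert phases and computes FAC", {
  ps <- generate_phantom_sequence(rand_phantom_spec(9L))
  rv <- quantify_rv_sequence(ps$masks, ps$pixel_spacing,
                             ps$true_ed_index, ps$true_es_index)
  ax <- echoseg:::phantom_axes(ps$spec)
  fac_true <- 100 * (1 - prod(ax[ps$true_es_index, ]) /
                       prod(ax[ps$true_ed_index, ]))
  expect_equal(rv$fac, fac_true, tolerance = 0.01)
  expect_equal(rv$fac, 100 * (rv$eda - rv$esa) / rv$eda)
  expect_error(quantify_rv_sequence(ps$masks, ps$pixel_spacing),
               "expert-supplied")
  m <- ps$masks[1:3]
  expect_equal(quantify_rv_sequence(m, 1, 1, 1)$fac, 0)
})

test_that("EF and FAC are invariant to pixel spacing", {
  ps <- generate_phantom_sequence(phantom_spec(n_frames = 10L, seed = 3L))
  r1 <- quantify_lv_sequence(ps$masks, 0.04)
  r2 <- quantify_lv_sequence(ps$masks, 0.08)
  expect_equal(r1$ef, r2$ef, tolerance = 1e-12)
  expect_identical(c(r1$ed_index, r1$es_index), c(r2$ed_index, r2$es_index))
  v1 <- quantify_rv_sequence(ps$masks, 0.04, 1L, 5L)
  v2 <- quantify_rv_sequence(ps$masks, 0.08, 1L, 5L)
  expect_equal(v1$fac, v2$fac, tolerance = 1e-12)
})

test_that("volumes from masks agree with the analytic ellipse family", {
  ps <- generate_phantom_sequence(phantom_spec(speckle_strength = 0,
                                               n_frames = 6L))
  rep_ <- quantify_lv_sequence(ps$masks, ps$pixel_spacing)
  expect_equal(rep_$volume, ps$true_volumes, tolerance = 0.03)
})
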