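test_that("phantom config validates contrast ordering and lesion parameters", {
  expect_error(phantom_config(wm_mean = 100, gm_mean = 110), "ordering")
  expect_error(phantom_config(ribbon_thickness_mm = 0), "ribbon_thickness")
  expect_error(lesion_spec(thickening_factor = 0.5), "thickening_factor")
  expect_error(lesion_spec(junction_blur_sigma_mm = -1), ">= 0")
})

test_that("phantom generation is deterministic and PV maps partition the head", {
  s1 <- generate_subject(small_cfg(seed = 42), "a")
  s2 <- generate_subject(small_cfg(seed = 42), "a")
  expect_identical(s1$volume$data, s2$volume$data)
  s <- small_control()
  pvsum <- s$pv_gm$data + s$pv_wm$data + s$pv_csf$data
  head <- s$volume$mask
  expect_true(all(abs(pvsum[head] - 1) < 1e-9))
  expect_true(all(pvsum[!head] == 0))
})

test_that("noise-free intensity equals the PV mixture exactly", {
  cfg <- small_cfg(seed = 9)
  s <- generate_subject(cfg, "nf")
  expected <- s$pv_wm$data * cfg$wm_mean + s$pv_gm$data * cfg$gm_mean +
    s$pv_csf$data * cfg$csf_mean
  head <- s$volume$mask
  expect_equal(s$volume$data[head], expected[head], tolerance = 1e-12)
})

test_that("null lesion produces a lesion-free control", {
  null_les <- small_lesion(thickening_factor = 1, junction_blur_sigma_mm = 0,
                           wm_intensity_shift = 0)
  s <- generate_subject(small_cfg(seed = 7, lesion = null_les), "nl")
  ref <- small_control()
  expect_false(s$is_patient)
  expect_null(s$lesion_mask)
  expect_equal(s$volume$data, ref$volume$data, tolerance = 1e-12)
})

test_that("a lesion clipped by the grid boundary is rejected", {
  les <- lesion_spec(center = c(46, 24, 24), radius_mm = 6)
  expect_error(generate_subject(small_cfg(seed = 7, lesion = les)), "clipped")
})

test_that("cohorts have the requested composition, shared grid, and are reproducible", {
  expect_identical(generate_cohort(0, 0), list())
  base <- small_cfg(seed = 1)
  coh <- generate_cohort(3, 2, base_cfg = base, seed = 11,
                         base_lesion = small_lesion())
  expect_length(coh, 5)
  n_lesion <- sum(vapply(coh, function(s) !is.null(s$lesion_mask), logical(1)))
  expect_identical(n_lesion, 2L)
  expect_identical(vapply(coh, `[[`, logical(1), "is_patient"),
                   rep(c(FALSE, TRUE), c(3, 2)))
  for (s in coh) expect_identical(dim(s$volume$data), dim(coh[[1]]$volume$data))
  coh2 <- generate_cohort(3, 2, base_cfg = base, seed = 11,
                          base_lesion = small_lesion())
  expect_identical(coh[[5]]$volume$data, coh2[[5]]$volume$data)
  expect_identical(coh[[5]]$lesion_mask$data, coh2[[5]]$lesion_mask$data)
})

test_that("thickening doubles mean in-lesion GM thickness against the analytic shell", {
  cfg <- small_cfg(seed = 7,
                   lesion = small_lesion(thickening_factor = 2,
                                         junction_blur_sigma_mm = 0,
                                         wm_intensity_shift = 0))
  s <- generate_subject(cfg, "thick")
  f <- compute_features(s)
  gm <- f$F1$data > 0
  lm <- s$lesion_mask$data != 0
  h <- mean(cfg$spacing)  # one-voxel bias of the paired distance transforms
  t_in <- mean(f$F1$data[lm & gm])
  t_out <- mean(f$F1$data[!lm & gm])
  expect_lt(abs(t_in - (2 * cfg$ribbon_thickness_mm + h)) /
              (2 * cfg$ribbon_thickness_mm + h), 0.15)
  expect_lt(abs(t_out - (cfg$ribbon_thickness_mm + h)) /
              (cfg$ribbon_thickness_mm + h), 0.15)
})

test_that("lesion signatures respond monotonically to their dials", {
  mk <- function(tf = 1, blur = 0, shift = 0, seed = 7) {
    les <- small_lesion(thickening_factor = tf, junction_blur_sigma_mm = blur,
                        wm_intensity_shift = shift)
    generate_subject(small_cfg(seed = seed, lesion = les), "m")
  }
  # union mask so means are compared on a common footprint
  strongest <- mk(tf = 1.8, blur = 2, shift = 30)
  lm <- strongest$lesion_mask$data != 0

  thick_means <- vapply(c(1.2, 1.5, 1.8), function(tf) {
    s <- mk(tf = tf)
    f <- compute_features(s)
    mean(f$F1$data[lm & f$F1$data > 0])
  }, numeric(1))
  expect_true(all(diff(thick_means) > 0))

  grad_means <- vapply(c(0, 1, 2), function(b) {
    s <- mk(blur = b)
    f <- compute_features(s)
    zone <- f$F4$data > 0
    mean(f$F2$data[lm & zone])
  }, numeric(1))
  expect_true(all(diff(grad_means) < 0))

  width_means <- vapply(c(0, 1, 2), function(b) {
    s <- mk(blur = b)
    f <- compute_features(s)
    mean(f$F4$data[lm & f$F4$data > 0])
  }, numeric(1))
  expect_true(all(diff(width_means) >= 0))

  ri_means <- vapply(c(0, 15, 30), function(sh) {
    s <- mk(shift = sh)
    f <- compute_features(s)
    wm <- s$pv_wm$data >= 0.5
    mean(f$F3$data[lm & wm])
  }, numeric(1))
  expect_true(all(diff(ri_means) > 0))
})
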