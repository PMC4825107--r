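test_that("GM thickness on an analytic slab matches the slab width", {
  s <- slab_subject(gm_vox = 5L)
  f1 <- gm_thickness_map(s$pv_gm, s$pv_wm)
  gm <- s$pv_gm$data >= 0.5
  mid <- f1$data[12, 6, 6]  # slab interior
  expect_true(gm[12, 6, 6])
  expect_lte(abs(mid - 5), 1)  # within one voxel of the 5 mm slab
  expect_true(all(f1$data[!gm] == 0))
  expect_true(all(f1$data >= 0))
  # slab thickness is constant across the slab interior
  vals <- f1$data[10:14, 4:9, 4:9]
  expect_lt(max(vals) - min(vals), 1e-9)
})

test_that("an isolated GM voxel is at most two voxels thick; empty GM errors", {
  d <- c(9, 9, 9)
  pvg <- array(0, d); pvw <- array(0, d)
  pvw[1:4, , ] <- 1
  pvg[5, 5, 5] <- 1
  f1 <- gm_thickness_map(fcd_volume(pvg), fcd_volume(pvw))
  expect_lte(f1$data[5, 5, 5], 2)
  expect_error(gm_thickness_map(fcd_volume(array(0, d)), fcd_volume(pvw)),
               "empty GM mask")
})

test_that("gradient map: zero on constants, exact on ramps, reduced by junction blur", {
  cv <- fcd_volume(array(42, c(6, 6, 6)))
  expect_true(all(gradient_map(cv)$data == 0))
  d <- c(10, 6, 6)
  ramp <- fcd_volume(array(rep(3 * seq_len(d[1]), d[2] * d[3]), d))
  g <- gradient_map(ramp)
  expect_equal(g$data[2:9, 3, 3], rep(3, 8), tolerance = 1e-12)
  # a smoothed step has a lower peak slope than a sharp one (1-D conv oracle)
  step <- c(rep(0, 10), rep(100, 10))
  k <- dnorm(-3:3); k <- k / sum(k)
  smooth <- stats::filter(c(rep(0, 3), step, rep(100, 3)), k, sides = 2)
  smooth <- smooth[4:23]
  vol_sharp <- fcd_volume(array(rep(step, 36), c(20, 6, 6)))
  vol_smooth <- fcd_volume(array(rep(smooth, 36), c(20, 6, 6)))
  expect_lt(max(gradient_map(vol_smooth)$data),
            max(gradient_map(vol_sharp)$data))
})

test_that("relative intensity peaks at the boundary intensity and clips", {
  d <- c(4, 4, 4)
  bg <- 135
  v <- fcd_volume(array(c(bg, 0, 2 * bg, rep(bg / 2, 61)), d),
                  mask = array(TRUE, d))
  f3 <- relative_intensity_map(v, boundary_intensity = bg)
  expect_equal(f3$data[1, 1, 1], 1)
  expect_equal(f3$data[2, 1, 1], 0)
  expect_equal(f3$data[3, 1, 1], 0)  # 2*Bg clips to 0
  expect_equal(f3$data[4, 1, 1], 0.5)
  expect_error(relative_intensity_map(v, boundary_intensity = -1), "positive")
})

test_that("GWB width: empty on hard steps, ramp width recovered, blur widens", {
  hard <- slab_subject(gm_vox = 5L, ramp_vox = 0L)
  expect_warning(f4 <- gwb_width_map(hard$pv_gm, hard$pv_wm), "empty")
  expect_true(all(f4$data == 0))
  soft <- slab_subject(gm_vox = 5L, ramp_vox = 4L)
  f4s <- gwb_width_map(soft$pv_gm, soft$pv_wm)
  expect_lte(abs(max(f4s$data) - 4), 1)  # 4-voxel ramp at 1 mm
  expect_true(all(f4s$data[soft$pv_wm$data %in% c(0, 1)] == 0))
})

test_that("normative mean equals the brute-force windowed average", {
  d <- c(6, 5, 4)
  maps <- list(with_test_seed(1, array(runif(prod(d)), d)),
               with_test_seed(2, array(runif(prod(d)), d)))
  mkfeat <- function(m) {
    f <- list(F1 = fcd_volume(m), F2 = fcd_volume(m), F3 = fcd_volume(m),
              F4 = fcd_volume(m), domain_mask = array(TRUE, d), id = "x",
              spacing = c(1, 1, 1))
    class(f) <- "fcd_features"
    f
  }
  nm <- fit_normative(lapply(maps, mkfeat), window_edge = 3L)
  expect_equal(nm$F_mu$F1$data, bf_normative(maps, 3L), tolerance = 1e-12)
  # window_edge = 1, K = 1 is the identity
  nm1 <- fit_normative(list(mkfeat(maps[[1]])), window_edge = 1L)
  expect_equal(nm1$F_mu$F2$data, maps[[1]], tolerance = 1e-15)
  # linearity: model(a*maps + b) = a*model(maps) + b
  a <- 2.5; b <- -1.25
  nm_lin <- fit_normative(lapply(maps, function(m) mkfeat(a * m + b)), 3L)
  expect_equal(nm_lin$F_mu$F1$data, a * nm$F_mu$F1$data + b, tolerance = 1e-10)
  # constant controls give a constant model
  nmc <- fit_normative(list(mkfeat(array(7, d)), mkfeat(array(7, d))), 3L)
  expect_true(all(abs(nmc$F_mu$F4$data - 7) < 1e-12))
})

test_that("feature difference is exact voxelwise subtraction", {
  d <- c(5, 5, 5)
  a <- with_test_seed(3, array(rnorm(125), d))
  b <- with_test_seed(4, array(rnorm(125), d))
  fd <- feature_difference(fcd_volume(a), fcd_volume(b))
  oracle <- array(0, d)
  for (i in seq_along(a)) oracle[i] <- a[i] - b[i]
  expect_equal(fd$data, oracle, tolerance = 1e-15)
  expect_true(all(feature_difference(fcd_volume(a), fcd_volume(a))$data == 0))
  expect_error(feature_difference(fcd_volume(a), fcd_volume(array(0, c(4, 5, 5)))),
               "mismatch")
})

test_that("feature groups have the documented membership and matrix columns", {
  expect_identical(feature_groups$FG1, c("F1", "F2", "F3"))
  expect_identical(feature_groups$FG2, c("F1", "F2", "F3", "F4"))
  expect_identical(feature_groups$FG3, c("F1", "F3", "F4"))
  expect_identical(feature_groups$FG4, c("Fd1", "Fd2", "Fd3"))
  expect_identical(feature_groups$FG5, c("Fd1", "Fd2", "Fd3", "Fd4"))
  expect_identical(feature_groups$FG6, c("Fd1", "Fd3", "Fd4"))

  s <- slab_subject(gm_vox = 5L, ramp_vox = 2L)
  f <- compute_features(s)
  nm <- fit_normative(list(f), window_edge = 3L)
  for (g in names(feature_groups)) {
    fm <- assemble_feature_matrix(f, nm, group = g)
    expect_identical(colnames(fm$x), feature_groups[[g]])
    expect_identical(nrow(fm$x), length(fm$voxels))
  }
  # empty mask gives zero rows; voxel order is deterministic grid order
  fm0 <- assemble_feature_matrix(f, nm, "FG1",
                                 mask = array(FALSE, dim(f$F1$data)))
  expect_identical(nrow(fm0$x), 0L)
  fm1 <- assemble_feature_matrix(f, nm, "FG1")
  expect_identical(fm1$voxels, sort(fm1$voxels))
  # a subject identical to the normative mean has an all-zero Fd matrix
  # (window_edge 1, single control: F_mu == F)
  nm1 <- fit_normative(list(f), window_edge = 1L)
  fm4 <- assemble_feature_matrix(f, nm1, "FG4")
  expect_true(all(abs(fm4$x) < 1e-12))
  # Fd groups demand a normative model
  expect_error(assemble_feature_matrix(f, NULL, "FG6"), "normative")
})

test_that("group selection averages classifier F-scores and breaks ties low", {
  expect_identical(as.character(select_best_group(
    list(FG1 = c(0.1, 0.1), FG2 = c(0.3, 0.1)))), "FG2")
  expect_identical(as.character(select_best_group(
    list(FG1 = c(0.2, 0.2), FG2 = c(0.2, 0.2), FG3 = c(0.2, 0.2)))), "FG1")
  expect_error(select_best_group(list()), "no group scores")
  expect_error(select_best_group(list(FG1 = c(0.1, 0.2), FG2 = 0.3)),
               "same non-empty")
  # the published selection: averaged F-scores across the four classifiers,
  # FG6 ahead of FG1-5, reproduces FG6 as the working group
  scores <- list(FG1 = c(0.040, 0.041, 0.041, 0.0404),
                 FG2 = c(0.050, 0.052, 0.048, 0.050),
                 FG3 = c(0.052, 0.052, 0.052, 0.052),
                 FG4 = c(0.060, 0.062, 0.058, 0.060),
                 FG5 = c(0.069, 0.0689, 0.0689, 0.0688),
                 FG6 = c(0.0713, 0.0713, 0.0713, 0.0713))
  best <- select_best_group(scores)
  expect_identical(as.character(best), "FG6")
  expect_equal(unname(attr(best, "A_E")["FG6"]), 0.0713, tolerance = 1e-12)
})
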