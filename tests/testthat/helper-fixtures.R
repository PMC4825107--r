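# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A flat-slab subject: WM half-space (x low), GM slab of `gm_vox` voxels, CSF
# half-space (x high); analytic PV maps are binary. Useful wherever feature
# operators have closed-form expectations.
slab_subject <- function(gm_vox = 5L, dims = c(24L, 12L, 12L),
                         spacing = c(1, 1, 1), wm = 160, gm = 110, csf = 30,
                         ramp_vox = 0L, id = "slab") {
  wm_end <- (dims[1] - gm_vox - ramp_vox) %/% 2L
  pvw <- array(0, dims); pvg <- array(0, dims); pvc <- array(0, dims)
  for (x in seq_len(dims[1])) {
    if (x <= wm_end) pvw[x, , ] <- 1
    else if (ramp_vox > 0 && x <= wm_end + ramp_vox) {
      fr <- (x - wm_end) / (ramp_vox + 1)
      pvw[x, , ] <- 1 - fr; pvg[x, , ] <- fr
    } else if (x <= wm_end + ramp_vox + gm_vox) pvg[x, , ] <- 1
    else pvc[x, , ] <- 1
  }
  head <- array(TRUE, dims)
  inten <- pvw * wm + pvg * gm + pvc * csf
  vol <- function(a, units = "raw") fcd_volume(a, spacing, mask = head, units = units)
  fcd_subject(id, vol(inten, "standardized"), pv_gm = vol(pvg),
              pv_wm = vol(pvw), pv_csf = vol(pvc))
}

# Small lesioned / control phantoms for feature and phantom property tests.
small_cfg <- function(seed = 7, lesion = NULL, ...) {
  phantom_config(grid_shape = c(48, 48, 48), ribbon_thickness_mm = 4,
                 inner_radius_mm = 11, noise_sd = 0, seed = seed,
                 lesion = lesion, ...)
}

small_lesion <- function(...) lesion_spec(radius_mm = 6, ...)

small_patient <- function() cached("small_patient",
  generate_subject(small_cfg(seed = 7, lesion = small_lesion()), "pat"))

small_control <- function() cached("small_control",
  generate_subject(small_cfg(seed = 7), "ctl"))

# Random binary volume with given positive fraction.
random_labels <- function(dims, p = 0.1, seed = 1) {
  with_test_seed(seed, array(as.integer(runif(prod(dims)) < p), dim = dims))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Random two-class Gaussian training data for classifier tests.
gaussian_classes <- function(n1, n2, mu1, mu2, S1, S2, seed = 1) {
  d <- length(mu1)
  with_test_seed(seed, {
    A1 <- chol(S1); A2 <- chol(S2)
    X1 <- matrix(rnorm(n1 * d), n1) %*% A1 + rep(mu1, each = n1)
    X2 <- matrix(rnorm(n2 * d), n2) %*% A2 + rep(mu2, each = n2)
    list(X = rbind(X1, X2), y = rep(c(1L, 0L), c(n1, n2)))
  })
}

# Fit all four classifier kinds on one training set.
fit_all_kinds <- function(X, y, ...) {
  models <- lapply(c("NB", "LDA", "QDA", "MDA"), function(k)
    gda_fit(X, y, kind = k, ...))
  names(models) <- c("NB", "LDA", "QDA", "MDA")
  models
}
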