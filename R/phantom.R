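#' Phantom configuration
#'
#' Describes one synthetic brain-like volume: a perturbed spherical-shell
#' cortical ribbon (inner white-matter ball, gray-matter shell, outer CSF
#' layer) on a regular grid, with optional FCD-like lesion. Intensities are on
#' the 0--255 scale with T1 contrast ordering `wm_mean > gm_mean > csf_mean`.
#' The shell radius is modulated by a low-order spherical-harmonic "gyral"
#' pattern (degrees 2--4); in a cohort the pattern is shared across subjects
#' (they are pre-aligned) with a small per-subject residual.
#'
#' @param grid_shape voxels per axis.
#' @param spacing voxel size in mm per axis.
#' @param wm_mean,gm_mean,csf_mean,background tissue intensity levels.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param ribbon_thickness_mm baseline cortical (GM shell) thickness.
#' @param inner_radius_mm nominal WM ball radius; default scales with grid.
#' @param csf_thickness_mm thickness of the CSF layer outside the ribbon.
#' @param gyral_amplitude peak relative radial modulation (fraction of the
#'   inner radius, <= 0.2).
#' @param lesion optional [lesion_spec()].
#' @param seed RNG seed (controls noise and, if not supplied, the gyral
#'   pattern).
#' @param gyral_coeffs optional precomputed spherical-harmonic coefficient
#'   table (internal; used by [generate_cohort()] to share anatomy).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                           wm_mean = 160, gm_mean = 110, csf_mean = 30,
                           background = 0, noise_sd = 4,
                           ribbon_thickness_mm = 6, inner_radius_mm = NULL,
                           csf_thickness_mm = 3, gyral_amplitude = 0.08,
                           lesion = NULL, seed = 1L, gyral_coeffs = NULL) {
  if (!(wm_mean > gm_mean && gm_mean > csf_mean && csf_mean >= 0))
    stop("need T1 contrast ordering wm_mean > gm_mean > csf_mean >= 0")
  if (ribbon_thickness_mm <= 0 || noise_sd < 0)
    stop("ribbon_thickness_mm must be > 0 and noise_sd >= 0")
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (is.null(inner_radius_mm))
    inner_radius_mm <- 0.25 * min(grid_shape * spacing)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 wm_mean = wm_mean, gm_mean = gm_mean, csf_mean = csf_mean,
                 background = background, noise_sd = noise_sd,
                 ribbon_thickness_mm = ribbon_thickness_mm,
                 inner_radius_mm = inner_radius_mm,
                 csf_thickness_mm = csf_thickness_mm,
                 gyral_amplitude = gyral_amplitude,
                 lesion = lesion, seed = as.integer(seed),
                 gyral_coeffs = gyral_coeffs),
            class = "phantom_config")
}

#' Lesion specification for the phantom
#'
#' The three radiological FCD signatures, each dialled independently:
#' cortical thickening (shell thickness multiplied by `thickening_factor`
#' inside the patch), GM/WM junction blurring (tissue partial volumes locally
#' smoothed with a Gaussian of width `junction_blur_sigma_mm`), and the
#' subjacent-WM signal change of magnitude `wm_intensity_shift` (on T1 the
#' lesional WM signal moves toward the gray/white boundary intensity, i.e.
#' toward GM). The patch is the ball of radius `radius_mm` around `center`
#' (voxel coordinates; `NULL` places it mid-ribbon along +x).
#'
#' @param center lesion centre in voxel coordinates (length 3) or `NULL`.
#' @param radius_mm patch radius in mm.
#' @param thickening_factor multiplier (>= 1) on ribbon thickness.
#' @param junction_blur_sigma_mm Gaussian blur width at the junction (>= 0).
#' @param wm_intensity_shift magnitude (>= 0) of the GM-ward intensity shift
#'   of in-patch WM.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center = NULL, radius_mm = 8, thickening_factor = 2,
                        junction_blur_sigma_mm = 2, wm_intensity_shift = 30) {
  if (thickening_factor < 1) stop("thickening_factor must be >= 1")
  if (junction_blur_sigma_mm < 0 || wm_intensity_shift < 0)
    stop("blur and intensity shift must be >= 0")
  structure(list(center = center, radius_mm = radius_mm,
                 thickening_factor = thickening_factor,
                 junction_blur_sigma_mm = junction_blur_sigma_mm,
                 wm_intensity_shift = wm_intensity_shift),
            class = "lesion_spec")
}

# Random real-spherical-harmonic coefficient table, degrees 2..4, scaled so
# the peak radial modulation equals `amplitude` (checked on sampled
# directions). Columns: l, m, amp, phase.
sample_gyral_coeffs <- function(amplitude, seed) {
  lm <- rbind(c(2, 0), c(2, 2), c(3, 1), c(3, 3), c(4, 2), c(4, 4))
  with_seed(seed, {
    tab <- data.frame(l = lm[, 1], m = lm[, 2],
                      amp = rnorm(nrow(lm)), phase = runif(nrow(lm), 0, 2 * pi))
    u <- matrix(rnorm(3 * 2000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- eval_gyral(tab, u[, 1], u[, 2], u[, 3])
    peak <- max(abs(p))
    if (peak > 0) tab$amp <- tab$amp * (amplitude / peak)
    tab
  })
}

# Evaluate the radial modulation sum_j amp_j P_l^m(cos theta) cos(m phi +
# phase_j) at unit directions (ux, uy, uz).
eval_gyral <- function(coeffs, ux, uy, uz) {
  if (is.null(coeffs) || nrow(coeffs) == 0) return(rep(0, length(ux)))
  ct <- pmin(pmax(uz, -1), 1)
  phi <- atan2(uy, ux)
  out <- rep(0, length(ux))
  for (l in unique(coeffs$l)) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, rows m = 0..l
    rows <- coeffs[coeffs$l == l, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      m <- rows$m[j]
      out <- out + rows$amp[j] * P[m + 1L, ] * cos(m * phi + rows$phase[j])
    }
  }
  out
}

# Tissue classification of arbitrary points (mm offsets from grid centre).
# Codes: 0 background, 1 CSF, 2 GM, 3 WM. `geom` bundles the resolved
# geometry including any lesion. With `boundary_margin` > 0 also reports
# which points lie within that distance of a radial tissue interface.
classify_points <- function(px, py, pz, geom, boundary_margin = 0) {
  r <- sqrt(px^2 + py^2 + pz^2)
  r_safe <- pmax(r, 1e-9)
  ux <- px / r_safe; uy <- py / r_safe; uz <- pz / r_safe
  r_in <- geom$r0 * (1 + eval_gyral(geom$coeffs, ux, uy, uz))
  thick <- rep(geom$thickness, length(r))
  if (!is.null(geom$lesion_mm)) {
    # thickening acts on the whole ribbon depth: weight by geodesic
    # (tangential) distance from the lesion axis on the mid-shell sphere
    uc <- geom$lesion_mm / sqrt(sum(geom$lesion_mm^2))
    cosang <- pmin(pmax(ux * uc[1] + uy * uc[2] + uz * uc[3], -1), 1)
    s <- acos(cosang) * (geom$r0 + geom$thickness / 2)
    # plateau with a smooth rim: full thickening out to 90% of the patch
    # radius, quadratic rolloff to 0 at the border; keeps the nominal
    # thickening factor equal to the realized mean thickening of the patch
    w <- pmin(pmax((1 - (s / geom$lesion_radius)^2) / 0.19, 0), 1)
    thick <- thick * (1 + (geom$thickening - 1) * w)
  }
  r_out <- r_in + thick
  code <- integer(length(r))
  code[r < r_in] <- 3L
  code[r >= r_in & r < r_out] <- 2L
  code[r >= r_out & r < geom$r_csf] <- 1L
  if (boundary_margin > 0) {
    near <- abs(r - r_in) < boundary_margin | abs(r - r_out) < boundary_margin |
      abs(r - geom$r_csf) < boundary_margin
    return(list(code = code, near_boundary = near))
  }
  list(code = code)
}

# Analytic PV maps by 3x3x3 subvoxel sampling. Voxels farther than one voxel
# diagonal from every tissue interface are pure and keep their centre
# classification; only interface-adjacent voxels are subsampled.
phantom_pv <- function(cfg, geom) {
  d <- cfg$grid_shape; sp <- cfg$spacing
  ctr <- (d + 1) / 2
  cx <- (seq_len(d[1]) - ctr[1]) * sp[1]
  cy <- (seq_len(d[2]) - ctr[2]) * sp[2]
  cz <- (seq_len(d[3]) - ctr[3]) * sp[3]
  gx <- rep(cx, times = d[2] * d[3])
  gy <- rep(rep(cy, each = d[1]), times = d[3])
  gz <- rep(cz, each = d[1] * d[2])
  cl <- classify_points(gx, gy, gz, geom, boundary_margin = sqrt(sum(sp^2)))
  acc <- list(wm = (cl$code == 3L) * 27, gm = (cl$code == 2L) * 27,
              csf = (cl$code == 1L) * 27)
  # the head/background boundary is voxel-sharp (decided at voxel centres):
  # only WM/GM/CSF interfaces get partial volumes, so PV maps sum to exactly
  # 1 inside the head and 0 outside
  head <- cl$code > 0L
  geom$r_csf <- Inf
  nb <- which(cl$near_boundary & head)
  if (length(nb)) {
    acc$wm[nb] <- 0; acc$gm[nb] <- 0; acc$csf[nb] <- 0
    offs <- c(-1, 0, 1) / 3
    bx <- gx[nb]; by <- gy[nb]; bz <- gz[nb]
    for (ox in offs) for (oy in offs) for (oz in offs) {
      code <- classify_points(bx + ox * sp[1], by + oy * sp[2],
                              bz + oz * sp[3], geom)$code
      acc$wm[nb] <- acc$wm[nb] + (code == 3L)
      acc$gm[nb] <- acc$gm[nb] + (code == 2L)
      acc$csf[nb] <- acc$csf[nb] + (code == 1L)
    }
  }
  lapply(acc, function(a) array(a / 27, dim = d))
}

resolve_geom <- function(cfg) {
  geom <- list(r0 = cfg$inner_radius_mm, thickness = cfg$ribbon_thickness_mm,
               r_csf = cfg$inner_radius_mm * (1 + cfg$gyral_amplitude) +
                 cfg$ribbon_thickness_mm *
                   max(1, if (is.null(cfg$lesion)) 1 else cfg$lesion$thickening_factor) +
                 cfg$csf_thickness_mm,
               coeffs = cfg$gyral_coeffs, lesion_mm = NULL,
               lesion_radius = NULL, thickening = 1)
  if (is.null(geom$coeffs))
    geom$coeffs <- sample_gyral_coeffs(cfg$gyral_amplitude,
                                       child_seed(cfg$seed, 1L))
  if (!is.null(cfg$lesion)) {
    les <- cfg$lesion
    ctr_vox <- les$center
    if (is.null(ctr_vox)) {
      # mid-ribbon along +x, on the actual (perturbed) shell
      rin <- geom$r0 * (1 + eval_gyral(geom$coeffs, 1, 0, 0))
      ctr <- (cfg$grid_shape + 1) / 2
      ctr_vox <- c(ctr[1] + (rin + cfg$ribbon_thickness_mm / 2) / cfg$spacing[1],
                   ctr[2], ctr[3])
    }
    geom$lesion_mm <- (ctr_vox - (cfg$grid_shape + 1) / 2) * cfg$spacing
    geom$lesion_radius <- les$radius_mm
    geom$thickening <- les$thickening_factor
    geom$lesion_center_vox <- ctr_vox
  }
  geom
}

#' Generate one phantom subject
#'
#' Builds the perturbed-shell phantom described by `cfg`: analytic PV maps by
#' 3x3x3 subvoxel sampling, noise-free intensity `pv_wm*wm_mean +
#' pv_gm*gm_mean + pv_csf*csf_mean` (plus the lesional WM shift), then
#' additive Gaussian noise inside the head. If a lesion is present the shell
#' is locally thickened, the junction PV locally blurred, and in-patch WM
#' intensity shifted toward GM; the ground-truth lesion mask is the set of
#' voxels whose PV vector changed by more than 0.01 against the unlesioned
#' phantom, plus the WM voxels receiving the intensity shift. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @param id subject identifier.
#' @return An [fcd_subject] with volume, PV maps, head mask, and (for
#'   patients) lesion mask.
#' @export
generate_subject <- function(cfg, id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  geom <- resolve_geom(cfg)
  d <- cfg$grid_shape; sp <- cfg$spacing

  lesioned <- !is.null(cfg$lesion)
  if (lesioned) {
    ctr_vox <- geom$lesion_center_vox
    rad_vox <- cfg$lesion$radius_mm / sp
    if (any(ctr_vox - rad_vox < 1) || any(ctr_vox + rad_vox > d))
      stop("lesion patch clipped by grid boundary")
  }

  geom_null <- geom
  geom_null$lesion_mm <- NULL; geom_null$thickening <- 1
  pv0 <- phantom_pv(cfg, geom_null)
  pv <- if (lesioned) phantom_pv(cfg, geom) else pv0

  shifted_wm <- array(FALSE, dim = d)
  patch_w <- NULL
  if (lesioned) {
    les <- cfg$lesion
    # voxel-centre distance to lesion centre, in mm
    ctr <- (d + 1) / 2
    ax <- (seq_len(d[1]) - ctr[1]) * sp[1] - geom$lesion_mm[1]
    ay <- (seq_len(d[2]) - ctr[2]) * sp[2] - geom$lesion_mm[2]
    az <- (seq_len(d[3]) - ctr[3]) * sp[3] - geom$lesion_mm[3]
    d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
    patch_w <- pmax(0, 1 - d2 / les$radius_mm^2)
    if (les$junction_blur_sigma_mm > 0) {
      ks <- lapply(1:3, function(a) gauss_kernel(les$junction_blur_sigma_mm / sp[a]))
      pvb <- lapply(pv, separable_conv3d, kernels = ks)
      pv <- lapply(names(pv), function(nm)
        (1 - patch_w) * pv[[nm]] + patch_w * pvb[[nm]])
      names(pv) <- c("wm", "gm", "csf")
    }
    shifted_wm <- pv$wm >= 0.5 & patch_w > 0 & les$wm_intensity_shift > 0
  }

  head <- (pv$wm + pv$gm + pv$csf) > 0
  intensity <- pv$wm * cfg$wm_mean + pv$gm * cfg$gm_mean + pv$csf * cfg$csf_mean
  if (lesioned && cfg$lesion$wm_intensity_shift > 0) {
    # T1 signature of lesional WM: signal moves toward the GM/WM boundary
    intensity[shifted_wm] <- intensity[shifted_wm] - cfg$lesion$wm_intensity_shift
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(child_seed(cfg$seed, 2L),
                       array(rnorm(prod(d), sd = cfg$noise_sd), dim = d))
    intensity[head] <- intensity[head] + noise[head]
  }
  intensity[head] <- pmin(pmax(intensity[head], 0.5), 255)
  intensity[!head] <- cfg$background

  mkvol <- function(a, units = "raw")
    fcd_volume(array(a, dim = d), sp, mask = head, units = units)

  lesion_mask <- NULL
  if (lesioned) {
    dpv <- pmax(abs(pv$wm - pv0$wm), abs(pv$gm - pv0$gm), abs(pv$csf - pv0$csf))
    lm <- dpv > 0.01 | shifted_wm
    if (any(lm)) lesion_mask <- mkvol(lm * 1)
  }
  fcd_subject(id = id,
              volume = mkvol(intensity, units = "standardized"),
              pv_gm = mkvol(pv$gm), pv_wm = mkvol(pv$wm), pv_csf = mkvol(pv$csf),
              lesion_mask = lesion_mask,
              is_patient = !is.null(lesion_mask))
}

#' Generate an aligned phantom cohort
#'
#' All subjects share the grid, spacing and cohort-level gyral pattern (the
#' cohort is "pre-registered"); per-subject anatomy varies through a small
#' residual gyral pattern, Gaussian jitter of the tissue intensity means, and
#' Gaussian jitter of the ribbon thickness. Patients additionally receive a
#' lesion whose signature strengths are jittered around `base_lesion` and
#' whose location is a random direction on the shell.
#'
#' @param n_controls,n_patients subject counts.
#' @param base_cfg cohort-level [phantom_config()].
#' @param seed cohort RNG seed.
#' @param base_lesion [lesion_spec()] giving mean lesion properties for
#'   patients.
#' @param jitter_intensity_sd SD of per-subject tissue-mean jitter.
#' @param jitter_thickness_sd SD (mm) of per-subject ribbon-thickness jitter.
#' @param residual_amplitude amplitude of the per-subject residual gyral
#'   pattern.
#' @param lesion_jitter relative SD applied to each lesion signature strength.
#' @return list of [fcd_subject]s (controls first).
#' @export
generate_cohort <- function(n_controls, n_patients, base_cfg = phantom_config(),
                            seed = 1L, base_lesion = lesion_spec(),
                            jitter_intensity_sd = 2, jitter_thickness_sd = 0.3,
                            residual_amplitude = 0.015, lesion_jitter = 0.1) {
  stopifnot(n_controls >= 0, n_patients >= 0)
  n <- n_controls + n_patients
  if (n == 0) return(list())
  shared <- sample_gyral_coeffs(base_cfg$gyral_amplitude, child_seed(seed, 100L))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- child_seed(seed, i)
    is_pat <- i > n_controls
    pars <- with_seed(child_seed(si, 3L), {
      resid <- sample_gyral_coeffs(residual_amplitude, child_seed(si, 4L))
      list(wm = base_cfg$wm_mean + rnorm(1, sd = jitter_intensity_sd),
           gm = base_cfg$gm_mean + rnorm(1, sd = jitter_intensity_sd),
           csf = max(0.5, base_cfg$csf_mean + rnorm(1, sd = jitter_intensity_sd)),
           thick = max(1, base_cfg$ribbon_thickness_mm +
                         rnorm(1, sd = jitter_thickness_sd)),
           resid = resid,
           u = { v <- rnorm(3); v / sqrt(sum(v^2)) },
           lj = exp(rnorm(3, sd = lesion_jitter)))
    })
    coeffs <- rbind(shared, pars$resid)
    lesion <- NULL
    if (is_pat) {
      # place the lesion mid-ribbon along the random direction u
      rin <- base_cfg$inner_radius_mm *
        (1 + eval_gyral(coeffs, pars$u[1], pars$u[2], pars$u[3]))
      ctr <- (base_cfg$grid_shape + 1) / 2
      ctr_vox <- ctr + pars$u * (rin + pars$thick / 2) / base_cfg$spacing
      lesion <- lesion_spec(center = ctr_vox,
                            radius_mm = base_lesion$radius_mm,
                            thickening_factor =
                              1 + (base_lesion$thickening_factor - 1) * pars$lj[1],
                            junction_blur_sigma_mm =
                              base_lesion$junction_blur_sigma_mm * pars$lj[2],
                            wm_intensity_shift =
                              base_lesion$wm_intensity_shift * pars$lj[3])
    }
    cfg <- phantom_config(grid_shape = base_cfg$grid_shape,
                          spacing = base_cfg$spacing,
                          wm_mean = pars$wm, gm_mean = pars$gm,
                          csf_mean = pars$csf,
                          background = base_cfg$background,
                          noise_sd = base_cfg$noise_sd,
                          ribbon_thickness_mm = pars$thick,
                          inner_radius_mm = base_cfg$inner_radius_mm,
                          csf_thickness_mm = base_cfg$csf_thickness_mm,
                          gyral_amplitude = base_cfg$gyral_amplitude,
                          lesion = lesion, seed = si, gyral_coeffs = coeffs)
    subjects[[i]] <- generate_subject(
      cfg, id = sprintf("%s%02d", if (is_pat) "patient" else "control",
                        if (is_pat) i - n_controls else i))
  }
  subjects
}
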