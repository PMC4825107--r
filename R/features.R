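#' Gray-matter thickness map (F1)
#'
#' Thickness of the cortical ribbon at each GM voxel, computed by paired
#' Euclidean distance transforms: distance to the nearest non-GM voxel on the
#' WM side plus distance to the nearest non-GM voxel on the CSF side, in mm.
#' The GM mask is `pv_gm >= 0.5`; non-GM voxels with `pv_wm >= 0.5` count as
#' the WM side and all remaining non-GM voxels (CSF and background) as the
#' CSF side. Zero outside the GM mask.
#'
#' @param pv_gm,pv_wm GM / WM partial-volume [fcd_volume]s.
#' @return [fcd_volume] of thickness in mm.
#' @export
gm_thickness_map <- function(pv_gm, pv_wm) {
  stopifnot(inherits(pv_gm, "fcd_volume"), same_grid(pv_gm, pv_wm))
  gm <- pv_gm$data >= 0.5
  if (!any(gm)) stop("empty GM mask")
  wm_side <- !gm & pv_wm$data >= 0.5
  csf_side <- !gm & !wm_side
  if (!any(wm_side) || !any(csf_side))
    stop("GM mask has no WM or no CSF side")
  thick <- distance_to(wm_side, pv_gm$spacing) +
    distance_to(csf_side, pv_gm$spacing)
  thick[!gm] <- 0
  fcd_volume(thick, pv_gm$spacing, mask = pv_gm$mask)
}

#' Intensity gradient magnitude map (F2)
#'
#' Euclidean norm of the central-difference gradient, each axis divided by its
#' voxel spacing (one-sided differences at the grid border). Lesional regions
#' with a blurred gray/white junction have lower gradient values.
#'
#' @param vol intensity [fcd_volume].
#' @return [fcd_volume] of gradient magnitude (intensity/mm).
#' @export
gradient_map <- function(vol) {
  stopifnot(inherits(vol, "fcd_volume"))
  a <- vol$data; d <- dim(a); sp <- vol$spacing
  diff_axis <- function(ax) {
    fwd <- switch(ax, shift_array(a, -1L, 0L, 0L), shift_array(a, 0L, -1L, 0L),
                  shift_array(a, 0L, 0L, -1L))
    bwd <- switch(ax, shift_array(a, 1L, 0L, 0L), shift_array(a, 0L, 1L, 0L),
                  shift_array(a, 0L, 0L, 1L))
    g <- (fwd - bwd) / (2 * sp[ax])
    # one-sided at the two boundary slices
    idx_lo <- slice.index(a, ax) == 1L
    idx_hi <- slice.index(a, ax) == d[ax]
    g[idx_lo] <- ((fwd - a) / sp[ax])[idx_lo]
    g[idx_hi] <- ((a - bwd) / sp[ax])[idx_hi]
    g
  }
  g <- sqrt(diff_axis(1)^2 + diff_axis(2)^2 + diff_axis(3)^2)
  fcd_volume(g, sp, mask = vol$mask)
}

#' Relative intensity map (F3)
#'
#' `F3(v) = max(0, 1 - |Bg - I(v)| / Bg)`, clipped to [0,1], where `Bg` is the
#' gray/white boundary intensity — by default the midpoint of the GM and WM
#' histogram peaks located by the package's peak detector. Voxels whose
#' intensity sits at the boundary intensity score 1; blurred junctions and
#' GM-like lesional WM therefore score high.
#'
#' @param vol standardized intensity [fcd_volume].
#' @param boundary_intensity `Bg`; `NULL` means the GM/WM peak midpoint.
#' @return [fcd_volume] with values in [0,1].
#' @export
relative_intensity_map <- function(vol, boundary_intensity = NULL) {
  stopifnot(inherits(vol, "fcd_volume"))
  bg <- boundary_intensity %||% mean(find_intensity_peaks(vol)$peak_intensities)
  if (bg <= 0) stop("boundary intensity must be positive")
  f <- 1 - abs(bg - vol$data) / bg
  f[f < 0] <- 0
  f[f > 1] <- 1
  f[!vol_mask(vol)] <- 0
  out <- fcd_volume(f, vol$spacing, mask = vol$mask)
  attr(out, "boundary_intensity") <- bg
  out
}

#' Gray/white boundary width map (F4)
#'
#' Width of the gray/white transition zone. The zone is the set of voxels with
#' `0.1 < pv_wm < 0.9` and `pv_gm > 0`; for a zone voxel the width is twice
#' the distance to the nearest non-zone voxel plus one voxel (mean spacing),
#' in mm, and 0 outside the zone. A blurred junction produces a wider zone
#' and larger values.
#'
#' @param pv_gm,pv_wm partial-volume [fcd_volume]s.
#' @param lo,hi PV thresholds bounding the transition zone.
#' @return [fcd_volume] of zone width in mm.
#' @export
gwb_width_map <- function(pv_gm, pv_wm, lo = 0.1, hi = 0.9) {
  stopifnot(inherits(pv_gm, "fcd_volume"), same_grid(pv_gm, pv_wm))
  zone <- pv_wm$data > lo & pv_wm$data < hi & pv_gm$data > 0
  sp <- pv_gm$spacing
  if (!any(zone)) {
    warning("empty gray/white transition zone")
    return(fcd_volume(array(0, dim(pv_gm$data)), sp, mask = pv_gm$mask))
  }
  w <- 2 * distance_to(!zone, sp) + mean(sp)
  w[!zone] <- 0
  fcd_volume(w, sp, mask = pv_gm$mask)
}

#' Compute the four feature maps for one subject
#'
#' Also derives the classification domain mask: voxels with `pv_gm > 0` or in
#' the gray/white transition zone. FCD features are cortical/juxta-cortical;
#' voxels outside the domain are never classified (they are negative by
#' construction).
#'
#' @param subject an [fcd_subject] with PV maps.
#' @param boundary_intensity optional `Bg` override for F3.
#' @return An object of class `fcd_features`: list with volumes `F1`..`F4`
#'   and logical array `domain_mask`.
#' @export
compute_features <- function(subject, boundary_intensity = NULL) {
  stopifnot(inherits(subject, "fcd_subject"))
  if (is.null(subject$pv_gm) || is.null(subject$pv_wm))
    stop("subject ", subject$id, " lacks the PV maps needed for features")
  F1 <- gm_thickness_map(subject$pv_gm, subject$pv_wm)
  F2 <- gradient_map(subject$volume)
  F3 <- relative_intensity_map(subject$volume, boundary_intensity)
  F4 <- gwb_width_map(subject$pv_gm, subject$pv_wm)
  zone <- F4$data > 0
  domain <- subject$pv_gm$data > 0 | zone
  structure(list(F1 = F1, F2 = F2, F3 = F3, F4 = F4, domain_mask = domain,
                 id = subject$id, spacing = subject$volume$spacing),
            class = "fcd_features")
}

#' @export
print.fcd_features <- function(x, ...) {
  cat(sprintf("<fcd_features> subject %s, domain %d voxels\n", x$id,
              sum(x$domain_mask)))
  for (nm in c("F1", "F2", "F3", "F4"))
    cat(sprintf("  %s range [%.3g, %.3g]\n", nm, min(x[[nm]]$data),
                max(x[[nm]]$data)))
  invisible(x)
}

#' Normative mean model of healthy controls
#'
#' For each feature, the local average over a cubic `window_edge`^3
#' neighbourhood, averaged over the K control subjects:
#' `F_mu(v) = (1/(K N)) sum_k sum_n F^(k)(v_n)`. Windows truncated by the
#' grid border are renormalized by their actual size.
#'
#' @param control_features list of `fcd_features` (one per healthy control).
#' @param window_edge odd window edge length in voxels (`N = window_edge^3`).
#' @param features which maps to model.
#' @return An object of class `puv_normative`: per-feature mean maps plus a
#'   pooled domain mask (union of control domains).
#' @export
fit_normative <- function(control_features, window_edge = 3L,
                          features = c("F1", "F2", "F3", "F4")) {
  stopifnot(length(control_features) >= 1L,
            window_edge >= 1L, window_edge %% 2L == 1L)
  dims <- dim(control_features[[1L]]$F1$data)
  sp <- control_features[[1L]]$spacing
  for (f in control_features)
    if (!identical(dim(f$F1$data), dims)) stop("control feature grid mismatch")
  K <- length(control_features)
  counts <- box_count3d(dims, window_edge)
  F_mu <- lapply(features, function(nm) {
    acc <- array(0, dim = dims)
    for (f in control_features) acc <- acc + box_sum3d(f[[nm]]$data, window_edge)
    fcd_volume(acc / (K * counts), sp)
  })
  names(F_mu) <- features
  domain <- Reduce(`|`, lapply(control_features, `[[`, "domain_mask"))
  structure(list(F_mu = F_mu, window_edge = as.integer(window_edge),
                 N = as.integer(window_edge^3), K = K, domain_mask = domain,
                 spacing = sp),
            class = "puv_normative")
}

#' @export
print.puv_normative <- function(x, ...) {
  cat(sprintf("<puv_normative> %d controls, %d^3-voxel window (N = %d), features: %s\n",
              x$K, x$window_edge, x$N, paste(names(x$F_mu), collapse = ", ")))
  invisible(x)
}

#' Voxelwise feature difference (Fd)
#'
#' `Fd(v) = F(v) - F_mu(v)`: the subject's feature minus the normative local
#' mean; may be negative.
#'
#' @param F_i subject feature [fcd_volume].
#' @param F_mu_i normative mean [fcd_volume] on the same grid.
#' @return [fcd_volume] of differences.
#' @export
feature_difference <- function(F_i, F_mu_i) {
  if (!same_grid(F_i, F_mu_i)) stop("feature/normative grid mismatch")
  fcd_volume(F_i$data - F_mu_i$data, F_i$spacing, mask = F_i$mask)
}

#' Feature groups
#'
#' The six candidate feature groups: FG1--FG3 use the raw maps (thickness,
#' gradient, relative intensity, boundary width), FG4--FG6 the corresponding
#' normative differences. FG6 = \{Fd1, Fd3, Fd4\} is the default working
#' group.
#'
#' @format list mapping `FG1`..`FG6` to ordered member vectors.
#' @export
feature_groups <- list(
  FG1 = c("F1", "F2", "F3"),
  FG2 = c("F1", "F2", "F3", "F4"),
  FG3 = c("F1", "F3", "F4"),
  FG4 = c("Fd1", "Fd2", "Fd3"),
  FG5 = c("Fd1", "Fd2", "Fd3", "Fd4"),
  FG6 = c("Fd1", "Fd3", "Fd4"))

#' Assemble the per-voxel feature matrix for classification
#'
#' Rows are the voxels inside `mask` in deterministic grid order (x fastest,
#' then y, then z); columns follow the feature group's member order. `Fd`
#' members require a fitted normative model.
#'
#' @param features `fcd_features` for the subject.
#' @param normative `puv_normative` or `NULL` (needed for `Fd` members).
#' @param group group id (`"FG1"`..`"FG6"`) or a character vector of members.
#' @param mask logical array of voxels to include; default the subject's
#'   classification domain.
#' @return list with integer vector `voxels` (linear indices into the grid)
#'   and numeric matrix `x` (one row per voxel).
#' @export
assemble_feature_matrix <- function(features, normative = NULL, group = "FG6",
                                    mask = NULL) {
  members <- if (length(group) == 1L && group %in% names(feature_groups))
    feature_groups[[group]] else as.character(group)
  mask <- mask %||% features$domain_mask
  vox <- which(mask)
  cols <- lapply(members, function(m) {
    base <- sub("^Fd", "F", m)
    if (grepl("^Fd", m)) {
      if (is.null(normative)) stop("feature group needs a normative model for ", m)
      feature_difference(features[[base]], normative$F_mu[[base]])$data[vox]
    } else {
      features[[base]]$data[vox]
    }
  })
  x <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(x)) x <- matrix(numeric(0), nrow = 0, ncol = length(members))
  colnames(x) <- members
  list(voxels = vox, x = x)
}

#' Select the best feature group by averaged F-score
#'
#' Each candidate group is scored by the arithmetic mean of its per-classifier
#' F-scores (`A_Ek`); the group with the highest mean wins, ties broken by the
#' smaller group index for determinism.
#'
#' @param per_group_scores named list: group id -> numeric vector of
#'   per-classifier F-scores (same classifier list for every group).
#' @return the winning group id (string), with the mean scores as attribute
#'   `A_E`.
#' @export
select_best_group <- function(per_group_scores) {
  if (length(per_group_scores) == 0L) stop("no group scores supplied")
  lens <- lengths(per_group_scores)
  if (length(unique(lens)) != 1L || any(lens == 0L))
    stop("every group needs the same non-empty classifier score list")
  ord <- names(per_group_scores)[order(match(names(per_group_scores),
                                             names(feature_groups)))]
  a <- vapply(per_group_scores[ord], mean, numeric(1))
  best <- ord[which.max(a)]  # which.max takes the first maximum: lowest index
  structure(best, A_E = a)
}
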