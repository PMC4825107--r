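#' 3D scalar volume with voxel spacing
#'
#' Lightweight container for a 3D scalar grid: the voxel data, per-axis voxel
#' size in millimetres, and an optional head (in-brain) mask. Brain-extracted
#' clinical volumes and phantoms both use intensity 0 for background, so the
#' mask defaults to `data > 0`; the phantom generator supplies it analytically.
#'
#' @param data 3D numeric array (index order x, y, z).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param mask optional logical array of the same shape marking in-brain
#'   voxels; `NULL` means "derive as `data > 0` when needed".
#' @param units intensity units: `"raw"` or `"standardized"` (0--255 scale).
#' @return An object of class `fcd_volume`.
#' @export
fcd_volume <- function(data, spacing = c(1, 1, 1), mask = NULL, units = "raw") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (any(!is.finite(data))) stop("volume data contains NaN/Inf")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(data))
    if (!identical(dim(mask), dim(data))) stop("mask shape mismatch")
  }
  structure(list(data = data, spacing = spacing, mask = mask, units = units),
            class = "fcd_volume")
}

#' @export
print.fcd_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fcd_volume> %d x %d x %d voxels, spacing %s mm, %s intensities\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$units))
  cat(sprintf("  range [%.3g, %.3g]%s\n", min(x$data), max(x$data),
              if (is.null(x$mask)) "" else
                sprintf(", head mask %d voxels", sum(x$mask))))
  invisible(x)
}

#' @export
as.array.fcd_volume <- function(x, ...) x$data

vol_mask <- function(vol) {
  if (!is.null(vol$mask)) vol$mask else vol$data > 0
}

as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "fcd_volume")) x else fcd_volume(x, spacing)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$spacing - b$spacing) < tol)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] returning
#' or accepting [fcd_volume] objects. Voxel spacing is taken from the NIfTI
#' `pixdim`. Masks are stored as uint8 0/1 images.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an [fcd_volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L, drop = TRUE]
  sp <- RNifti::pixdim(img)[1:3]
  fcd_volume(a, spacing = sp)
}

#' @rdname read_volume
#' @param vol an [fcd_volume].
#' @param mask logical; write as uint8 0/1 mask.
#' @export
write_volume <- function(vol, path, mask = FALSE) {
  a <- vol$data
  if (mask) a <- array(as.integer(a != 0), dim = dim(a))
  attr(a, "pixdim") <- vol$spacing
  img <- if (mask) RNifti::asNifti(a, datatype = "uint8") else RNifti::asNifti(a)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Cohort subject
#'
#' Bundles one subject's T1 volume with optional partial-volume (PV) tissue
#' maps, an optional ground-truth lesion mask, and patient/control status.
#' All member volumes must share grid shape and spacing; where all three PV
#' maps are present their voxelwise sum may not exceed 1; a non-empty lesion
#' mask implies patient status.
#'
#' @param id subject identifier (string).
#' @param volume [fcd_volume] with the (standardized or raw) T1 intensities.
#' @param pv_gm,pv_wm,pv_csf optional PV [fcd_volume]s with values in [0,1].
#' @param lesion_mask optional binary [fcd_volume] of ground-truth lesion.
#' @param is_patient logical patient/control flag.
#' @return An object of class `fcd_subject`.
#' @export
fcd_subject <- function(id, volume, pv_gm = NULL, pv_wm = NULL, pv_csf = NULL,
                        lesion_mask = NULL, is_patient = FALSE) {
  stopifnot(inherits(volume, "fcd_volume"))
  vols <- Filter(Negate(is.null),
                 list(pv_gm = pv_gm, pv_wm = pv_wm, pv_csf = pv_csf,
                      lesion_mask = lesion_mask))
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!inherits(v, "fcd_volume")) stop(nm, " must be an fcd_volume")
    if (!same_grid(volume, v)) stop(nm, ": grid/spacing mismatch for subject ", id)
  }
  for (nm in c("pv_gm", "pv_wm", "pv_csf")) {
    v <- get(nm)
    if (!is.null(v) && (min(v$data) < -1e-6 || max(v$data) > 1 + 1e-6))
      stop(nm, " values outside [0,1]")
  }
  if (!is.null(pv_gm) && !is.null(pv_wm) && !is.null(pv_csf)) {
    s <- pv_gm$data + pv_wm$data + pv_csf$data
    if (max(s) > 1 + 1e-6) stop("PV maps sum to more than 1 for subject ", id)
  }
  if (!is.null(lesion_mask) && any(lesion_mask$data != 0) && !is_patient)
    stop("subject ", id, " has a non-empty lesion mask but is_patient = FALSE")
  structure(list(id = as.character(id), volume = volume, pv_gm = pv_gm,
                 pv_wm = pv_wm, pv_csf = pv_csf, lesion_mask = lesion_mask,
                 is_patient = isTRUE(is_patient)),
            class = "fcd_subject")
}

#' @export
print.fcd_subject <- function(x, ...) {
  cat(sprintf("<fcd_subject> %s (%s)\n", x$id,
              if (x$is_patient) "patient" else "control"))
  print(x$volume)
  extras <- c("pv_gm", "pv_wm", "pv_csf", "lesion_mask")
  have <- extras[!vapply(x[extras], is.null, logical(1))]
  if (length(have)) cat("  with:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `id, path, is_patient, lesion_mask_path,
#' pv_gm_path, pv_wm_path, pv_csf_path` (empty fields allowed). Relative paths
#' are resolved against the manifest's directory. All subjects must share grid
#' shape and spacing — the pipeline assumes pre-aligned volumes.
#'
#' @param manifest path to the manifest CSV.
#' @return list of [fcd_subject]s.
#' @export
read_cohort <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "path", "is_patient")
  if (!all(need %in% names(tab)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  opt <- function(row, col) {
    p <- if (col %in% names(tab)) resolve(row[[col]]) else NULL
    if (is.null(p)) NULL else read_volume(p)
  }
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    fcd_subject(id = row$id,
                volume = read_volume(resolve(row$path)),
                pv_gm = opt(row, "pv_gm_path"),
                pv_wm = opt(row, "pv_wm_path"),
                pv_csf = opt(row, "pv_csf_path"),
                lesion_mask = opt(row, "lesion_mask_path"),
                is_patient = as.logical(row$is_patient))
  })
  ref <- subjects[[1]]$volume
  for (s in subjects)
    if (!same_grid(ref, s$volume))
      stop("cohort volumes are not on a common grid (subject ", s$id, ")")
  subjects
}

#' Write a cohort of subjects as NIfTI files plus a manifest CSV
#'
#' @param subjects list of [fcd_subject]s.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    paths <- list(path = sprintf("%s_t1.nii.gz", s$id),
                  lesion_mask_path = sprintf("%s_lesion.nii.gz", s$id),
                  pv_gm_path = sprintf("%s_pvgm.nii.gz", s$id),
                  pv_wm_path = sprintf("%s_pvwm.nii.gz", s$id),
                  pv_csf_path = sprintf("%s_pvcsf.nii.gz", s$id))
    write_volume(s$volume, file.path(dir, paths$path))
    member <- list(lesion_mask_path = s$lesion_mask, pv_gm_path = s$pv_gm,
                   pv_wm_path = s$pv_wm, pv_csf_path = s$pv_csf)
    for (col in names(member)) {
      if (is.null(member[[col]])) paths[[col]] <- ""
      else write_volume(member[[col]], file.path(dir, paths[[col]]),
                        mask = col == "lesion_mask_path")
    }
    data.frame(id = s$id, path = paths$path, is_patient = s$is_patient,
               lesion_mask_path = paths$lesion_mask_path,
               pv_gm_path = paths$pv_gm_path, pv_wm_path = paths$pv_wm_path,
               pv_csf_path = paths$pv_csf_path, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
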