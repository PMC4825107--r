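#' Morphological opening of a binary label volume
#'
#' Erosion followed by dilation with a cubic `Lw^3` structuring element
#' (separable min/max filters; outside the grid counts as background). Opening
#' removes positive structures thinner than the window, is anti-extensive
#' (output positives are a subset of the input positives) and idempotent.
#'
#' @param labels 0/1 3D array or [fcd_volume].
#' @param Lw odd window edge length in voxels (`Lw = 1` is the identity).
#' @return 0/1 3D array.
#' @export
morphological_opening <- function(labels, Lw = 3L) {
  a <- if (inherits(labels, "fcd_volume")) labels$data else labels
  stopifnot(Lw >= 1L, Lw %% 2L == 1L, all(a %in% c(0, 1)))
  if (Lw == 1L) return(a)
  mode_in <- storage.mode(a)
  r <- (Lw - 1L) %/% 2L
  minmax_axis <- function(x, ax, op, fill) {
    acc <- x
    for (off in setdiff(seq(-r, r), 0L)) {
      sh <- switch(ax,
                   shift_array(x, off, 0L, 0L, fill = fill),
                   shift_array(x, 0L, off, 0L, fill = fill),
                   shift_array(x, 0L, 0L, off, fill = fill))
      acc <- op(acc, sh)
    }
    acc
  }
  erode <- function(x) {
    for (ax in 1:3) x <- minmax_axis(x, ax, pmin, fill = 0)
    x
  }
  dilate <- function(x) {
    for (ax in 1:3) x <- minmax_axis(x, ax, pmax, fill = 0)
    x
  }
  out <- dilate(erode(a))
  storage.mode(out) <- mode_in
  out
}

#' Connected regions of a binary label volume
#'
#' Labels maximal connected components of the positive voxels under 6-, 18-
#' or 26-connectivity (voxel adjacency graph, components via igraph) and
#' measures each: voxel count, physical volume, bounding box, centroid.
#'
#' @param labels 0/1 3D array or [fcd_volume].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @param spacing voxel size in mm (taken from `labels` if an [fcd_volume]).
#' @return An object of class `puv_regions`: list with `label_map` (integer
#'   array, 0 = background), `regions` (data frame), `spacing`.
#' @export
connected_regions <- function(labels, connectivity = 26L, spacing = NULL) {
  if (inherits(labels, "fcd_volume")) {
    spacing <- spacing %||% labels$spacing
    labels <- labels$data
  }
  spacing <- as.numeric(spacing %||% c(1, 1, 1))
  stopifnot(connectivity %in% c(6L, 18L, 26L), all(labels %in% c(0, 1)))
  d <- dim(labels)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  deg <- abs(offsets$dx) + abs(offsets$dy) + abs(offsets$dz)
  keep <- switch(as.character(connectivity),
                 "6" = deg == 1, "18" = deg >= 1 & deg <= 2, "26" = deg >= 1)
  offsets <- offsets[keep, , drop = FALSE]
  # half set: each unordered neighbour pair appears once
  offsets <- offsets[offsets$dx > 0 |
                     (offsets$dx == 0 & offsets$dy > 0) |
                     (offsets$dx == 0 & offsets$dy == 0 & offsets$dz > 0), ,
                     drop = FALSE]
  pos <- which(labels == 1)
  label_map <- array(0L, dim = d)
  if (length(pos) == 0L) {
    return(structure(list(label_map = label_map,
                          regions = data.frame(region_id = integer(),
                                               voxel_count = integer(),
                                               volume_mm3 = numeric()),
                          spacing = spacing),
                     class = "puv_regions"))
  }
  vid <- array(0L, dim = d)
  vid[pos] <- seq_along(pos)
  edges <- NULL
  lab <- labels == 1
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    nb <- shift_array(lab, -o$dx, -o$dy, -o$dz, fill = FALSE)
    both <- which(lab & nb)
    if (length(both)) {
      nbid <- shift_array(vid, -o$dx, -o$dy, -o$dz, fill = 0L)
      edges <- rbind(edges, cbind(vid[both], nbid[both]))
    }
  }
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  label_map[pos] <- comp
  vox_per_mm3 <- prod(spacing)
  idx <- arrayInd(pos, d)
  regions <- do.call(rbind, lapply(sort(unique(comp)), function(cid) {
    sel <- comp == cid
    coords <- idx[sel, , drop = FALSE]
    data.frame(region_id = cid, voxel_count = sum(sel),
               volume_mm3 = sum(sel) * vox_per_mm3,
               xmin = min(coords[, 1]), xmax = max(coords[, 1]),
               ymin = min(coords[, 2]), ymax = max(coords[, 2]),
               zmin = min(coords[, 3]), zmax = max(coords[, 3]),
               centroid_x = mean(coords[, 1]), centroid_y = mean(coords[, 2]),
               centroid_z = mean(coords[, 3]))
  }))
  structure(list(label_map = label_map, regions = regions, spacing = spacing),
            class = "puv_regions")
}

#' @export
print.puv_regions <- function(x, ...) {
  cat(sprintf("<puv_regions> %d connected region(s)\n", nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions[, c("region_id", "voxel_count", "volume_mm3")])
  invisible(x)
}

#' Convert a physical size threshold to a voxel count
#'
#' `Ts` is configured in mm^3 and compared against region volumes; at a given
#' voxel spacing it corresponds to `Ts_mm3 / prod(spacing)` voxels (e.g.
#' 112.5 mm^3 at 0.5 mm isotropic spacing is 900 voxels).
#'
#' @param Ts_mm3 size threshold in mm^3.
#' @param spacing voxel size in mm per axis.
#' @return equivalent (possibly fractional) voxel count.
#' @export
ts_voxel_count <- function(Ts_mm3, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(Ts_mm3 >= 0, all(spacing > 0))
  Ts_mm3 / prod(spacing)
}

#' Remove connected regions smaller than a physical size threshold
#'
#' Regions with volume strictly below `Ts_mm3` are relabelled non-lesional;
#' survivors are untouched, so every surviving component has volume at least
#' `Ts_mm3`.
#'
#' @param regions a `puv_regions` from [connected_regions()].
#' @param Ts_mm3 size threshold in mm^3 (default the working default
#'   112.5 mm^3).
#' @return list with 0/1 array `labels` and data frame `surviving` describing
#'   the retained regions.
#' @export
filter_small_regions <- function(regions, Ts_mm3 = 112.5) {
  stopifnot(inherits(regions, "puv_regions"), Ts_mm3 >= 0)
  keep <- regions$regions$region_id[regions$regions$volume_mm3 >= Ts_mm3]
  out <- array(0, dim = dim(regions$label_map))
  out[regions$label_map %in% keep] <- 1
  list(labels = out,
       surviving = regions$regions[regions$regions$region_id %in% keep, ,
                                   drop = FALSE])
}

#' Subject-level call from a refined label volume
#'
#' A subject is called a patient exactly when any positive voxel survives
#' region refinement.
#'
#' @param refined 0/1 3D array (post-filter label volume).
#' @param subject_id subject identifier.
#' @param surviving optional data frame of surviving regions.
#' @return An object of class `puv_call`: list with `subject_id`,
#'   `is_patient_pred`, `surviving`.
#' @export
subject_call <- function(refined, subject_id, surviving = NULL) {
  a <- if (inherits(refined, "fcd_volume")) refined$data else refined
  structure(list(subject_id = as.character(subject_id),
                 is_patient_pred = any(a != 0),
                 surviving = surviving),
            class = "puv_call")
}

#' @export
print.puv_call <- function(x, ...) {
  cat(sprintf("<puv_call> %s -> %s\n", x$subject_id,
              if (x$is_patient_pred) "patient" else "control"))
  invisible(x)
}

#' Refine a raw label volume: opening, labelling, size filter, subject call
#'
#' The region-connection stage in pipeline order: morphological opening with
#' an `Lw^3` window, connected-component labelling, removal of components
#' smaller than `Ts_mm3`, and the subject-level patient/control call.
#'
#' @param labels 0/1 3D array or [fcd_volume] of raw voxel labels.
#' @param spacing voxel size in mm.
#' @param subject_id subject identifier for the call.
#' @param Lw opening window edge (odd; 3 by default).
#' @param Ts_mm3 region size threshold in mm^3 (112.5 by default).
#' @param connectivity component connectivity (26 by default).
#' @return list with arrays `opened` and `filtered`, the `puv_regions`, the
#'   surviving-region table, and the `puv_call`.
#' @export
refine_labels <- function(labels, spacing, subject_id = "subject",
                          Lw = 3L, Ts_mm3 = 112.5, connectivity = 26L) {
  if (inherits(labels, "fcd_volume")) {
    spacing <- labels$spacing
    labels <- labels$data
  }
  opened <- morphological_opening(labels, Lw)
  regions <- connected_regions(opened, connectivity, spacing)
  filt <- filter_small_regions(regions, Ts_mm3)
  list(opened = opened, filtered = filt$labels, regions = regions,
       surviving = filt$surviving,
       call = subject_call(filt$labels, subject_id, filt$surviving))
}
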