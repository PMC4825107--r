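#' Standardize volume intensities to the 0--255 scale
#'
#' Two-point robust linear rescale: the `lo`/`hi` percentiles of the in-brain
#' intensities are mapped to 0/255 and the result is clipped to [0, 255].
#' Percentiles are order statistics (inverse-ECDF, no interpolation), so
#' clipping ties the extreme tails at exactly 0 and 255 and the operation is
#' exactly idempotent. Background voxels (outside the head mask) are set to 0.
#'
#' @param vol an [fcd_volume].
#' @param lo,hi robust percentiles (in percent) mapped to 0 and 255.
#' @return A standardized [fcd_volume] with `units = "standardized"`.
#' @export
standardize_intensity <- function(vol, lo = 1, hi = 99) {
  stopifnot(inherits(vol, "fcd_volume"), lo < hi)
  m <- vol_mask(vol)
  x <- vol$data[m]
  if (length(unique(x[is.finite(x)])) < 2L) stop("degenerate intensity range")
  p <- quantile(x, c(lo, hi) / 100, names = FALSE, type = 1)
  if (p[2] <= p[1]) stop("degenerate intensity range")
  y <- (vol$data - p[1]) * (255 / (p[2] - p[1]))
  y[y < 0] <- 0
  y[y > 255] <- 255
  y[!m] <- 0
  fcd_volume(y, vol$spacing, mask = vol$mask, units = "standardized")
}

# Smoothed 256-bin in-brain histogram on [0,255] plus GM/WM peak windows.
# Modes: local maxima of the width-5 moving-average-smoothed histogram,
# accepted in height order when separated from every accepted mode by >=
# min_sep bins with a genuine valley between (dip below half the smaller
# peak). Up to three modes are kept (CSF can out-count GM/WM); the two
# brightest are the GM and WM peaks. Each peak's support window is
# +/- 2 x FWHM around the peak.
find_intensity_peaks <- function(vol, bins = 256L, min_sep = 20L) {
  m <- vol_mask(vol)
  x <- vol$data[m]
  breaks <- seq(0, 255, length.out = bins + 1L)
  x <- pmin(pmax(x, 0), 255)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  # moving average width 5, truncated-renormalized at the ends
  k <- 2L
  hs <- vapply(seq_len(bins), function(i) {
    w <- max(1L, i - k):min(bins, i + k)
    mean(h[w])
  }, numeric(1))
  is_max <- vapply(seq_len(bins), function(i) {
    l <- if (i > 1L) hs[i - 1L] else -Inf
    r <- if (i < bins) hs[i + 1L] else -Inf
    hs[i] > l && hs[i] >= r && hs[i] > 0
  }, logical(1))
  cand <- which(is_max)[order(hs[is_max], decreasing = TRUE)]
  if (length(cand) < 2L) stop("bimodality not found")
  valley_ok <- function(p, q) {
    abs(p - q) >= min_sep && min(hs[min(p, q):max(p, q)]) < 0.5 * min(hs[p], hs[q])
  }
  modes <- cand[1L]
  for (p in cand[-1L]) {
    if (length(modes) == 3L) break
    if (hs[p] < 0.05 * hs[cand[1L]]) break  # sparse tail bumps are not modes
    if (all(vapply(modes, valley_ok, logical(1), p = p)))
      modes <- c(modes, p)
  }
  if (length(modes) < 2L) stop("bimodality not found")
  # the two brightest modes are the GM and WM peaks
  bright <- sort(modes)[(length(modes) - 1L):length(modes)]
  p1 <- bright[1L]; p2 <- bright[2L]
  fwhm <- function(p) {
    half <- hs[p] / 2
    l <- p; while (l > 1L && hs[l] > half) l <- l - 1L
    r <- p; while (r < bins && hs[r] > half) r <- r + 1L
    max(r - l, 1L)
  }
  window <- function(p) {
    w <- 2L * fwhm(p)
    max(1L, p - w):min(bins, p + w)
  }
  centers <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  peaks <- sort(c(p1, p2))
  list(bins = bins, counts = h, smoothed = hs, centers = centers,
       peak_bins = peaks, peak_intensities = centers[peaks],
       windows = list(window(peaks[1L]), window(peaks[2L])))
}

#' Histogram-peak overlap between a query and a reference volume
#'
#' Checks that a standardized query volume's GM and WM histogram peaks line up
#' with a reference subject's. Both in-brain histograms are restricted to the
#' union of the two volumes' peak support windows (+/- 2 FWHM around each of
#' the GM and WM peaks), normalized to unit mass there, and compared by
#' histogram intersection: `sum_b min(hq_b, hr_b)`. A query passes intensity
#' normalization when the overlap is at least `pass` (0.9 by default).
#'
#' @param query,reference standardized [fcd_volume]s.
#' @param bins histogram bin count on the 0--255 scale.
#' @param pass overlap fraction required to pass.
#' @return list with `overlap` (fraction in [0,1]) and logical `pass`.
#' @export
histogram_peak_overlap <- function(query, reference, bins = 256L, pass = 0.9) {
  for (v in list(query, reference))
    if (!identical(v$units, "standardized"))
      stop("histogram_peak_overlap expects standardized volumes")
  pq <- find_intensity_peaks(query, bins)
  pr <- find_intensity_peaks(reference, bins)
  sel <- sort(unique(c(unlist(pq$windows), unlist(pr$windows))))
  hq <- pq$counts[sel]; hr <- pr$counts[sel]
  if (sum(hq) == 0 || sum(hr) == 0) return(list(overlap = 0, pass = FALSE))
  hq <- hq / sum(hq); hr <- hr / sum(hr)
  ov <- sum(pmin(hq, hr)) / sum(hr)  # sum(hr) == 1; kept for the stated form
  list(overlap = ov, pass = ov >= pass)
}

#' Trilinear resampling to a target voxel spacing
#'
#' Resamples a volume onto a new grid whose shape is `ceil(extent /
#' target_spacing)` per axis, with voxel centres at `(i-1) * target_spacing`.
#' Values are trilinear interpolants of the input (clamped to the input grid at
#' the borders), so the output range is contained in the input range and
#' resampling at the original spacing is the identity.
#'
#' @param vol an [fcd_volume].
#' @param target_spacing numeric length-3, target voxel size in mm.
#' @return The resampled [fcd_volume].
#' @export
resample_trilinear <- function(vol, target_spacing) {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  d <- dim(vol$data); sp <- vol$spacing
  nd <- pmax(1L, as.integer(ceiling(d * sp / target_spacing)))
  # continuous input index (1-based) of each output voxel centre, clamped
  idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(nd[ax]) - 1) * target_spacing[ax]) / sp[ax] + 1
    pmin(pmax(x, 1), d[ax])
  })
  i0 <- lapply(1:3, function(ax) pmin(floor(idx[[ax]]), d[ax] - 1L))
  fr <- lapply(1:3, function(ax) {
    if (d[ax] == 1L) rep(0, nd[ax]) else idx[[ax]] - i0[[ax]]
  })
  i0 <- lapply(1:3, function(ax) if (d[ax] == 1L) rep(1L, nd[ax]) else as.integer(i0[[ax]]))
  gx <- rep(i0[[1]], times = nd[2] * nd[3])
  gy <- rep(rep(i0[[2]], each = nd[1]), times = nd[3])
  gz <- rep(i0[[3]], each = nd[1] * nd[2])
  fx <- rep(fr[[1]], times = nd[2] * nd[3])
  fy <- rep(rep(fr[[2]], each = nd[1]), times = nd[3])
  fz <- rep(fr[[3]], each = nd[1] * nd[2])
  interp <- function(a) {
    at <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
    sx <- pmin(gx + 1L, d[1]); sy <- pmin(gy + 1L, d[2]); sz <- pmin(gz + 1L, d[3])
    v <- at(gx, gy, gz) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(sx, gy, gz) * fx * (1 - fy) * (1 - fz) +
      at(gx, sy, gz) * (1 - fx) * fy * (1 - fz) +
      at(sx, sy, gz) * fx * fy * (1 - fz) +
      at(gx, gy, sz) * (1 - fx) * (1 - fy) * fz +
      at(sx, gy, sz) * fx * (1 - fy) * fz +
      at(gx, sy, sz) * (1 - fx) * fy * fz +
      at(sx, sy, sz) * fx * fy * fz
    array(v, dim = nd)
  }
  out <- interp(vol$data)
  mask <- if (is.null(vol$mask)) NULL else interp(vol$mask * 1) >= 0.5
  fcd_volume(out, target_spacing, mask = mask, units = vol$units)
}
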