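#' Collewet intensity normalization
#'
#' Clips ROI intensities to the mean +/- 3 SD band of the ROI itself,
#' reducing protocol-dependent outliers.  Statistics are computed from
#' `stats_mask` (the tumor ROI by default) and the clip is applied to
#' in-mask voxels only; out-of-mask voxels are untouched.  A zero-variance
#' ROI is returned unchanged with a message.
#'
#' @param volume an [image_volume].
#' @param tumor_mask logical array; voxels to clip.
#' @param stats_mask logical array for the mean/SD statistics; defaults
#'   to `tumor_mask`.
#' @return an [image_volume] with attribute `collewet_applied = TRUE`.
#' @export
collewet_normalize <- function(volume, tumor_mask, stats_mask = tumor_mask) {
  if (!any(stats_mask)) stop("empty mask")
  v <- volume$data
  x <- v[stats_mask != 0]
  mu <- mean(x); s <- sd(x) * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) {
    message("collewet_normalize: zero in-mask variance, volume unchanged")
    out <- volume
  } else {
    sel <- tumor_mask != 0
    v[sel] <- pmin(pmax(v[sel], mu - 3 * s), mu + 3 * s)
    out <- image_volume(v, volume$spacing)
  }
  attr(out, "collewet_applied") <- TRUE
  attr(out, "urine_applied") <- isTRUE(attr(volume, "urine_applied"))
  out
}

#' Bladder-urine intensity normalization
#'
#' Divides every voxel by the mean intensity inside the bladder-urine
#' reference mask, so the urine mean becomes exactly 1.  This anchors the
#' quantization scale across scanners and timepoints.
#'
#' @param volume an [image_volume].
#' @param bladder_mask logical array (non-empty; mean intensity > 0).
#' @return an [image_volume] with attribute `urine_applied = TRUE`.
#' @export
urine_normalize <- function(volume, bladder_mask) {
  if (!any(bladder_mask)) stop("empty bladder mask")
  m <- mean(volume$data[bladder_mask != 0])
  if (!is.finite(m) || m <= 0)
    stop("non-positive bladder mean intensity (", format(m),
         "); degenerate input")
  out <- image_volume(volume$data / m, volume$spacing)
  attr(out, "collewet_applied") <- isTRUE(attr(volume, "collewet_applied"))
  attr(out, "urine_applied") <- TRUE
  out
}

# Core level mapping: right-closed bins so an intensity of exactly 1
# (the urine mean) lands on the top level.
quantize_levels <- function(v, levels = 64L) {
  if (levels < 2L) stop("need at least 2 quantization levels")
  q <- ceiling(levels * v)
  q[q < 1] <- 1L
  q[q > levels] <- levels
  storage.mode(q) <- "integer"
  q
}

#' Quantize a normalized volume into discrete gray levels
#'
#' Maps urine-normalized intensities to levels `1..levels` via
#' `clamp(ceiling(levels * v), 1, levels)`: intensity 1 (the urine mean)
#' maps to the highest level, `v <= 0` to level 1, `v > 1` to the top
#' level.  The whole grid is quantized; the mask only selects voxels, so
#' translated masks can reuse the same level array.
#'
#' @param volume an [image_volume] after urine normalization.
#' @param mask logical tumor mask.
#' @param levels level count (default 64).
#' @param dims `"3D"` or `"2D"`.
#' @return a [quantized_roi].
#' @export
quantize <- function(volume, mask, levels = 64L, dims = c("3D", "2D")) {
  dims <- match.arg(dims)
  lev <- quantize_levels(volume$data, levels)
  quantized_roi(lev, mask, volume$data, volume$spacing, levels, dims)
}

# Resample a (z,y,x) array from `spacing` to `new_spacing` (mm).
# Trilinear for intensities, nearest-neighbor for masks; voxel centers at
# (i + 0.5) * spacing, output grid sized to preserve physical extent.
resample_grid <- function(arr, spacing, new_spacing, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  nd <- pmax(1L, as.integer(round(d * spacing / new_spacing)))
  fs <- lapply(1:3, function(a) {
    f <- ((seq_len(nd[a]) - 0.5) * new_spacing[a]) / spacing[a] - 0.5
    pmin(pmax(f, 0), d[a] - 1)
  })
  if (method == "nearest") {
    iz <- round(fs[[1]]) + 1; iy <- round(fs[[2]]) + 1; ix <- round(fs[[3]]) + 1
    return(arr[iz, iy, ix, drop = FALSE])
  }
  lo <- lapply(fs, floor)
  w <- mapply(function(f, l) f - l, fs, lo, SIMPLIFY = FALSE)
  lo <- lapply(seq_along(lo), function(a) pmin(lo[[a]], d[a] - 1))
  hi <- lapply(seq_along(lo), function(a) pmin(lo[[a]] + 1, d[a] - 1))
  out <- array(0, dim = nd)
  grid <- function(zv, yv, xv)
    arr[cbind(rep(zv + 1, times = nd[2] * nd[3]),
              rep(rep(yv + 1, each = nd[1]), times = nd[3]),
              rep(xv + 1, each = nd[1] * nd[2]))]
  wz <- rep(w[[1]], times = nd[2] * nd[3])
  wy <- rep(rep(w[[2]], each = nd[1]), times = nd[3])
  wx <- rep(w[[3]], each = nd[1] * nd[2])
  vals <-
    grid(lo[[1]], lo[[2]], lo[[3]]) * (1 - wz) * (1 - wy) * (1 - wx) +
    grid(hi[[1]], lo[[2]], lo[[3]]) * wz       * (1 - wy) * (1 - wx) +
    grid(lo[[1]], hi[[2]], lo[[3]]) * (1 - wz) * wy       * (1 - wx) +
    grid(hi[[1]], hi[[2]], lo[[3]]) * wz       * wy       * (1 - wx) +
    grid(lo[[1]], lo[[2]], hi[[3]]) * (1 - wz) * (1 - wy) * wx +
    grid(hi[[1]], lo[[2]], hi[[3]]) * wz       * (1 - wy) * wx +
    grid(lo[[1]], hi[[2]], hi[[3]]) * (1 - wz) * wy       * wx +
    grid(hi[[1]], hi[[2]], hi[[3]]) * wz       * wy       * wx
  array(vals, dim = nd)
}

#' Isotropic 1 mm resampling of a volume and its masks
#'
#' Trilinear interpolation for intensities, nearest-neighbor for masks;
#' the output grid covers the same physical extent at `target` (default
#' 1 mm) isotropic spacing.
#'
#' @param volume an [image_volume].
#' @param masks named list of logical arrays on the same grid.
#' @param target isotropic target spacing in mm.
#' @return list with `volume` (resampled [image_volume]) and `masks`.
#' @export
resample_isotropic_3d <- function(volume, masks, target = 1) {
  ns <- rep(target, 3)
  v <- resample_grid(volume$data, volume$spacing, ns, "linear")
  ms <- lapply(masks, function(m) {
    r <- resample_grid(m + 0, volume$spacing, ns, "nearest") > 0
    if (!any(r)) stop("mask empty after resampling")
    r
  })
  list(volume = image_volume(v, ns), masks = ms)
}

#' Select and resample the largest-area axial slice
#'
#' Finds the axial (z) slice with maximal in-plane mask area (mm^2), ties
#' broken toward the lowest slice index, and resamples the slice and mask
#' in-plane to 1 x 1 mm.  The result is a single-slice `(1, ny, nx)`
#' volume/mask pair ready for 2D quantization.
#'
#' @param volume an [image_volume] (normalized intensities).
#' @param mask3d logical tumor mask on the same grid.
#' @param target in-plane target spacing in mm.
#' @return list with `volume`, `mask`, and the selected `slice_index`.
#' @export
select_largest_slice_2d <- function(volume, mask3d, target = 1) {
  if (!any(mask3d)) stop("empty mask")
  pix <- prod(volume$spacing[2:3])
  areas <- apply(mask3d, 1, sum) * pix
  k <- which.max(areas)            # which.max takes the first (lowest) tie
  sl <- volume$data[k, , , drop = FALSE]
  mk <- mask3d[k, , , drop = FALSE]
  sp_in <- c(1, volume$spacing[2:3])
  sp_out <- c(1, target, target)
  v2 <- resample_grid(sl, sp_in, sp_out, "linear")
  m2 <- resample_grid(mk + 0, sp_in, sp_out, "nearest") > 0
  if (!any(m2)) stop("mask empty after in-plane resampling")
  out <- image_volume(v2, sp_out)
  attr(out, "urine_applied") <- isTRUE(attr(volume, "urine_applied"))
  list(volume = out, mask = m2, slice_index = k)
}

#' Full preprocessing of one volume with its ROIs
#'
#' Runs the fixed chain Collewet clip (tumor ROI statistics) ->
#' urine normalization -> isotropic 1 mm resampling -> 64-level
#' quantization for 3D, and largest-slice selection with in-plane 1 mm
#' resampling for 2D.  Intensities are resampled before quantization so
#' discrete levels are never interpolated.
#'
#' @param volume raw [image_volume].
#' @param rois an [roi_set] on the same grid.
#' @param levels quantization level count.
#' @param collewet apply the Collewet clip first (default TRUE).
#' @return list with `q3d`, `q2d` ([quantized_roi]s), the normalized
#'   native-grid `normalized` volume, and the 2D `slice_index`.
#' @export
preprocess_case <- function(volume, rois, levels = 64L, collewet = TRUE) {
  v <- if (collewet) collewet_normalize(volume, rois$tumor) else volume
  v <- urine_normalize(v, rois$bladder)
  iso <- resample_isotropic_3d(v, list(tumor = rois$tumor))
  q3d <- quantize(iso$volume, iso$masks$tumor, levels, "3D")
  sl <- select_largest_slice_2d(v, rois$tumor)
  q2d <- quantize(sl$volume, sl$mask, levels, "2D")
  list(q3d = q3d, q2d = q2d, normalized = v, slice_index = sl$slice_index)
}
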