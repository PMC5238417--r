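# Scan-to-map workflow: breast masking, reference-region averaging, lesion
# ROI rules, and per-pixel absorption/composition difference maps.

#' Scanned transmittance image
#'
#' A grid of time-resolved transmittance curves acquired at 1 mm pitch over
#' the compressed breast, co-registered across the 7 wavelengths. Pixel
#' coordinates are 0-based grid indices with (0,0) at the top-left, x
#' rightward, y downward; physical position in mm is index times the pitch.
#'
#' @param curves Named list (names = wavelengths, nm) of 3-D arrays
#'   `[ny, nx, nt]` of per-pixel counts.
#' @param time_ps Shared uniform time grid (length nt).
#' @param pitch_mm Scan pitch (1 mm for the instrument protocol).
#' @param view Acquisition view, `"CC"` (cranio-caudal) or `"OB"` (oblique).
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(curves, time_ps, pitch_mm = 1, view = c("CC", "OB")) {
  view <- match.arg(view)
  stopifnot(is.list(curves), length(curves) >= 1)
  dims <- dim(curves[[1]])
  for (a in curves) {
    stopifnot(length(dim(a)) == 3L, identical(dim(a), dims))
  }
  stopifnot(dims[3] == length(time_ps))
  structure(list(curves = curves,
                 wavelengths = as.numeric(names(curves)),
                 time_ps = time_ps, pitch_mm = pitch_mm, view = view,
                 dim = dims[1:2]),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Scan image: %d x %d pixels at %g mm pitch, %d wavelengths (%s view)\n",
              x$dim[1], x$dim[2], x$pitch_mm, length(x$curves), x$view))
  invisible(x)
}

# per-pixel total counts summed over time and wavelengths
.scan_totals <- function(scan) {
  Reduce(`+`, lapply(scan$curves, function(a) apply(a, c(1, 2), sum)))
}

#' Breast mask from total counts
#'
#' Marks pixels whose total counts (all wavelengths) reach `count_threshold`
#' — mirroring the acquisition feedback that restricts the scan to the breast
#' — and keeps only the largest connected component.
#'
#' @param scan A [scan_image()].
#' @param count_threshold Minimum total counts per pixel (> 0).
#' @return Logical matrix `[ny, nx]`.
#' @export
breast_mask <- function(scan, count_threshold) {
  stopifnot(inherits(scan, "scan_image"))
  if (count_threshold <= 0) stop("count_threshold must be > 0")
  mask <- .scan_totals(scan) >= count_threshold
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  labm <- t(EBImage::imageData(lab))
  sizes <- table(labm[labm > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  labm == keep
}

# binary erosion with a disc of the given radius in pixels
.erode_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  if (2 * radius_px + 1 > min(dim(mask)))
    return(mask & FALSE)                    # structuring element exceeds grid
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  er <- EBImage::erode(EBImage::Image(t(mask * 1)), brush)
  t(EBImage::imageData(er)) > 0.5
}

#' Reference (unperturbed) curve from the breast interior
#'
#' Averages per-pixel curves over a reference region: the breast mask eroded
#' by `erosion_mm` (excluding boundaries), minus pixels whose window-8 counts
#' deviate more than `mad_k` MADs from the region median at any wavelength
#' (excluding marked inhomogeneities such as vessels or the lesion itself).
#' A warning is raised when the final region covers less than half the mask.
#'
#' @param scan A [scan_image()].
#' @param mask Breast mask from [breast_mask()].
#' @param erosion_mm Boundary erosion depth, mm (default 10).
#' @param mad_k Outlier cut in MAD units (default 3).
#' @param K Number of equal-count windows (default 10).
#' @return List with `T0` (named list of per-pixel-mean [trcurve()]s),
#'   `windows` (per-wavelength `time_windows` gates derived from `T0`),
#'   `region` (logical matrix), `coverage` (region / mask fraction).
#' @export
reference_curve <- function(scan, mask, erosion_mm = 10, mad_k = 3, K = 10) {
  stopifnot(inherits(scan, "scan_image"), is.logical(mask))
  r_px <- round(erosion_mm / scan$pitch_mm)
  region <- .erode_mask(mask, r_px)
  if (!any(region)) stop("reference region empty after erosion")
  idx <- which(region)
  nt <- length(scan$time_ps)
  # preliminary per-wavelength mean curves and gates
  t0_prelim <- lapply(scan$curves, function(a) {
    m <- matrix(a, ncol = nt)[idx, , drop = FALSE]
    colMeans(m)
  })
  keep <- rep(TRUE, length(idx))
  for (wl in names(scan$curves)) {
    w <- equal_count_windows(t0_prelim[[wl]], K)
    m <- matrix(scan$curves[[wl]], ncol = nt)[idx, , drop = FALSE]
    w8 <- as.numeric(m %*% w$weights[, min(8, K)])
    med <- median(w8); s <- mad(w8)
    if (s > 0) keep <- keep & abs(w8 - med) <= mad_k * s
  }
  region2 <- region
  region2[idx[!keep]] <- FALSE
  coverage <- sum(region2) / sum(mask)
  if (coverage < 0.5)
    warning(sprintf("reference region covers only %.0f%% of the breast mask",
                    100 * coverage))
  idx2 <- which(region2)
  T0 <- lapply(names(scan$curves), function(wl) {
    m <- matrix(scan$curves[[wl]], ncol = nt)[idx2, , drop = FALSE]
    trcurve(scan$time_ps, colMeans(m), as.numeric(wl))
  })
  names(T0) <- names(scan$curves)
  windows <- lapply(T0, equal_count_windows, K = K)
  list(T0 = T0, windows = windows, region = region2, coverage = coverage)
}

#' Lesion ROI side from the maximum lesion diameter
#'
#' The analysis protocol selects a 9 x 9 mm^2 lesion area for maximum
#' diameters strictly greater than 15 mm and 5 x 5 mm^2 otherwise; lesions
#' below 10 mm are not analyzed.
#'
#' @param max_diameter_mm Maximum lesion diameter, mm (>= 10).
#' @return ROI side in mm (5 or 9).
#' @examples
#' roi_for_diameter(18)  # 9
#' roi_for_diameter(15)  # 5 (strict inequality)
#' @export
roi_for_diameter <- function(max_diameter_mm) {
  if (!is.finite(max_diameter_mm) || max_diameter_mm < 10)
    stop("only lesions with maximum diameter >= 10 mm are analyzed")
  if (max_diameter_mm > 15) 9 else 5
}

#' Equivalent-sphere radius from the maximum lesion diameter
#'
#' The perturbation volume is an equivalent sphere based on the maximum
#' lesion diameter (from histopathology or radiology).
#'
#' @param max_diameter_mm Maximum diameter, mm (> 0).
#' @return Radius in cm.
#' @export
equivalent_sphere <- function(max_diameter_mm) {
  if (!is.finite(max_diameter_mm) || max_diameter_mm <= 0)
    stop("diameter must be > 0")
  max_diameter_mm / 2 / 10
}

# exact window-level delta_mua for a vector of pixel window counts
.invert_window <- function(Tw, T0_counts, wweights, l_cm) {
  T0w <- wweights * T0_counts
  vapply(Tw, function(tw) estimate_delta_mua(tw, T0w, l_cm), numeric(1))
}

#' Absorption and composition difference maps
#'
#' Per-pixel perturbative analysis of a scan: window-8 counts against the
#' reference curve are inverted through the modified Beer-Lambert law (with a
#' fixed default sphere as the assumed perturbation volume, since maps carry
#' no lesion prior), then unmixed into constituent concentration differences.
#' Out-of-mask pixels are NA.
#'
#' @param scan A [scan_image()].
#' @param mask Breast mask.
#' @param ref Reference from [reference_curve()].
#' @param props_list Named list (by wavelength) of background
#'   [optical_properties()].
#' @param geom [slab_geometry()].
#' @param spectra `extinction_spectra` for the unmixing step.
#' @param pert_radius_cm Assumed sphere radius for the per-pixel kernel
#'   (default 0.5 cm; ROI quantification should use [quantify_lesion()] with
#'   the known equivalent sphere instead).
#' @param window Analysis window index (default 8 of 10).
#' @param nq Quadrature orders for the Born kernel.
#' @param irf Known `instrument_response`, used to put the pathlength kernel
#'   on the measured time axis (see [effective_pathlength()]); `NULL` skips
#'   the correction.
#' @return Object of class `composition_maps`: list with `delta_mua` (list of
#'   matrices by wavelength), `delta_c` (matrices Hb, HbO2, tHb, water, lipid,
#'   collagen), `mask`, and `stats` (per-map min/max).
#' @export
compute_maps <- function(scan, mask, ref, props_list, geom, spectra,
                         pert_radius_cm = 0.5, window = 8, nq = c(8, 8, 8),
                         irf = NULL) {
  stopifnot(inherits(scan, "scan_image"))
  wls <- names(scan$curves)
  if (!all(wls %in% names(props_list)))
    stop("props_list must cover every scan wavelength")
  nt <- length(scan$time_ps)
  idx <- which(mask)
  dmua <- matrix(NA_real_, length(idx), length(wls))
  pert <- spherical_perturbation(pert_radius_cm)
  for (j in seq_along(wls)) {
    wl <- wls[j]
    props <- props_list[[wl]]
    kern <- effective_pathlength(props, geom, pert, scan$time_ps, irf = irf,
                                 nq = nq)
    w <- ref$windows[[wl]]
    wv <- w$weights[, window]
    m <- matrix(scan$curves[[wl]], ncol = nt)[idx, , drop = FALSE]
    Tw <- as.numeric(m %*% wv)
    dmua[, j] <- .invert_window(Tw, ref$T0[[wl]]$counts, wv, kern$l_cm)
  }
  dc <- t(qr.solve(qr(unclass(spectra)), t(dmua)))
  colnames(dc) <- colnames(spectra)
  shape <- function(vals) {
    mm <- matrix(NA_real_, scan$dim[1], scan$dim[2])
    mm[idx] <- vals
    mm
  }
  delta_mua_maps <- lapply(seq_along(wls), function(j) shape(dmua[, j]))
  names(delta_mua_maps) <- wls
  dc_maps <- list(Hb = shape(dc[, "Hb"]), HbO2 = shape(dc[, "HbO2"]),
                  tHb = shape(dc[, "Hb"] + dc[, "HbO2"]),
                  water = shape(dc[, "water"]), lipid = shape(dc[, "lipid"]),
                  collagen = shape(dc[, "collagen"]))
  all_maps <- c(delta_mua_maps, dc_maps)
  stats <- data.frame(map = names(all_maps),
                      min = vapply(all_maps, min, numeric(1), na.rm = TRUE),
                      max = vapply(all_maps, max, numeric(1), na.rm = TRUE),
                      row.names = NULL)
  structure(list(delta_mua = delta_mua_maps, delta_c = dc_maps, mask = mask,
                 stats = stats, pitch_mm = scan$pitch_mm),
            class = "composition_maps")
}

#' @export
print.composition_maps <- function(x, ...) {
  cat("Composition maps:\n")
  print(x$stats, digits = 3)
  invisible(x)
}

#' Quantify a lesion from its ROI
#'
#' Aggregates curves over the lesion area (side from [roi_for_diameter()]),
#' inverts the window-8 modified Beer-Lambert law with the equivalent-sphere
#' pathlength kernel, and unmixes the 7-wavelength absorption differences
#' into composition differences.
#'
#' @param scan,ref,props_list,geom,spectra,nq,irf As in [compute_maps()].
#' @param center_mm Lesion center `(x, y)` in mm.
#' @param max_diameter_mm Maximum lesion diameter, mm (>= 10).
#' @param window Analysis window (default 8).
#' @return List with `delta_mua` (named, cm^-1), `delta_c` (Hb, HbO2, water,
#'   lipid, collagen + `thb`), `side_mm`, `radius_cm`, `n_pixels`.
#' @export
quantify_lesion <- function(scan, ref, center_mm, max_diameter_mm,
                            props_list, geom, spectra, window = 8,
                            nq = c(16, 16, 16), irf = NULL) {
  side <- roi_for_diameter(max_diameter_mm)
  radius <- equivalent_sphere(max_diameter_mm)
  half <- side / 2
  nx <- scan$dim[2]; ny <- scan$dim[1]
  xs <- (seq_len(nx) - 1) * scan$pitch_mm
  ys <- (seq_len(ny) - 1) * scan$pitch_mm
  in_x <- which(abs(xs - center_mm[1]) <= half)
  in_y <- which(abs(ys - center_mm[2]) <= half)
  if (!length(in_x) || !length(in_y)) stop("ROI falls outside the scan grid")
  # lateral offsets of the ROI pixels from the known lesion center: the ROI
  # mean mixes lines of sight that clip the sphere differently, so the
  # inversion models the ROI-mean attenuation with per-offset kernels
  off <- round(sqrt(outer((ys[in_y] - center_mm[2])^2,
                          (xs[in_x] - center_mm[1])^2, `+`)), 6)
  uoff <- sort(unique(as.numeric(off)))
  wls <- names(scan$curves)
  dmua <- setNames(numeric(length(wls)), wls)
  tab <- table(as.numeric(off))
  for (wl in wls) {
    a <- scan$curves[[wl]][in_y, in_x, , drop = FALSE]
    roi_curve <- apply(a, 3, mean)
    w <- ref$windows[[wl]]
    props <- props_list[[wl]]
    kerns <- lapply(uoff, function(d) {
      pert <- spherical_perturbation(
        radius, center = c(geom$source_xy[1] + d / 10, geom$source_xy[2],
                           geom$thickness / 2))
      partial_pathlength(props, geom, pert, scan$time_ps, nq = nq)$l_cm
    })
    wv <- w$weights[, window]
    T0m <- slab_transmittance(props, geom, scan$time_ps)
    blur <- function(y) {
      if (is.null(irf)) y else convolve_irf(trcurve(scan$time_ps, y), irf)$counts
    }
    T0w_model <- sum(wv * blur(T0m$counts))
    # window-w attenuation ratio of the ROI mean, modelled per offset with
    # the same forward chain (perturb, then blur) as the measurement
    ratio_model <- function(d) {
      att <- 0
      for (k in seq_along(uoff))
        att <- att + tab[[k]] *
          sum(wv * blur(T0m$counts * exp(-d * kerns[[k]])))
      att / sum(tab) / T0w_model
    }
    T0w <- wv * ref$T0[[wl]]$counts
    ratio_obs <- sum(wv * roi_curve) / sum(T0w)
    lbar <- sum(T0w * kerns[[1]]) / sum(T0w)
    d0 <- -log(ratio_obs) / max(lbar, 1e-6)
    dmua[wl] <- uniroot(function(d) ratio_model(d) - ratio_obs,
                        c(min(d0, 0) - 2, max(d0, 0) + 2), tol = 1e-12,
                        extendInt = "yes")$root
  }
  fit <- unmix(dmua, spectra)
  dc <- fit$delta_c
  list(delta_mua = dmua,
       delta_c = c(dc, thb = unname(dc["Hb"] + dc["HbO2"])),
       residual_norm = fit$residual_norm,
       side_mm = side, radius_cm = radius,
       n_pixels = length(in_x) * length(in_y))
}
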