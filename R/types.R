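#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and
#' wavelength of a measurement. These are the quantities recovered by
#' [fit_homogeneous()] from a time-resolved transmittance curve.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, cm^-1 (> 0).
#' @param wavelength Wavelength in nm.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(0.07, 10, 785)
#' @export
optical_properties <- function(mua, musp, wavelength = NA_real_) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua),
            is.numeric(musp), length(musp) == 1L, is.finite(musp))
  if (mua < 0) stop("mua must be >= 0")
  if (musp <= 0) stop("musp must be > 0")
  structure(list(mua = mua, musp = musp, wavelength = wavelength),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties: mua = %.4g cm^-1, musp = %.4g cm^-1, lambda = %s nm\n",
              x$mua, x$musp, format(x$wavelength)))
  invisible(x)
}

#' Transmittance slab geometry
#'
#' Geometry of the compressed-breast measurement: a slab of given thickness,
#' refractive index, and a source/detector pair facing each other on opposite
#' faces along the same line of sight (shared x, y).
#'
#' @param thickness Slab thickness in cm (> 0). Default 4 cm, a mildly
#'   compressed breast.
#' @param refractive_index Tissue refractive index (>= 1). Default 1.4.
#' @param source_xy Source (x, y) on the entry face, cm. Default c(0, 0).
#' @return An object of class `slab_geometry`. The detector shares the source
#'   (x, y) on the exit face.
#' @export
slab_geometry <- function(thickness = 4, refractive_index = 1.4,
                          source_xy = c(0, 0)) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  stopifnot(length(source_xy) == 2L)
  structure(list(thickness = thickness,
                 refractive_index = refractive_index,
                 source_xy = as.numeric(source_xy)),
            class = "slab_geometry")
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat(sprintf("Slab: s = %.3g cm, n = %.3g, source (x,y) = (%.3g, %.3g) cm\n",
              x$thickness, x$refractive_index, x$source_xy[1], x$source_xy[2]))
  invisible(x)
}

#' Spherical absorbing perturbation
#'
#' A localized lesion modelled as a sphere with an absorption contrast
#' `delta_mua` relative to the homogeneous background, fully contained in the
#' slab. By convention the sphere sits halfway between source and detector
#' (z = thickness / 2) unless a center is given.
#'
#' @param radius Sphere radius, cm (> 0).
#' @param delta_mua Absorption difference lesion minus background, cm^-1 (may
#'   be negative). Scalar, or one value per wavelength downstream.
#' @param center Numeric (x, y, z) in cm, or `NULL` for on-axis mid-slab
#'   (resolved against the geometry by the forward model).
#' @return An object of class `spherical_perturbation`.
#' @export
spherical_perturbation <- function(radius, delta_mua = 0, center = NULL) {
  stopifnot(is.numeric(radius), length(radius) == 1L)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.null(center)) stopifnot(is.numeric(center), length(center) == 3L)
  structure(list(radius = radius, delta_mua = delta_mua, center = center),
            class = "spherical_perturbation")
}

# resolve a perturbation center against geometry: default on-axis, mid-slab
.pert_center <- function(pert, geom) {
  if (is.null(pert$center))
    c(geom$source_xy[1], geom$source_xy[2], geom$thickness / 2)
  else pert$center
}

# reject spheres touching or crossing a slab face
.check_pert_inside <- function(pert, geom) {
  ctr <- .pert_center(pert, geom)
  if (ctr[3] - pert$radius <= 0 || ctr[3] + pert$radius >= geom$thickness)
    stop("perturbation sphere must lie strictly inside the slab")
  invisible(ctr)
}

#' Time-resolved transmittance curve
#'
#' A photon-count (or flux) histogram versus arrival time, the raw object of
#' time-correlated single-photon-counting detection.
#'
#' @param time_ps Strictly increasing, uniformly spaced bin centers (ps).
#' @param counts Non-negative counts or flux per bin.
#' @param wavelength Wavelength in nm (metadata).
#' @return An object of class `trcurve`.
#' @export
trcurve <- function(time_ps, counts, wavelength = NA_real_) {
  stopifnot(length(time_ps) == length(counts), length(time_ps) >= 2L)
  dt <- diff(time_ps)
  if (any(dt <= 0)) stop("time_ps must be strictly increasing")
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) stop("time bins must be uniform")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(time_ps = as.numeric(time_ps), counts = as.numeric(counts),
                 wavelength = wavelength),
            class = "trcurve")
}

#' @export
print.trcurve <- function(x, ...) {
  cat(sprintf("Time-resolved curve: %d bins, dt = %.3g ps, total = %.4g, lambda = %s nm\n",
              length(x$time_ps), x$time_ps[2] - x$time_ps[1], sum(x$counts),
              format(x$wavelength)))
  invisible(x)
}

# bin width of a trcurve, ps
.bin_width <- function(curve) curve$time_ps[2] - curve$time_ps[1]
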