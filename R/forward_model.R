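# Time-domain diffusion theory for a homogeneous slab with extrapolated
# boundaries (image-source series), and the first-order Born mean partial
# pathlength of a spherical absorbing inclusion.

# derived diffusion parameters for a slab medium
.diff_pars <- function(props, geom) {
  D <- 1 / (3 * props$musp)            # diffusion coefficient, cm
  v <- light_speed(geom$refractive_index)
  n <- geom$refractive_index
  # internal-reflection parameter A from the empirical polynomial for the
  # effective reflection coefficient at a tissue/air boundary
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  list(D = D, v = v, z0 = 1 / props$musp, ze = 2 * A * D, A = A)
}

.check_time_grid <- function(time_ps) {
  stopifnot(is.numeric(time_ps), length(time_ps) >= 2L)
  if (any(time_ps <= 0)) stop("time grid must be strictly positive")
  if (any(diff(time_ps) <= 0)) stop("time grid must be strictly increasing")
  invisible(time_ps)
}

#' Uniform time grid for transmittance curves
#'
#' Bin centers at `dt, 2 dt, ..., n dt` picoseconds. Convolution-based
#' operations (Born pathlength kernel, IRF convolution) assume this layout.
#'
#' @param dt Bin width, ps.
#' @param n Number of bins.
#' @return Numeric vector of length `n`.
#' @export
time_grid <- function(dt = 25, n = 320) dt * seq_len(n)

# image-source z coordinates for a source at depth zs inside the slab:
# positive images zp_m and negative images zm_m, m = -m_max..m_max
.slab_images <- function(zs, s, ze, m_max) {
  m <- seq.int(-m_max, m_max)
  list(zp = 2 * m * (s + 2 * ze) + zs,
       zm = 2 * m * (s + 2 * ze) - 2 * ze - zs)
}

# fluence Green's function phi(rho, z, t) inside the slab for an isotropic
# unit impulse source at depth zs (vector over t)
.slab_fluence <- function(rho, z, props, geom, time_ps, zs = NULL, m_max = 10) {
  p <- .diff_pars(props, geom)
  if (is.null(zs)) zs <- p$z0
  im <- .slab_images(zs, geom$thickness, p$ze, m_max)
  fourDvt <- 4 * p$D * p$v * time_ps
  ssum <- 0
  for (k in seq_along(im$zp)) {
    ssum <- ssum + exp(-(z - im$zp[k])^2 / fourDvt) -
                   exp(-(z - im$zm[k])^2 / fourDvt)
  }
  p$v * (pi * fourDvt)^(-1.5) *
    exp(-props$mua * p$v * time_ps - rho^2 / fourDvt) * ssum
}

# transmitted flux at the exit face for an isotropic impulse source at depth
# zs; rho is the lateral source-detector offset. integrated = TRUE returns the
# transmittance integrated over the whole exit plane.
.slab_transmittance_raw <- function(rho, props, geom, time_ps, zs = NULL,
                                    m_max = 10, integrated = FALSE) {
  p <- .diff_pars(props, geom)
  if (is.null(zs)) zs <- p$z0
  s <- geom$thickness
  im <- .slab_images(zs, s, p$ze, m_max)
  z1 <- s - im$zp                       # s(1-2m) - 4 m ze - zs
  z2 <- s - im$zm                       # s(1-2m) - (4m-2) ze + zs
  fourDvt <- 4 * p$D * p$v * time_ps
  ssum <- 0
  for (k in seq_along(z1)) {
    ssum <- ssum + z1[k] * exp(-z1[k]^2 / fourDvt) -
                   z2[k] * exp(-z2[k]^2 / fourDvt)
  }
  att <- exp(-props$mua * p$v * time_ps)
  if (integrated) {
    out <- att / (2 * sqrt(4 * pi * p$D * p$v) * time_ps^1.5) * ssum
  } else {
    out <- att * exp(-rho^2 / fourDvt) /
      (2 * (4 * pi * p$D * p$v)^1.5 * time_ps^2.5) * ssum
  }
  pmax(out, 0)
}

#' Time-resolved slab transmittance (diffusion approximation)
#'
#' Transmittance of a picosecond impulse through a homogeneous turbid slab,
#' computed with the diffusion approximation and extrapolated-boundary
#' conditions via a truncated image-source series. Source and detector face
#' each other on opposite slab faces (optionally offset laterally by `rho`).
#'
#' @param props [optical_properties()].
#' @param geom [slab_geometry()].
#' @param time_ps Strictly increasing positive time grid, ps.
#' @param rho Lateral source-detector offset, cm (default 0: line of sight).
#' @param m_max Image-source pairs on each side (default 10; contributions
#'   decay super-exponentially).
#' @param integrated If `TRUE`, integrate over the entire exit face instead of
#'   evaluating at a point detector.
#' @return A [trcurve()] in arbitrary units.
#' @examples
#' tg <- time_grid(25, 200)
#' T0 <- slab_transmittance(optical_properties(0.05, 10), slab_geometry(4), tg)
#' @export
slab_transmittance <- function(props, geom, time_ps, rho = 0, m_max = 10,
                               integrated = FALSE) {
  stopifnot(inherits(props, "optical_properties"), inherits(geom, "slab_geometry"))
  .check_time_grid(time_ps)
  y <- .slab_transmittance_raw(rho, props, geom, time_ps, zs = NULL,
                               m_max = m_max, integrated = integrated)
  trcurve(time_ps, y, props$wavelength)
}

#' Mean partial pathlength in a spherical inclusion
#'
#' Time-resolved mean pathlength `l(t)` traveled inside a spherical region by
#' photons detected at time `t`, computed as the first-order Born sensitivity:
#' the time convolution of the source-to-voxel fluence and voxel-to-detector
#' transmittance Green's functions, integrated over the sphere volume by
#' Gauss-Legendre quadrature and normalized by the unperturbed transmittance.
#'
#' The kernel satisfies `0 <= l(t) <= v t` and enters the time-resolved
#' modified Beer-Lambert law `T(t) = T0(t) exp(-delta_mua * l(t))`.
#'
#' @param props,geom Background medium and slab geometry.
#' @param pert [spherical_perturbation()] strictly inside the slab. A `NULL`
#'   center places the sphere on the line of sight at mid-slab.
#' @param time_ps Uniform time grid starting at its own bin width (see
#'   [time_grid()]); required by the discrete convolution.
#' @param nq Gauss-Legendre orders `c(radial, polar, azimuthal)`; default
#'   `c(16, 16, 16)`.
#' @param m_max Image-source pairs.
#' @return Object of class `pathlength_kernel`: list with `time_ps` and `l_cm`.
#' @export
partial_pathlength <- function(props, geom, pert, time_ps,
                               nq = c(16, 16, 16), m_max = 10) {
  stopifnot(inherits(pert, "spherical_perturbation"))
  .check_time_grid(time_ps)
  dt <- time_ps[2] - time_ps[1]
  if (abs(time_ps[1] - dt) > 1e-6 * dt)
    stop("time grid must start at its bin width (use time_grid())")
  ctr <- .check_pert_inside(pert, geom)
  nt <- length(time_ps)

  # quadrature nodes over the sphere in spherical coordinates
  gr <- .gauss_legendre(nq[1], 0, pert$radius)
  gu <- .gauss_legendre(nq[2], -1, 1)
  gp <- .gauss_legendre(nq[3], 0, 2 * pi)
  nodes <- expand.grid(ir = seq_len(nq[1]), iu = seq_len(nq[2]),
                       ip = seq_len(nq[3]))
  r <- gr$x[nodes$ir]; u <- gu$x[nodes$iu]; ph <- gp$x[nodes$ip]
  w <- gr$w[nodes$ir] * gu$w[nodes$iu] * gp$w[nodes$ip] * r^2
  st <- sqrt(pmax(0, 1 - u^2))
  px <- ctr[1] + r * st * cos(ph)
  py <- ctr[2] + r * st * sin(ph)
  pz <- ctr[3] + r * u

  sx <- geom$source_xy[1]; sy <- geom$source_xy[2]
  rho_s <- sqrt((px - sx)^2 + (py - sy)^2)
  rho_d <- rho_s                         # detector shares the source (x, y)

  # FFT-based accumulation of sum_q w_q (phi_q (*) Tg_q)(t)
  nfft <- 2^ceiling(log2(2 * nt))
  acc <- complex(nfft)
  chunk <- 1024L
  nqtot <- length(w)
  for (i0 in seq(1L, nqtot, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nqtot)
    A <- matrix(0, nfft, length(idx))
    B <- matrix(0, nfft, length(idx))
    for (j in seq_along(idx)) {
      q <- idx[j]
      A[1:nt, j] <- .slab_fluence(rho_s[q], pz[q], props, geom, time_ps,
                                  m_max = m_max)
      B[1:nt, j] <- .slab_transmittance_raw(rho_d[q], props, geom, time_ps,
                                            zs = pz[q], m_max = m_max)
    }
    fa <- stats::mvfft(A)
    fb <- stats::mvfft(B)
    acc <- acc + (fa * fb) %*% w[idx]
  }
  conv <- Re(stats::fft(acc, inverse = TRUE)) / nfft * dt
  # conv index k corresponds to time (k + 1) * dt on a grid t_k = k * dt
  num <- c(0, conv[seq_len(nt - 1L)])
  T0 <- .slab_transmittance_raw(0, props, geom, time_ps, m_max = m_max)
  # the ratio is meaningless where the unperturbed signal has underflowed
  l <- ifelse(T0 > 1e-14 * max(T0), num / T0, 0)
  v <- light_speed(geom$refractive_index)
  l <- pmin(pmax(l, 0), v * time_ps)
  structure(list(time_ps = time_ps, l_cm = l), class = "pathlength_kernel")
}

#' @export
print.pathlength_kernel <- function(x, ...) {
  cat(sprintf("Pathlength kernel: %d bins, max l = %.3g cm\n",
              length(x$time_ps), max(x$l_cm)))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch
.gauss_legendre <- function(n, a, b) {
  if (n == 1L) return(list(x = (a + b) / 2, w = b - a))
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (b - a) / 2 * x[ord] + (a + b) / 2, w = (b - a) / 2 * w[ord])
}

#' Effective pathlength kernel under the instrument response
#'
#' Measured curves are blurred by the instrument response function, so the
#' pathlength kernel seen by a time gate on the measured axis is the
#' count-weighted blur of `l(t)`:
#' `l_eff(t) = (T0 * irf (x) l T0)(t) / (T0 (x) irf)(t)`. Without an IRF this
#' reduces to [partial_pathlength()].
#'
#' @inheritParams partial_pathlength
#' @param irf An `instrument_response` on the same grid, or `NULL`.
#' @return A `pathlength_kernel` on the measured time axis.
#' @export
effective_pathlength <- function(props, geom, pert, time_ps, irf = NULL,
                                 nq = c(16, 16, 16), m_max = 10) {
  kern <- partial_pathlength(props, geom, pert, time_ps, nq = nq,
                             m_max = m_max)
  if (is.null(irf)) return(kern)
  T0 <- slab_transmittance(props, geom, time_ps, m_max = m_max)
  num <- convolve_irf(trcurve(time_ps, T0$counts * kern$l_cm), irf)$counts
  den <- convolve_irf(T0, irf)$counts
  l <- ifelse(den > 1e-14 * max(den), num / den, 0)
  v <- light_speed(geom$refractive_index)
  structure(list(time_ps = time_ps, l_cm = pmin(pmax(l, 0), v * time_ps)),
            class = "pathlength_kernel")
}

#' Perturbed transmittance via the time-resolved modified Beer-Lambert law
#'
#' `T(t) = T0(t) exp(-delta_mua * l(t))`: the unperturbed slab transmittance
#' attenuated by the absorption contrast of a spherical inclusion acting over
#' the mean partial pathlength `l(t)`.
#'
#' @inheritParams partial_pathlength
#' @param kernel Optional precomputed `pathlength_kernel` on the same grid
#'   (avoids recomputing the Born integral).
#' @return A [trcurve()].
#' @export
perturbed_transmittance <- function(props, geom, pert, time_ps,
                                    nq = c(16, 16, 16), m_max = 10,
                                    kernel = NULL) {
  T0 <- slab_transmittance(props, geom, time_ps, m_max = m_max)
  if (identical(pert$delta_mua, 0)) return(T0)
  if (is.null(kernel))
    kernel <- partial_pathlength(props, geom, pert, time_ps, nq, m_max)
  stopifnot(length(kernel$l_cm) == length(time_ps))
  trcurve(time_ps, T0$counts * exp(-pert$delta_mua * kernel$l_cm),
          props$wavelength)
}
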