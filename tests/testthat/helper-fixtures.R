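# shared fixtures and independent oracles used across test files

std_props <- function(mua = 0.05, musp = 10) optical_properties(mua, musp)
std_geom <- function() slab_geometry(4)

# robust peak time / FWHM estimates for noisy histograms: quadratic fit of
# log counts around the mode, FWHM by linear interpolation at half maximum
peak_fwhm <- function(y, t) {
  i <- which.max(y)
  win <- which(y >= 0.7 * y[i] & y > 0)
  fitc <- coef(lm(log(y[win]) ~ t[win] + I(t[win]^2)))
  tp <- as.numeric(-fitc[2] / (2 * fitc[3]))
  ymax <- exp(fitc[1] + fitc[2] * tp + fitc[3] * tp^2)
  half <- ymax / 2
  above <- which(y >= half)
  lo <- min(above); hi <- max(above)
  tl <- if (lo > 1) approx(y[c(lo - 1, lo)], t[c(lo - 1, lo)], xout = half)$y
        else t[lo]
  th <- if (hi < length(y)) approx(y[c(hi, hi + 1)], t[c(hi, hi + 1)],
                                   xout = half)$y else t[hi]
  c(peak = tp, fwhm = th - tl)
}

# independent continuous-wave slab transmittance (closed-form dipole series)
# for the time-integral cross-check
cw_transmittance <- function(mua, musp, s, n = 1.4, m_max = 10) {
  D <- 1 / (3 * musp)
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  ze <- 2 * A * D
  z0 <- 1 / musp
  mueff <- sqrt(mua / D)
  m <- seq(-m_max, m_max)
  z1 <- s * (1 - 2 * m) - 4 * m * ze - z0
  z2 <- s * (1 - 2 * m) - (4 * m - 2) * ze + z0
  flux <- function(z) {
    r <- abs(z)
    sign(z) * (mueff + 1 / r) * exp(-mueff * r) / (4 * pi * r^2) * abs(z)
  }
  sum(flux(z1)) - sum(flux(z2))
}

# flood-fill connected-components oracle (4-connectivity) for mask tests
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1) p - 1L, if (r < nrow(mask)) p + 1L,
              if (cc > 1) p - nrow(mask), if (cc < ncol(mask)) p + nrow(mask))
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  lab
}

# small scan fixture: constant-count curves with a spatial amplitude pattern
toy_scan <- function(pattern, nt = 40, base = 100) {
  ny <- nrow(pattern); nx <- ncol(pattern)
  tg <- time_grid(25, nt)
  shape <- dnorm(seq_len(nt), nt / 3, nt / 8)
  shape <- shape / sum(shape)
  arr <- array(0, c(ny, nx, nt))
  for (i in seq_len(ny)) for (j in seq_len(nx))
    arr[i, j, ] <- base * pattern[i, j] * shape
  scan_image(setNames(list(arr), "785"), tg)
}

# compact phantom spec for fast mapping tests (single-purpose, low counts)
small_phantom <- function(lesion = TRUE, counts = 1e5, nx = 21, ny = 21) {
  les <- if (lesion)
    list(center_mm = c(7, 7), diameter_mm = 10,
         delta_c = c(Hb = 5, HbO2 = 10, water = 50, lipid = -30,
                     collagen = 30))
  else NULL
  phantom_spec(nx_mm = nx, ny_mm = ny, border_mm = 2, lesion = les,
               counts_per_pixel = counts, dt_ps = 25, nt = 220)
}
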