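test_that("constructors reject non-physical inputs", {
  expect_error(optical_properties(-0.1, 10), "mua")
  expect_error(optical_properties(0.05, 0), "musp")
  expect_error(slab_geometry(0), "thickness")
  expect_error(slab_geometry(4, 0.9), "refractive_index")
  expect_error(spherical_perturbation(0), "radius")
  expect_error(trcurve(c(1, 2, 3), c(1, -1, 1)), "non-negative")
})

test_that("time-domain Beer-Lambert scaling of the slab Green's function is exact", {
  tg <- time_grid(10, 600)
  geom <- std_geom()
  v <- light_speed(geom$refractive_index)
  T0 <- slab_transmittance(std_props(0.05, 10), geom, tg)
  for (delta in c(0.01, 0.05, -0.02)) {
    Td <- slab_transmittance(optical_properties(0.05 + delta, 10), geom, tg)
    expect_lt(max(abs(Td$counts / (T0$counts * exp(-delta * v * tg)) - 1),
                  na.rm = TRUE), 1e-10)
  }
})

test_that("transmittance is non-negative and vanishes at both time extremes", {
  tg <- time_grid(5, 3000)
  Tt <- slab_transmittance(std_props(), std_geom(), tg)
  expect_true(all(Tt$counts >= 0))
  expect_lt(Tt$counts[1], 1e-30)
  expect_lt(Tt$counts[length(tg)] / max(Tt$counts), 1e-6)
})

test_that("time integral matches the independent CW closed form within 0.1%", {
  for (pars in list(c(0.05, 10), c(0.1, 8), c(0.02, 15))) {
    tg <- time_grid(5, 4000)
    Tt <- slab_transmittance(optical_properties(pars[1], pars[2]),
                             std_geom(), tg)
    ti <- sum(Tt$counts) * 5
    cw <- cw_transmittance(pars[1], pars[2], 4)
    expect_lt(abs(ti / cw - 1), 1e-3)
  }
})

test_that("swapping source and detector leaves the transmittance unchanged", {
  # homogeneous slab: exchanging the faces relabels the image construction;
  # the mirrored sphere position probes the same reciprocity for the kernel
  tg <- time_grid(20, 300)
  props <- std_props(0.06, 9)
  geom <- std_geom()
  kA <- partial_pathlength(props, geom,
                           spherical_perturbation(0.5, center = c(0, 0, 1.5)),
                           tg, nq = c(8, 8, 8))
  kB <- partial_pathlength(props, geom,
                           spherical_perturbation(0.5, center = c(0, 0, 2.5)),
                           tg, nq = c(8, 8, 8))
  sel <- tg > 500
  expect_lt(max(abs(kA$l_cm[sel] / kB$l_cm[sel] - 1)), 0.02)
})

test_that("Born pathlength kernel obeys its limits", {
  tg <- time_grid(25, 200)
  props <- std_props(0.07, 10)
  geom <- std_geom()
  v <- light_speed(geom$refractive_index)
  # vanishing volume
  k0 <- partial_pathlength(props, geom, spherical_perturbation(1e-3), tg,
                           nq = c(4, 4, 4))
  expect_lt(max(k0$l_cm), 1e-4)
  # bounded by the total pathlength
  k <- partial_pathlength(props, geom, spherical_perturbation(0.8), tg,
                          nq = c(8, 8, 8))
  expect_true(all(k$l_cm <= v * tg + 1e-12))
  expect_true(all(k$l_cm >= 0))
  # monotone growth of the late-photon pathlength for a mid-slab sphere
  expect_gt(k$l_cm[180], k$l_cm[60])
  # sphere touching a face is rejected
  expect_error(partial_pathlength(props, geom,
                                  spherical_perturbation(0.5,
                                                         center = c(0, 0, 0.3)),
                                  tg), "inside the slab")
})

test_that("perturbed transmittance follows the modified Beer-Lambert law", {
  tg <- time_grid(25, 200)
  props <- std_props(0.07, 10)
  geom <- std_geom()
  T0 <- slab_transmittance(props, geom, tg)
  pert0 <- spherical_perturbation(0.5, delta_mua = 0)
  expect_equal(perturbed_transmittance(props, geom, pert0, tg)$counts,
               T0$counts)
  k <- partial_pathlength(props, geom, spherical_perturbation(0.5), tg,
                          nq = c(8, 8, 8))
  neg <- spherical_perturbation(0.5, delta_mua = -0.05)
  Tn <- perturbed_transmittance(props, geom, neg, tg, kernel = k)
  expect_true(all(Tn$counts >= T0$counts))
  pos <- spherical_perturbation(0.5, delta_mua = 0.1)
  Tp <- perturbed_transmittance(props, geom, pos, tg, kernel = k)
  expect_equal(Tp$counts, T0$counts * exp(-0.1 * k$l_cm))
})

test_that("Monte-Carlo oracle reproduces the ballistic limit", {
  # scattering-free, absorption-free, index-matched slab: every photon
  # arrives after exactly one slab crossing, t = s n / c
  geom <- std_geom()
  v <- light_speed(geom$refractive_index)
  tg <- time_grid(5, 100)
  mc <- monte_carlo_oracle(optical_properties(0, 1e-6), geom, NULL,
                           n_photons = 2000, seed = 3, time_ps = tg,
                           det_radius = 0.1, n_out = geom$refractive_index)
  t_ball <- geom$thickness / v
  hit <- which(mc$curve$counts > 0)
  expect_equal(mc$n_detected, 2000)
  expect_true(all(abs(tg[hit] - t_ball) <= 5))
})

test_that("Monte-Carlo standard error scales with the photon budget", {
  geom <- slab_geometry(2)
  props <- std_props(0.05, 10)
  tg <- time_grid(25, 200)
  tot <- function(n, seed)
    sum(monte_carlo_oracle(props, geom, NULL, n_photons = n, seed = seed,
                           time_ps = tg, det_radius = Inf)$curve$counts) / n
  a <- vapply(1:8, function(s) tot(3e3, s), numeric(1))
  b <- vapply(1:8, function(s) tot(12e3, 100 + s), numeric(1))
  # quadrupling the photons should roughly halve the relative SE
  ratio <- sd(a) / sd(b)
  expect_gt(ratio, 1.1)
  expect_lt(ratio, 4)
})

test_that("effective pathlength reduces to the bare kernel without an IRF", {
  tg <- time_grid(25, 160)
  props <- std_props()
  geom <- std_geom()
  pert <- spherical_perturbation(0.5)
  k1 <- partial_pathlength(props, geom, pert, tg, nq = c(6, 6, 6))
  k2 <- effective_pathlength(props, geom, pert, tg, irf = NULL,
                             nq = c(6, 6, 6))
  expect_equal(k1$l_cm, k2$l_cm)
  # IRF blur delays the apparent kernel (late gates see longer paths)
  irf <- gaussian_irf(tg, 600)
  k3 <- effective_pathlength(props, geom, pert, tg, irf = irf,
                             nq = c(6, 6, 6))
  sel <- 60:140
  expect_true(mean(k3$l_cm[sel] < k1$l_cm[sel]) > 0.9)
})
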