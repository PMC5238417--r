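test_that("IRF convolution preserves area and handles the identity kernel", {
  tg <- time_grid(25, 320)
  # strongly absorbed thin-slab pulse: compact support well inside the grid,
  # so no counts can leak past the grid end after convolution
  Tt <- slab_transmittance(optical_properties(0.3, 10), slab_geometry(2), tg)
  # single-bin unit spike leaves the curve unchanged
  expect_equal(convolve_irf(Tt, c(1, rep(0, 20)))$counts, Tt$counts)
  irf <- gaussian_irf(tg, 460)
  Tc <- convolve_irf(Tt, irf)
  expect_lt(abs(sum(Tc$counts) / sum(Tt$counts) - 1), 1e-10)
})

test_that("convolution shifts the mean time by the IRF mean", {
  tg <- time_grid(25, 400)
  Tt <- slab_transmittance(std_props(0.1, 10), slab_geometry(3), tg)
  irf <- gaussian_irf(tg, 460)
  Tc <- convolve_irf(Tt, irf)
  mt <- function(y) sum(y * tg) / sum(y)
  irf_mean <- mt(irf$curve$counts)
  # first moments add under convolution (up to the grid origin at one bin)
  expect_lt(abs((mt(Tc$counts) - mt(Tt$counts)) - (irf_mean - tg[1])), 2)
})

test_that("Poisson noise has the right mean, variance and determinism", {
  tg <- time_grid(25, 60)
  base <- trcurve(tg, dnorm(seq_len(60), 25, 8))
  n_rep <- 600
  reps <- vapply(seq_len(n_rep),
                 function(s) add_poisson_noise(base, 5e4, seed = s)$counts,
                 numeric(60))
  lam <- base$counts / sum(base$counts) * 5e4
  mu_hat <- rowMeans(reps)
  se <- sqrt(lam / n_rep)
  sel <- lam > 5
  expect_true(all(abs(mu_hat[sel] - lam[sel]) < 4 * se[sel]))
  v_hat <- apply(reps, 1, var)
  expect_lt(abs(median((v_hat / lam)[sel]) - 1), 0.15)
  expect_identical(add_poisson_noise(base, 1e4, seed = 42)$counts,
                   add_poisson_noise(base, 1e4, seed = 42)$counts)
})

test_that("equal-count windows match the worked partition and symmetry cases", {
  # cumulative boundary after bin 3 (cumsum 10 of 20), exactly equal halves
  w <- equal_count_windows(c(5, 1, 4, 2, 8), K = 2)
  expect_equal(w$boundaries[1], 3)
  expect_equal(w$totals, c(10, 10))
  # uniform curve, bins divisible by K: equal-width windows
  wu <- equal_count_windows(rep(7, 40), K = 10)
  expect_equal(diff(wu$boundaries), rep(4, 9))
  expect_equal(wu$totals, rep(28, 10))
  expect_error(equal_count_windows(c(1, 1, 1), K = 5), "at least K")
})

test_that("every window carries total/K counts on arbitrary curves", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(30:300, 1)
    counts <- rpois(n, exp(rnorm(n, 3, 1.5)))
    if (sum(counts) < 10) next
    w <- equal_count_windows(counts, K = 10)
    expect_lt(max(abs(w$totals - sum(counts) / 10)), 1)
    expect_equal(sum(w$totals), sum(counts))
    expect_true(all(diff(w$boundaries) >= 0))
    # fractional bin memberships partition each bin exactly once
    expect_equal(rowSums(w$weights), rep(1, n))
  }
})

test_that("reference gating applied to a second curve preserves contrast", {
  tg <- time_grid(25, 200)
  T0 <- slab_transmittance(std_props(0.06, 10), std_geom(), tg)
  w <- equal_count_windows(T0, 10)
  att <- exp(-0.05 * seq_along(tg) / 40)
  Tp <- T0$counts * att
  cw <- window_counts(Tp, w)
  expect_equal(length(cw), 10)
  # later windows must show stronger attenuation than early ones
  expect_lt(cw[8] / w$totals[8], cw[2] / w$totals[2])
})

test_that("homogeneous fit recovers the generating optical properties", {
  tg <- time_grid(25, 280)
  geom <- std_geom()
  irf <- gaussian_irf(tg, 600)
  truth <- optical_properties(0.08, 12)
  clean <- convolve_irf(slab_transmittance(truth, geom, tg), irf)
  # inverse-crime round trip: noise-free self-generated curve
  fit0 <- fit_homogeneous(trcurve(tg, clean$counts * 1e6 / sum(clean$counts)),
                          irf, geom, start = c(0.05, 9))
  expect_true(fit0$converged)
  expect_lt(abs(fit0$props$mua / truth$mua - 1), 1e-3)
  expect_lt(abs(fit0$props$musp / truth$musp - 1), 1e-3)
  # photon noise at 1e6 counts
  errs <- sapply(1:4, function(s) {
    noisy <- add_poisson_noise(clean, 1e6, seed = s)
    fit <- fit_homogeneous(noisy, irf, geom, start = c(0.05, 9))
    expect_true(fit$converged)
    c(abs(fit$props$mua / truth$mua - 1), abs(fit$props$musp / truth$musp - 1))
  })
  expect_lt(max(errs[1, ]), 0.02)
  expect_lt(max(errs[2, ]), 0.05)
})

test_that("a curve of pure IRF is flagged instead of silently fitted", {
  tg <- time_grid(25, 280)
  irf <- gaussian_irf(tg, 600)
  pure <- trcurve(tg, irf$curve$counts * 1e6)
  fit <- expect_no_error(fit_homogeneous(pure, irf, std_geom(),
                                         start = c(0.05, 9)))
  expect_false(fit$converged)
})

test_that("window-level absorption contrast inversion is exact", {
  expect_equal(estimate_delta_mua(1, 1, 1), 0)
  expect_equal(estimate_delta_mua(exp(-1), 1, 1), 1)
  expect_error(estimate_delta_mua(0, 1, 1), "positive")
  tg <- time_grid(25, 240)
  props <- std_props(0.07, 10)
  geom <- std_geom()
  pert <- spherical_perturbation(0.5, delta_mua = 0.08)
  k <- partial_pathlength(props, geom, pert, tg, nq = c(8, 8, 8))
  T0 <- slab_transmittance(props, geom, tg)
  Tp <- perturbed_transmittance(props, geom, pert, tg, kernel = k)
  w <- equal_count_windows(T0, 10)
  Tw8 <- sum(w$weights[, 8] * Tp$counts)
  # exact root solve against the same kernel recovers the planted contrast
  est <- estimate_delta_mua(Tw8, w$weights[, 8] * T0$counts, k$l_cm)
  expect_lt(abs(est - 0.08), 1e-10)
  # the scalar closed form with the count-weighted pathlength is first-order
  lbar <- window_pathlength(k, w, T0$counts, 8)
  est1 <- estimate_delta_mua(Tw8, sum(w$weights[, 8] * T0$counts), lbar)
  expect_lt(abs(est1 - 0.08), 0.005)
})

test_that("estimated contrast bias shrinks as counts grow", {
  tg <- time_grid(25, 240)
  props <- std_props(0.07, 10)
  geom <- std_geom()
  pert <- spherical_perturbation(0.5, delta_mua = 0.08)
  k <- partial_pathlength(props, geom, pert, tg, nq = c(8, 8, 8))
  T0m <- slab_transmittance(props, geom, tg)
  Tpm <- perturbed_transmittance(props, geom, pert, tg, kernel = k)
  est_at <- function(counts, seed) {
    T0n <- add_poisson_noise(T0m, counts, seed = seed)
    Tpn <- add_poisson_noise(Tpm, counts * sum(Tpm$counts) / sum(T0m$counts),
                             seed = seed + 1000)
    w <- equal_count_windows(T0n, 10)
    estimate_delta_mua(sum(w$weights[, 8] * Tpn$counts),
                       w$weights[, 8] * T0n$counts, k$l_cm)
  }
  spread <- sapply(c(1e5, 1e6, 1e7), function(cc) {
    ests <- vapply(1:8, function(s) est_at(cc, s), numeric(1))
    c(abs(mean(ests) - 0.08), sd(ests))
  })
  # noise (and with it the error) decreases with the photon budget
  expect_gt(spread[2, 1], spread[2, 3])
  expect_lt(spread[1, 3], 0.002)
})

test_that("window-8 pathlength exceeds window-2 pathlength for a mid-slab sphere", {
  tg <- time_grid(25, 240)
  props <- std_props()
  geom <- std_geom()
  k <- partial_pathlength(props, geom, spherical_perturbation(0.5), tg,
                          nq = c(8, 8, 8))
  T0 <- slab_transmittance(props, geom, tg)
  w <- equal_count_windows(T0, 10)
  expect_gt(window_pathlength(k, w, T0$counts, 8),
            window_pathlength(k, w, T0$counts, 2))
})
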