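test_that("ROI side and equivalent sphere follow the diameter rules", {
  expect_equal(roi_for_diameter(18), 9)
  expect_equal(roi_for_diameter(16), 9)
  expect_equal(roi_for_diameter(15), 5)   # strict inequality
  expect_equal(roi_for_diameter(10), 5)
  expect_error(roi_for_diameter(9.9), ">= 10 mm")
  expect_equal(equivalent_sphere(10), 0.5)
  expect_equal(equivalent_sphere(45), 2.25)
  expect_error(equivalent_sphere(0), "> 0")
})

test_that("breast mask thresholds counts and keeps the largest component", {
  # uniform phantom: full-grid mask
  p1 <- matrix(1, 8, 8)
  expect_true(all(breast_mask(toy_scan(p1), 1)))
  # zero-count border excluded exactly
  p2 <- matrix(0, 10, 10); p2[3:8, 3:8] <- 1
  m2 <- breast_mask(toy_scan(p2), 1)
  expect_equal(m2, p2 > 0)
  # two disconnected blobs: only the larger survives; flood-fill oracle agrees
  p3 <- matrix(0, 12, 12); p3[2:7, 2:7] <- 1; p3[10:11, 10:11] <- 1
  m3 <- breast_mask(toy_scan(p3), 1)
  lab <- flood_components(p3 > 0)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  expect_equal(m3, lab == keep)
  expect_error(breast_mask(toy_scan(p1), 0), "> 0")
})

test_that("reference region excludes boundaries and bright structures", {
  set.seed(31)
  nt <- 60
  tg <- time_grid(25, nt)
  shape <- dnorm(seq_len(nt), 20, 6); shape <- shape / sum(shape)
  mk <- function(vessel) {
    arr <- array(rpois(20 * 20 * nt, 1e3 * rep(shape, each = 400)),
                 c(20, 20, nt))
    if (vessel) {
      for (k in seq_len(nt))
        arr[10, , k] <- rpois(20, 3e3 * shape[k])
    }
    scan_image(setNames(list(arr), "785"), tg)
  }
  scan_v <- mk(TRUE)
  scan_h <- mk(FALSE)
  mask <- matrix(TRUE, 20, 20)
  ref_v <- reference_curve(scan_v, mask, erosion_mm = 3)
  ref_h <- reference_curve(scan_h, mask, erosion_mm = 3)
  # the bright line is trimmed out of the reference region entirely
  expect_true(all(!ref_v$region[10, ]))
  # and the reference curve matches the vessel-free phantom within noise
  expect_lt(abs(sum(ref_v$T0[["785"]]$counts) /
                sum(ref_h$T0[["785"]]$counts) - 1), 0.02)
  # homogeneous case: per-pixel mean close to a single pixel's curve
  expect_lt(abs(sum(ref_h$T0[["785"]]$counts) / sum(scan_h$curves[["785"]][5, 5, ]) - 1),
            0.2)
  expect_error(reference_curve(scan_h, mask, erosion_mm = 40), "empty")
})

test_that("null phantom yields maps indistinguishable from zero", {
  ph <- generate_phantom_scan(small_phantom(lesion = FALSE), seed = 9)
  scan <- ph$scan
  expect_equal(unname(ph$truth$delta_c), rep(0, 5))
  mask <- breast_mask(scan, 1e4)
  ref <- suppressWarnings(reference_curve(scan, mask, erosion_mm = 3))
  maps <- compute_maps(scan, mask, ref, ph$spec$props_list, std_geom(),
                       ph$spec$spectra, irf = gaussian_irf(scan$time_ps,
                                                           ph$spec$irf_fwhm_ps))
  for (wl in names(maps$delta_mua)) {
    m <- maps$delta_mua[[wl]]
    vals <- m[!is.na(m)]
    # per-pixel noise floor for a 1/10-count window at this budget
    expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 1e-4)
    expect_lt(sd(vals), 0.05)
  }
  # tHb additivity is exact
  expect_equal(maps$delta_c$tHb, maps$delta_c$Hb + maps$delta_c$HbO2,
               tolerance = 1e-12)
  # masked-out pixels never acquire values
  expect_true(all(is.na(maps$delta_c$collagen[!mask])))
})

test_that("a planted lesion localizes in the absorption maps", {
  ph <- generate_phantom_scan(small_phantom(lesion = TRUE, counts = 3e5),
                              seed = 10)
  scan <- ph$scan
  mask <- breast_mask(scan, 1e4)
  ref <- suppressWarnings(reference_curve(scan, mask, erosion_mm = 3))
  maps <- compute_maps(scan, mask, ref, ph$spec$props_list, std_geom(),
                       ph$spec$spectra,
                       irf = gaussian_irf(scan$time_ps, ph$spec$irf_fwhm_ps))
  # smooth lightly before locating the peak (single-pixel windows are noisy)
  sm <- function(m) {
    m[is.na(m)] <- 0
    k <- matrix(1 / 9, 3, 3)
    out <- m
    for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1))
      out[i, j] <- sum(m[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
    out
  }
  centroid <- function(m) {
    top <- m >= 0.5 * max(m)
    c(sum(row(m)[top] * m[top]), sum(col(m)[top] * m[top])) / sum(m[top])
  }
  ctr_px <- ph$truth$center_mm + 1     # mm -> 1-based pixel index
  pk <- centroid(sm(maps$delta_mua[["635"]]))
  expect_lt(sqrt(sum((pk - c(ctr_px[2], ctr_px[1]))^2)), 2.5)
  # the collagen map also localizes the lesion, more loosely: at this photon
  # budget its per-pixel noise (amplified by the near-collinear lipid and
  # collagen spectra) is comparable to the signal
  pkc <- centroid(sm(maps$delta_c$collagen))
  expect_lt(sqrt(sum((pkc - c(ctr_px[2], ctr_px[1]))^2)), 5)
})

test_that("map serialization writes matrices and a range sidecar", {
  ph <- generate_phantom_scan(small_phantom(lesion = FALSE, counts = 1e4,
                                            nx = 15, ny = 15), seed = 2)
  mask <- breast_mask(ph$scan, 1e3)
  ref <- suppressWarnings(reference_curve(ph$scan, mask, erosion_mm = 3))
  maps <- compute_maps(ph$scan, mask, ref, ph$spec$props_list, std_geom(),
                       ph$spec$spectra)
  dir <- tempfile()
  write_maps(maps, dir)
  expect_true(file.exists(file.path(dir, "delta_c_collagen.tsv")))
  ranges <- jsonlite::read_json(file.path(dir, "map_ranges.json"))
  expect_true("delta_mua_635" %in% names(ranges))
  got <- as.matrix(read.table(file.path(dir, "delta_c_tHb.tsv")))
  expect_equal(unname(got[!is.na(maps$delta_c$tHb)]),
               unname(maps$delta_c$tHb[!is.na(maps$delta_c$tHb)]),
               tolerance = 1e-12)
})
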