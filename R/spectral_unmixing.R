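# Beer-law spectral unmixing: multi-wavelength absorption differences into
# concentration differences of the five main breast constituents.

.CONSTITUENTS <- c("Hb", "HbO2", "water", "lipid", "collagen")

#' Load an extinction-spectra table
#'
#' Reads a CSV with a `wavelength_nm` column and one column per constituent
#' (`Hb`, `HbO2`, `water`, `lipid`, `collagen`), sorts rows by wavelength, and
#' validates non-negativity and full column rank. Units: cm^-1/uM for
#' hemoglobins, cm^-1/(mg/cm^3) for water, lipid and collagen.
#'
#' The packaged default (`extinction_defaults_synthetic.csv`) is a synthetic,
#' literature-shaped table: it mimics the qualitative spectral features of the
#' constituents but is not a measured reference, and no quantitative result in
#' this package depends on its absolute values.
#'
#' @param path CSV path, or `NULL` for the packaged default.
#' @param wavelengths Required wavelength set (default [default_wavelengths()]);
#'   set to `NULL` to accept any.
#' @return An `extinction_spectra` object: numeric matrix (rows = wavelengths,
#'   columns = the 5 constituents) with attributes `wavelengths` and
#'   `condition_number`.
#' @export
load_extinction_table <- function(path = NULL,
                                  wavelengths = default_wavelengths()) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_defaults_synthetic.csv",
                        package = "optimammo", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"wavelength_nm" %in% names(tab)) stop("missing wavelength_nm column")
  missing_cols <- setdiff(.CONSTITUENTS, names(tab))
  if (length(missing_cols))
    stop("missing constituent columns: ", paste(missing_cols, collapse = ", "))
  tab <- tab[order(tab$wavelength_nm), , drop = FALSE]
  if (!is.null(wavelengths)) {
    if (!setequal(tab$wavelength_nm, wavelengths))
      stop("table wavelengths do not match the configured set")
  }
  eps <- as.matrix(tab[, .CONSTITUENTS])
  rownames(eps) <- tab$wavelength_nm
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("extinction coefficients must be finite and non-negative")
  sv <- svd(eps)$d
  if (sv[length(sv)] <= 1e-12 * sv[1])
    stop("extinction matrix is rank deficient")
  kappa <- sv[1] / sv[length(sv)]
  message(sprintf("extinction table: %d wavelengths x %d constituents, condition number %.3g",
                  nrow(eps), ncol(eps), kappa))
  structure(eps, wavelengths = tab$wavelength_nm, condition_number = kappa,
            class = c("extinction_spectra", "matrix"))
}

#' Unmix absorption differences into constituent concentration differences
#'
#' Solves the Beer-law system `delta_mua(lambda) = sum_i eps_i(lambda) dC_i`
#' by unconstrained linear least squares (7 equations, 5 unknowns). The
#' concentration differences are signed, so no non-negativity constraint is
#' applied by default; set `nonneg = TRUE` for absolute-composition problems.
#'
#' @param delta_mua Numeric vector of absorption differences (cm^-1), one per
#'   table wavelength (sorted ascending).
#' @param spectra An `extinction_spectra` matrix.
#' @param nonneg Constrain solutions to be non-negative (Lawson-Hanson active
#'   set); not the pathway for signed differences.
#' @return List with `delta_c` (named vector: Hb, HbO2 in uM; water, lipid,
#'   collagen in mg/cm^3), `residual` (per-wavelength), `residual_norm`.
#' @examples
#' eps <- load_extinction_table()
#' truth <- c(Hb = 5, HbO2 = 10, water = 50, lipid = -30, collagen = 30)
#' fit <- unmix(as.numeric(eps %*% truth), eps)
#' all.equal(fit$delta_c, truth)
#' @export
unmix <- function(delta_mua, spectra, nonneg = FALSE) {
  stopifnot(inherits(spectra, "extinction_spectra"))
  delta_mua <- as.numeric(delta_mua)
  if (length(delta_mua) != nrow(spectra))
    stop("delta_mua must have one value per table wavelength")
  if (any(!is.finite(delta_mua))) stop("delta_mua must be finite")
  E <- unclass(spectra)
  if (nonneg) {
    dc <- .nnls(E, delta_mua)
  } else {
    dc <- qr.solve(qr(E), delta_mua)
  }
  names(dc) <- colnames(E)
  res <- delta_mua - as.numeric(E %*% dc)
  list(delta_c = dc, residual = res, residual_norm = sqrt(sum(res^2)))
}

# Lawson-Hanson non-negative least squares
.nnls <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  P <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!P) && max(w[!P]) > tol && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.solve(qr(A[, P, drop = FALSE]), b)
      if (all(s[P] > tol)) break
      alpha <- min(x[P] / (x[P] - s[P]), na.rm = TRUE)
      x <- x + alpha * (s - x)
      P[x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Derived hemoglobin quantities
#'
#' Total hemoglobin `tHb = Hb + HbO2` is additive and valid for both absolute
#' concentrations and signed differences. Oxygen saturation
#' `SO2 = HbO2 / (Hb + HbO2)` is only defined for absolute (non-negative)
#' concentrations and is refused on signed differences.
#'
#' @param hb,hbo2 Deoxy- and oxy-hemoglobin, uM. Absolute concentrations or
#'   (for `tHb` only) differences.
#' @param absolute Set `TRUE` to declare absolute concentrations and obtain
#'   `so2`.
#' @return List with `thb` and (when `absolute`) `so2` in `[0, 1]`.
#' @examples
#' derived_hemoglobin(10, 30, absolute = TRUE)  # thb 40, so2 0.75
#' derived_hemoglobin(-5, 12)$thb               # +7
#' @export
derived_hemoglobin <- function(hb, hbo2, absolute = FALSE) {
  out <- list(thb = hb + hbo2)
  if (absolute) {
    if (any(hb < 0) || any(hbo2 < 0))
      stop("SO2 requires absolute non-negative concentrations, not differences")
    if (any(hb + hbo2 == 0))
      stop("SO2 undefined when Hb and HbO2 are both zero")
    out$so2 <- hbo2 / (hb + hbo2)
  }
  out
}
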