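# Text-based interchange: curve files, cohort tables, map rasters/matrices
# and model serialization.

#' Write / read a time-resolved curve as delimited text
#'
#' Two columns (`time_ps`, `counts`) preceded by a `# wavelength_nm=` header
#' line.
#'
#' @param curve A [trcurve()].
#' @param path Output path.
#' @return `write_curve` returns `path` invisibly; `read_curve` a [trcurve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "trcurve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength_nm=%s", format(curve$wavelength)), con)
  utils::write.table(data.frame(time_ps = curve$time_ps,
                                counts = curve$counts),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  first <- readLines(path, n = 1)
  wl <- NA_real_
  if (grepl("^#\\s*wavelength_nm=", first))
    wl <- suppressWarnings(as.numeric(sub("^#\\s*wavelength_nm=", "", first)))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  trcurve(tab$time_ps, tab$counts, wl)
}

#' Write / read a lesion cohort as CSV
#'
#' @param cohort A `cohort` data frame.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path)
  out$label <- factor(out$label, levels = c("benign", "malignant"))
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write composition/absorption maps to disk
#'
#' Each map is written as a tab-delimited text matrix and, when the `tiff`
#' package is available and `tiff = TRUE`, as a 16-bit grayscale raster
#' (min-max scaled). A JSON sidecar records each map's value range, mirroring
#' the color-bar ranges of a map figure.
#'
#' @param maps A `composition_maps` object from [compute_maps()].
#' @param dir Output directory (created if needed).
#' @param tiff Also write 16-bit TIFF rasters.
#' @return Invisibly, the sidecar path.
#' @export
write_maps <- function(maps, dir, tiff = FALSE) {
  stopifnot(inherits(maps, "composition_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_maps <- c(setNames(maps$delta_mua,
                         paste0("delta_mua_", names(maps$delta_mua))),
                setNames(maps$delta_c,
                         paste0("delta_c_", names(maps$delta_c))))
  ranges <- list()
  for (nm in names(all_maps)) {
    m <- all_maps[[nm]]
    utils::write.table(m, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    rng <- range(m, na.rm = TRUE)
    ranges[[nm]] <- list(min = rng[1], max = rng[2])
    if (tiff && requireNamespace("tiff", quietly = TRUE)) {
      scaled <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
      scaled[is.na(scaled)] <- 0
      tiff::writeTIFF(scaled, file.path(dir, paste0(nm, ".tif")),
                      bits.per.sample = 16)
    }
  }
  sidecar <- file.path(dir, "map_ranges.json")
  jsonlite::write_json(ranges, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Serialize / restore a Discrete AdaBoost model as JSON
#'
#' Trees are stored as nested split records (`var`, `threshold`, `gain`,
#' `left`, `right`) with the coefficient list and metadata.
#'
#' @param model A `boost_model`.
#' @param path JSON path.
#' @return `write_boost_model` returns `path` invisibly;
#'   `read_boost_model` a `boost_model`.
#' @export
write_boost_model <- function(model, path) {
  stopifnot(inherits(model, "boost_model"))
  payload <- list(trees = model$trees, coefficients = model$coefficients,
                  errors = model$errors, M = model$M,
                  features = model$features, base_depth = model$base_depth,
                  y_levels = model$y_levels, n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix_tree <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (node$leaf) {
      node$pred <- as.numeric(node$pred)
    } else {
      node$var <- as.integer(node$var)
      node$threshold <- as.numeric(node$threshold)
      node$gain <- as.numeric(node$gain)
      node$left <- fix_tree(node$left)
      node$right <- fix_tree(node$right)
    }
    node
  }
  structure(list(trees = lapply(raw$trees, fix_tree),
                 coefficients = as.numeric(unlist(raw$coefficients)),
                 errors = as.numeric(unlist(raw$errors)),
                 M = as.integer(raw$M),
                 features = as.character(unlist(raw$features)),
                 base_depth = raw$base_depth,
                 bags = NULL,
                 y_levels = if (is.null(raw$y_levels)) NULL
                            else as.character(unlist(raw$y_levels)),
                 n_train = raw$n_train),
            class = "boost_model")
}
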