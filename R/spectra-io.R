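#' Write a dataset as per-spectrum CSV files plus a manifest
#'
#' Each spectrum is stored as a two-column CSV (`wavelength_nm,intensity`);
#' a manifest CSV (`path,origin,pellet_id`) lists all records, and a JSON
#' sidecar records the generating [dataset_spec()] (including the seed)
#' when one is supplied.
#'
#' @param records list of spectrum records.
#' @param dir output directory (created if missing).
#' @param spec optional `"dataset_spec"` stored as `dataset_spec.json`.
#' @return path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(records, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    paths[i] <- sprintf("spectrum_%04d.csv", i)
    # 17 significant digits so doubles round-trip bit-identically
    lines <- c("wavelength_nm,intensity",
               sprintf("%.17g,%.17g", r$wavelengths, r$intensities))
    writeLines(lines, file.path(dir, paths[i]))
  }
  manifest <- data.frame(path = paths,
                         origin = dataset_labels(records),
                         pellet_id = dataset_pellets(records),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  if (!is.null(spec)) {
    sidecar <- list(
      origins = vapply(spec$profiles, function(p) p$origin, character(1)),
      pellets_per_origin = spec$pellets_per_origin,
      spectra_per_pellet = spec$spectra_per_pellet,
      acquisition = unclass(spec$acquisition),
      seed = spec$seed)
    jsonlite::write_json(sidecar, file.path(dir, "dataset_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest_path)
}

#' Read a dataset from a manifest CSV
#'
#' Parses every referenced two-column spectrum CSV and validates that all
#' records share one strictly increasing wavelength grid.
#'
#' @param manifest_path path to a manifest CSV with columns
#'   `path,origin,pellet_id`.
#' @return list of `"spectrum_record"` with class `"spectrum_dataset"`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("manifest not found: %s", manifest_path)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("path", "origin", "pellet_id")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stopf("manifest lacks column(s): %s", paste(missing_cols, collapse = ", "))
  base <- dirname(manifest_path)
  grid <- NULL
  records <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(base, manifest$path[i])
    if (!file.exists(f)) stopf("spectrum file missing: %s", f)
    df <- tryCatch(read.csv(f), error = function(e)
      stopf("malformed spectrum file %s: %s", f, conditionMessage(e)))
    if (!all(c("wavelength_nm", "intensity") %in% names(df)))
      stopf("%s must have columns wavelength_nm,intensity", f)
    bad <- which(!is.finite(df$wavelength_nm) | !is.finite(df$intensity))
    if (length(bad))
      stopf("non-numeric value in %s at data row %d", f, bad[1])
    if (any(diff(df$wavelength_nm) <= 0))
      stopf("wavelength grid not strictly increasing in %s", f)
    if (is.null(grid)) {
      grid <- df$wavelength_nm
    } else if (length(grid) != length(df$wavelength_nm) ||
               any(grid != df$wavelength_nm)) {
      stopf("wavelength grid of %s differs from the first record", f)
    }
    records[[i]] <- spectrum_record(manifest$origin[i], manifest$pellet_id[i],
                                    df$wavelength_nm, df$intensity)
  }
  structure(records, class = "spectrum_dataset")
}
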