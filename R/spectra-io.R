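#' Construct a profile spectrum
#'
#' A profile spectrum is the continuous (m/z, intensity) trace for one
#' sample and modality, prior to peak picking.  The m/z grid must be
#' strictly increasing and intensities non-negative.
#'
#' @param mz numeric, strictly increasing m/z grid (Da).
#' @param intensity numeric, same length as `mz`, all values >= 0.
#' @param sample_id sample identifier.
#' @param modality `"extract"` or `"IMS"`.
#' @return An object of class `profile_spectrum`.
#' @export
profile_spectrum <- function(mz, intensity, sample_id = NA_character_,
                             modality = NA_character_) {
  if (length(mz) != length(intensity))
    mc_error("mz and intensity must have equal length", "mc_invalid_spectrum")
  if (length(mz) && any(diff(mz) <= 0))
    mc_error("mz grid must be strictly increasing", "mc_invalid_spectrum")
  if (any(intensity < 0))
    mc_error("intensities must be non-negative", "mc_invalid_spectrum")
  structure(
    list(mz = as.numeric(mz), intensity = as.numeric(intensity),
         sample_id = sample_id, modality = modality),
    class = "profile_spectrum")
}

#' @export
print.profile_spectrum <- function(x, ...) {
  cat(sprintf("<profile_spectrum> %s [%s]: %d points, m/z %.2f-%.2f\n",
              x$sample_id, x$modality, length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Construct a centroided peak list
#'
#' The working currency of the pipeline: ordered (m/z, intensity) pairs for
#' one sample and modality.  If `normalized` is `TRUE` the intensities must
#' sum to 1 (within 1e-9).
#'
#' @param mz numeric peak positions (Da); strictly increasing.
#' @param intensity numeric peak intensities, >= 0.
#' @param sample_id sample identifier.
#' @param modality `"extract"` or `"IMS"`.
#' @param normalized logical; whether intensities are TIC-normalized.
#' @return An object of class `peak_list` (a data.frame with columns
#'   `mz` and `intensity` and attributes `sample_id`, `modality`,
#'   `normalized`).
#' @export
peak_list <- function(mz, intensity, sample_id = NA_character_,
                      modality = NA_character_, normalized = FALSE) {
  if (length(mz) != length(intensity))
    mc_error("mz and intensity must have equal length", "mc_invalid_peaklist")
  o <- order(mz)
  mz <- as.numeric(mz)[o]; intensity <- as.numeric(intensity)[o]
  if (length(mz) > 1 && any(diff(mz) <= 0))
    mc_error("duplicate m/z values in peak list", "mc_invalid_peaklist")
  if (any(intensity < 0))
    mc_error("peak intensities must be non-negative", "mc_invalid_peaklist")
  if (isTRUE(normalized) && length(intensity) &&
      abs(sum(intensity) - 1) > 1e-9)
    mc_error("normalized peak list must have intensities summing to 1",
             "mc_invalid_peaklist")
  structure(
    data.frame(mz = mz, intensity = intensity),
    sample_id = sample_id, modality = modality, normalized = normalized,
    class = c("peak_list", "data.frame"))
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))
pl_modality <- function(x) attr(x, "modality")

#' Write / read a peak list as tabular text
#'
#' Plain two-column text (header `mz<TAB>intensity`, '.' decimal, UTF-8).
#' `read_peaklist()` accepts tab-, comma- or whitespace-separated rows,
#' sorts peaks by m/z (warning if the input was unsorted), and reports the
#' offending line number on malformed input.  Round-tripping preserves
#' values to at least 6 significant digits.
#'
#' @param x a [peak_list()].
#' @param path file path.
#' @rdname peaklist_io
#' @export
write_peaklist <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("mz\tintensity", con)
  if (nrow(x))
    writeLines(sprintf("%.10g\t%.10g", x$mz, x$intensity), con)
  invisible(path)
}

#' @param sample_id,modality metadata attached to the returned peak list.
#' @rdname peaklist_io
#' @export
read_peaklist <- function(path, sample_id = NA_character_,
                          modality = NA_character_) {
  if (!file.exists(path))
    mc_error(sprintf("peak list file not found: %s", path), "mc_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines) && grepl("[A-Za-z]", lines[[1L]])) start <- 2L
  rows <- if (start > 1L) lines[-seq_len(start - 1L)] else lines
  n <- length(rows)
  mz <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(rows[[i]]), "[,\t ]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals))
      mc_error(sprintf("malformed peak list row at line %d of %s: '%s'",
                       i + start - 1L, path, rows[[i]]), "mc_parse_error")
    mz[i] <- vals[1L]; intensity[i] <- vals[2L]
  }
  if (n > 1 && any(diff(mz) <= 0))
    warning(sprintf("peak list %s was not sorted by m/z; sorting", path))
  peak_list(mz, intensity, sample_id = sample_id, modality = modality)
}

#' @rdname peaklist_io
#' @export
write_profile_spectrum <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("mz\tintensity", con)
  writeLines(sprintf("%.10g\t%.10g", x$mz, x$intensity), con)
  invisible(path)
}

#' @rdname peaklist_io
#' @export
read_profile_spectrum <- function(path, sample_id = NA_character_,
                                  modality = NA_character_) {
  pl <- read_peaklist(path, sample_id, modality)
  profile_spectrum(pl$mz, pl$intensity, sample_id, modality)
}

#' Read or write a sample manifest
#'
#' The manifest is tab-separated text with case-sensitive columns
#' `sample_id`, `group`, `replicate`, `modality`, `path`.  Groups come from
#' the closed vocabulary A8, CS4, CS8, CS8+R and modalities from
#' extract, IMS.
#'
#' @param path manifest file path.
#' @param check_paths if `TRUE` (default), error when a referenced data
#'   file does not exist (paths are resolved relative to the manifest).
#' @return A data.frame with the five manifest columns.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path))
    mc_error(sprintf("manifest not found: %s", path), "mc_io_error")
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "replicate", "modality", "path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    mc_error(sprintf("manifest is missing column(s): %s",
                     paste(missing, collapse = ", ")), "mc_invalid_manifest")
  bad_group <- !(m$group %in% GROUP_LEVELS)
  if (any(bad_group))
    mc_error(sprintf("unknown group label(s) in manifest rows %s: %s",
                     paste(which(bad_group), collapse = ", "),
                     paste(unique(m$group[bad_group]), collapse = ", ")),
             "mc_invalid_manifest")
  bad_mod <- !(m$modality %in% MODALITY_LEVELS)
  if (any(bad_mod))
    mc_error(sprintf("unknown modality label(s) in manifest rows %s: %s",
                     paste(which(bad_mod), collapse = ", "),
                     paste(unique(m$modality[bad_mod]), collapse = ", ")),
             "mc_invalid_manifest")
  if (anyDuplicated(m$sample_id))
    mc_error(sprintf("duplicate sample_id in manifest: %s",
                     paste(unique(m$sample_id[duplicated(m$sample_id)]),
                           collapse = ", ")), "mc_invalid_manifest")
  if (check_paths) {
    full <- ifelse(file.exists(m$path), m$path,
                   file.path(dirname(path), m$path))
    absent <- !file.exists(full)
    if (any(absent))
      mc_error(sprintf("manifest references missing file(s): %s",
                       paste(m$path[absent], collapse = ", ")),
               "mc_io_error")
    m$path <- full
  }
  m
}

#' @param manifest a manifest data.frame.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the bundled shared-ion reference table
#'
#' Returns the package's transcription of the 25 lipid ions detected by
#' both modalities (MALDI of lipid extracts and imaging mass spectrometry)
#' in cerebral white matter, with their lipid assignments, C13-isotope
#' flags, and five-level relative-abundance categories (IMS vs extract):
#' `EQ` (intensities within 10%), `IMS_GT`/`IMS_LT` (IMS 10-49% higher or
#' lower), `IMS_GGT`/`IMS_LLT` (IMS at least 50% higher or lower).  The
#' `mz_alias` column carries the higher-precision m/z variants used in the
#' running text for some ions.
#'
#' @param path fixture path; defaults to the copy bundled with the package.
#' @return A data.frame with columns `mz`, `lipid_id`, `isotope_flag`,
#'   `category`, `mz_alias`.
#' @export
load_table1 <- function(path = system.file("extdata", "shared_ion_table.tsv",
                                           package = "maldiconcord")) {
  if (!nzchar(path) || !file.exists(path))
    mc_error("shared-ion fixture not found", "mc_io_error")
  t1 <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  required <- c("mz", "lipid_id", "isotope_flag", "category", "mz_alias")
  if (!identical(names(t1), required))
    mc_error("shared-ion fixture is corrupted: unexpected columns",
             "mc_fixture_integrity")
  if (nrow(t1) != 25L)
    mc_error(sprintf("shared-ion fixture is corrupted: %d records, expected 25",
                     nrow(t1)), "mc_fixture_integrity")
  if (!all(t1$category %in% names(CATEGORY_GLYPHS)))
    mc_error("shared-ion fixture is corrupted: unknown category code",
             "mc_fixture_integrity")
  t1$isotope_flag <- as.logical(t1$isotope_flag)
  if (anyNA(t1$isotope_flag) || anyNA(t1$mz))
    mc_error("shared-ion fixture is corrupted: missing values",
             "mc_fixture_integrity")
  t1
}

#' Concordance category glyphs
#'
#' Mapping from category codes to the conventional glyphs used in
#' relative-abundance tables: `EQ` (=), `IMS_LT` (<), `IMS_LLT`
#' (\u226a), `IMS_GT` (>), `IMS_GGT` (\u226b).
#'
#' @export
CATEGORY_GLYPHS <- c(EQ = "=", IMS_LT = "<", IMS_LLT = "\u226a",
                     IMS_GT = ">", IMS_GGT = "\u226b")
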