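#' Match extract and IMS peak lists
#'
#' One-to-one pairing of two peak lists.  Candidate pairs are all
#' extract/IMS peak combinations within `tolerance` Da; they are accepted
#' greedily in order of ascending absolute m/z difference (ties broken
#' toward the lower-m/z extract peak, then the lower-m/z IMS peak), each
#' peak being used at most once.  Unmatched peaks are returned as the
#' modality-only remainders.
#'
#' @param extract,ims peak collections (a [peak_list()],
#'   `consensus_peaklist`, or any data.frame with `mz` and `intensity`);
#'   both must be in the same normalization state.
#' @param tolerance matching tolerance in Da (> 0); default 0.25.
#' @return An object of class `match_result`: list with `pairs` (columns
#'   `extract_mz`, `ims_mz`, `extract_intensity`, `ims_intensity`, `dmz`),
#'   `extract_only`, `ims_only`, `tolerance`.
#' @export
match_peaklists <- function(extract, ims, tolerance = 0.25) {
  if (tolerance <= 0)
    mc_error("tolerance must be positive", "mc_config_error")
  ne <- !is.null(attr(extract, "normalized"))
  ni <- !is.null(attr(ims, "normalized"))
  if (ne && ni && !identical(is_normalized(extract), is_normalized(ims)))
    mc_error("cannot match normalized against unnormalized peak lists",
             "mc_unnormalized_input")
  emz <- extract$mz; imz <- ims$mz
  cand <- NULL
  for (i in seq_along(emz)) {
    j <- which(abs(imz - emz[i]) <= tolerance)
    if (length(j))
      cand <- rbind(cand, data.frame(e = i, i = j,
                                     d = abs(imz[j] - emz[i])))
  }
  pairs <- data.frame(e = integer(0), i = integer(0), d = numeric(0))
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, emz[cand$e], imz[cand$i]), ]
    used_e <- logical(length(emz)); used_i <- logical(length(imz))
    for (r in seq_len(nrow(cand))) {
      ce <- cand$e[r]; ci <- cand$i[r]
      if (!used_e[ce] && !used_i[ci]) {
        used_e[ce] <- TRUE; used_i[ci] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  pair_df <- data.frame(extract_mz = emz[pairs$e],
                        ims_mz = imz[pairs$i],
                        extract_intensity = extract$intensity[pairs$e],
                        ims_intensity = ims$intensity[pairs$i],
                        dmz = imz[pairs$i] - emz[pairs$e])
  res <- list(pairs = pair_df,
              extract_only = as.data.frame(extract)[setdiff(seq_along(emz),
                                                            pairs$e), ,
                                                    drop = FALSE],
              ims_only = as.data.frame(ims)[setdiff(seq_along(imz),
                                                    pairs$i), , drop = FALSE],
              tolerance = tolerance)
  rownames(res$extract_only) <- rownames(res$ims_only) <- NULL
  stopifnot(nrow(pair_df) + nrow(res$extract_only) == length(emz),
            nrow(pair_df) + nrow(res$ims_only) == length(imz),
            all(abs(pair_df$dmz) <= tolerance + 1e-12))
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("<match_result> %d pairs, %d extract-only, ",
                     "%d IMS-only (tolerance %g Da)\n"),
              nrow(x$pairs), nrow(x$extract_only), nrow(x$ims_only),
              x$tolerance))
  invisible(x)
}

#' Flag C13 isotope satellites in a peak list
#'
#' A peak is flagged as a first C13 isotopologue when another peak exists
#' `delta` (default 1.00335) Da below it, within `tol`, and the intensity
#' ratio satellite/parent does not exceed `max_ratio` (default 1: a first
#' isotope peak of a lipid in this mass range cannot exceed its
#' monoisotopic peak).
#'
#' @param peaks a peak collection with `mz` and `intensity` columns,
#'   sorted by m/z.
#' @param delta C13 isotope spacing in Da.
#' @param tol spacing tolerance in Da.
#' @param max_ratio maximum satellite/parent intensity ratio.
#' @return Logical vector, one flag per peak.
#' @export
flag_isotopes <- function(peaks, delta = C13_DELTA, tol = 0.1,
                          max_ratio = 1.0) {
  mz <- peaks$mz; intensity <- peaks$intensity
  n <- length(mz)
  flags <- logical(n)
  for (p in seq_len(n)) {
    gap <- mz[p] - mz
    q <- which(gap >= delta - tol & gap <= delta + tol &
                 intensity[p] <= max_ratio * intensity)
    flags[p] <- length(q) > 0
  }
  flags
}

#' Classify cross-modality relative abundance of a shared ion
#'
#' Computes the signed percent difference of the IMS intensity relative to
#' the extract intensity, `100 * (ims - extract) / extract`, and maps it
#' onto the five-level category scale: `EQ` when the intensities differ by
#' less than 10%; `IMS_GT` / `IMS_LT` when IMS is 10-49% higher or lower;
#' `IMS_GGT` / `IMS_LLT` when IMS is at least 50% higher or lower.
#' Boundaries are half-open: exactly 10% falls in the GT/LT class and
#' exactly 50% in the GGT/LLT class.
#'
#' @param ims_intensity,extract_intensity positive (normalized)
#'   intensities; vectorized.
#' @return A data.frame with columns `pct_diff` and `category`.
#' @export
classify_concordance <- function(ims_intensity, extract_intensity) {
  if (any(ims_intensity <= 0) || any(extract_intensity <= 0))
    mc_error(paste0("concordance requires positive intensities in both ",
                    "modalities; an ion absent from one modality is ",
                    "modality-only, not shared"), "mc_degenerate_input")
  pct <- 100 * (ims_intensity - extract_intensity) / extract_intensity
  category <- ifelse(abs(pct) < 10, "EQ",
              ifelse(abs(pct) < 50,
                     ifelse(pct > 0, "IMS_GT", "IMS_LT"),
                     ifelse(pct > 0, "IMS_GGT", "IMS_LLT")))
  data.frame(pct_diff = pct, category = category)
}

#' Build concordance records for the shared ions of a match
#'
#' One record per matched (shared) ion: consensus m/z (mean of the two
#' modality m/z values), optional lipid assignment looked up from a
#' reference table, isotope flag, percent difference and five-level
#' category.  Isotope flags are taken from [flag_isotopes()] applied to
#' the full extract and IMS peak collections (a satellite's parent may be
#' detected in only one modality); flagged records carry no lipid
#' assignment.
#'
#' @param match a `match_result` from [match_peaklists()].
#' @param extract,ims the full peak collections the match was computed
#'   from (for isotope context); optional — when omitted, flags are
#'   computed on the matched pairs only.
#' @param lipid_ref optional reference data.frame with columns `mz` and
#'   `lipid_id` (e.g. [load_table1()]).
#' @param lipid_tol m/z tolerance for reference lookup, Da.
#' @param isotope_tol,max_ratio passed to [flag_isotopes()].
#' @return A data.frame of class `concordance_records` with columns `mz`,
#'   `lipid_id`, `isotope_flag`, `pct_diff`, `category`, `glyph`.
#' @export
concordance_records <- function(match, extract = NULL, ims = NULL,
                                lipid_ref = NULL, lipid_tol = 0.25,
                                isotope_tol = 0.1, max_ratio = 1.0) {
  p <- match$pairs
  mz <- (p$extract_mz + p$ims_mz) / 2
  cc <- classify_concordance(p$ims_intensity, p$extract_intensity)
  flag_in <- function(full, pos) {
    if (is.null(full)) return(rep(FALSE, length(pos)))
    fl <- flag_isotopes(full, tol = isotope_tol, max_ratio = max_ratio)
    vapply(pos, function(m) {
      i <- which.min(abs(full$mz - m))
      length(i) == 1L && abs(full$mz[i] - m) < 1e-6 && fl[i]
    }, logical(1))
  }
  if (is.null(extract) && is.null(ims)) {
    shared <- data.frame(mz = mz, intensity = p$extract_intensity)
    flags <- flag_isotopes(shared, tol = isotope_tol, max_ratio = max_ratio)
  } else {
    flags <- flag_in(extract, p$extract_mz) | flag_in(ims, p$ims_mz)
  }
  lipid <- rep(NA_character_, length(mz))
  if (!is.null(lipid_ref)) {
    for (k in seq_along(mz)) {
      j <- which.min(abs(lipid_ref$mz - mz[k]))
      if (length(j) && abs(lipid_ref$mz[j] - mz[k]) <= lipid_tol)
        lipid[k] <- lipid_ref$lipid_id[j]
    }
  }
  lipid[flags] <- NA_character_
  out <- data.frame(mz = mz, lipid_id = lipid, isotope_flag = flags,
                    pct_diff = cc$pct_diff, category = cc$category,
                    glyph = unname(CATEGORY_GLYPHS[cc$category]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concordance_records", "data.frame")
  out
}

#' Summarize cross-modality detection
#'
#' Detection arithmetic for a match: per-modality ion counts, shared
#' count, modality-only counts, the total number of distinct ions
#' (`extract + IMS - shared`), category tallies over the shared set, and
#' the shared fraction on both denominators (shared/total and
#' shared/(extract + IMS)).
#'
#' @param match a `match_result`.
#' @param records optional `concordance_records` derived from `match`;
#'   must have one record per matched pair.
#' @return A list of class `detection_summary`.
#' @export
summarize_detection <- function(match, records = NULL) {
  shared <- nrow(match$pairs)
  extract_only <- nrow(match$extract_only)
  ims_only <- nrow(match$ims_only)
  n_extract <- shared + extract_only
  n_ims <- shared + ims_only
  total <- n_extract + n_ims - shared
  tallies <- NULL
  if (!is.null(records)) {
    if (nrow(records) != shared)
      mc_error("concordance records do not correspond to the match",
               "mc_inconsistent_input")
    tallies <- table(factor(records$category,
                            levels = names(CATEGORY_GLYPHS)))
    stopifnot(sum(tallies) == shared)
  }
  structure(list(total = total, n_extract = n_extract, n_ims = n_ims,
                 shared = shared, extract_only = extract_only,
                 ims_only = ims_only,
                 shared_of_total = shared / total,
                 shared_of_sum = shared / (n_extract + n_ims),
                 category_tallies = tallies),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf(paste0("<detection_summary> total %d | extract %d ",
                     "(only %d) | IMS %d (only %d) | shared %d\n"),
              x$total, x$n_extract, x$extract_only, x$n_ims,
              x$ims_only, x$shared))
  if (!is.null(x$category_tallies)) {
    t <- x$category_tallies
    cat("  concordance: ",
        paste(sprintf("%s %d", CATEGORY_GLYPHS[names(t)], t),
              collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a shared-ion concordance report
#'
#' Tabular text report in the style of a shared-ion table: m/z, lipid
#' assignment, isotope flag, signed percent difference and category
#' glyph.
#'
#' @param records `concordance_records`.
#' @param path output file.
#' @export
write_concordance_report <- function(records, path) {
  df <- as.data.frame(records)
  df$pct_diff <- sprintf("%.2f", df$pct_diff)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
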