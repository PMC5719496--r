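#' Pick peaks from a profile spectrum
#'
#' Centroiding for profile traces.  The baseline is estimated as the
#' median intensity and the noise level as the median absolute deviation
#' of the trace (scaled by 1.4826 to estimate a Gaussian standard
#' deviation).  A candidate peak is a strict local maximum that exceeds
#' `snr_threshold` times the noise level above the baseline, together
#' with both immediate neighbours (a resolved peak spans several grid
#' points, so this width requirement suppresses single-point noise
#' spikes); its centroid is the intensity-weighted mean m/z over a
#' `+/- window` neighbourhood (baseline-subtracted weights).  Candidates
#' closer than `window` to a stronger candidate are dropped, and peaks are
#' restricted to the analysis m/z range.
#'
#' @param spectrum a [profile_spectrum()].
#' @param snr_threshold signal-to-noise threshold (> 0); default 3.
#' @param window centroiding half-window in Da; default 0.1.
#' @param mz_min,mz_max analysis range (Da); defaults 600-1300.
#' @return A [peak_list()] of centroids with baseline-subtracted apex
#'   intensities, sorted by m/z.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 3, window = 0.1,
                       mz_min = 600, mz_max = 1300) {
  if (!inherits(spectrum, "profile_spectrum"))
    mc_error("pick_peaks expects a profile_spectrum", "mc_invalid_spectrum")
  if (snr_threshold <= 0 || window <= 0)
    mc_error("snr_threshold and window must be positive", "mc_config_error")
  y <- spectrum$intensity; x <- spectrum$mz
  n <- length(y)
  if (n < 3L)
    mc_error("spectrum has fewer than 3 points", "mc_invalid_spectrum")
  baseline <- stats::median(y)
  noise <- stats::mad(y)           # MAD * 1.4826
  threshold <- baseline + snr_threshold * noise
  mid <- 2:(n - 1L)
  # a genuine peak is resolved over several grid points: the apex must be
  # a strict local maximum and its immediate neighbours must also clear
  # the threshold, which suppresses single-point noise spikes
  cand <- mid[y[mid] > y[mid - 1L] & y[mid] > y[mid + 1L] &
                y[mid] > threshold & y[mid - 1L] > threshold &
                y[mid + 1L] > threshold & y[mid] > baseline]
  if (!length(cand))
    return(peak_list(numeric(0), numeric(0),
                     sample_id = spectrum$sample_id,
                     modality = spectrum$modality))
  # suppress shoulder candidates within `window` of a stronger one
  keep <- logical(length(cand))
  ord <- order(y[cand], decreasing = TRUE)
  kept_mz <- numeric(0)
  for (j in ord) {
    if (!length(kept_mz) || min(abs(kept_mz - x[cand[j]])) >= window) {
      keep[j] <- TRUE
      kept_mz <- c(kept_mz, x[cand[j]])
    }
  }
  cand <- cand[keep]
  cmz <- numeric(length(cand)); cint <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    idx <- which(x >= x[i] - window & x <= x[i] + window)
    w <- pmax(y[idx] - baseline, 0)
    cmz[j] <- if (sum(w) > 0) sum(w * x[idx]) / sum(w) else x[i]
    cint[j] <- y[i] - baseline
  }
  sel <- cmz >= mz_min & cmz <= mz_max
  peak_list(cmz[sel], cint[sel], sample_id = spectrum$sample_id,
            modality = spectrum$modality)
}

#' Normalize a peak list to total ion count
#'
#' Divides every intensity by the summed intensity of the list so that
#' intensities sum to 1; rank order and pairwise ratios are preserved and
#' the operation is idempotent.
#'
#' @param peaks a [peak_list()] with at least one positive intensity.
#' @return The TIC-normalized [peak_list()] (`normalized` flag set).
#' @export
tic_normalize <- function(peaks) {
  tic <- sum(peaks$intensity)
  if (!is.finite(tic) || tic <= 0)
    mc_error("cannot TIC-normalize a peak list with no positive intensity",
             "mc_degenerate_input")
  peak_list(peaks$mz, peaks$intensity / tic,
            sample_id = attr(peaks, "sample_id"),
            modality = pl_modality(peaks), normalized = TRUE)
}

#' Aggregate replicate peak lists into a consensus peak list
#'
#' Pools the peaks of all replicates of one group and modality, groups
#' them by single-linkage chaining (adjacent pooled peaks closer than
#' `cluster_tol` join one consensus ion), and reports per ion the mean
#' m/z, the detection frequency (fraction of replicates contributing) and
#' the mean normalized intensity.  By default replicates in which the ion
#' was not detected contribute zero intensity (`absent_as_zero = TRUE`);
#' alternatively the mean is taken over detections only.  If a replicate
#' contributes several pooled peaks to one consensus ion only its most
#' intense peak is used.  Consensus ions detected in fewer than
#' `min_frequency` of replicates are dropped.
#'
#' @param peaklists list of TIC-normalized [peak_list()]s from the same
#'   modality.
#' @param cluster_tol single-linkage clustering tolerance in Da.
#' @param min_frequency minimum detection frequency (a consensus ion is
#'   retained when its frequency is `>= min_frequency`).
#' @param absent_as_zero treat non-detections as zero intensity when
#'   averaging.
#' @param group optional group label stored on the result.
#' @return A data.frame of class `consensus_peaklist` with columns `mz`,
#'   `intensity`, `frequency`, and attributes `group`, `modality`,
#'   `n_replicates`, `normalized`.
#' @export
aggregate_replicates <- function(peaklists, cluster_tol = 0.25,
                                 min_frequency = 0.5,
                                 absent_as_zero = TRUE,
                                 group = NA_character_) {
  if (!length(peaklists))
    mc_error("no peak lists supplied", "mc_degenerate_input")
  if (cluster_tol <= 0)
    mc_error("cluster_tol must be positive", "mc_config_error")
  mods <- unique(vapply(peaklists, pl_modality, character(1)))
  if (length(mods) > 1L)
    mc_error(sprintf("mixed modalities in aggregate_replicates: %s",
                     paste(mods, collapse = ", ")), "mc_mixed_modality")
  norm <- vapply(peaklists, is_normalized, logical(1))
  if (!all(norm))
    mc_error("all replicate peak lists must be TIC-normalized",
             "mc_unnormalized_input")
  n_rep <- length(peaklists)
  pooled <- do.call(rbind, lapply(seq_along(peaklists), function(i)
    data.frame(mz = peaklists[[i]]$mz,
               intensity = peaklists[[i]]$intensity, rep = i)))
  if (!nrow(pooled))
    return(structure(data.frame(mz = numeric(0), intensity = numeric(0),
                                frequency = numeric(0)),
                     group = group, modality = mods, n_replicates = n_rep,
                     normalized = TRUE,
                     class = c("consensus_peaklist", "data.frame")))
  pooled <- pooled[order(pooled$mz), ]
  cl <- cumsum(c(1L, diff(pooled$mz) > cluster_tol))
  agg <- lapply(split(pooled, cl), function(d) {
    # one peak per replicate per consensus ion: keep the most intense
    if (anyDuplicated(d$rep)) {
      d <- d[order(d$rep, -d$intensity), ]
      d <- d[!duplicated(d$rep), ]
    }
    denom <- if (absent_as_zero) n_rep else nrow(d)
    data.frame(mz = mean(d$mz),
               intensity = sum(d$intensity) / denom,
               frequency = nrow(d) / n_rep)
  })
  out <- do.call(rbind, agg)
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, group = group, modality = mods, n_replicates = n_rep,
            normalized = TRUE,
            class = c("consensus_peaklist", "data.frame"))
}
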