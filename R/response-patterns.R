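# Classification of per-ion trajectories across the exposure design
# A8 (control) -> CS4 -> CS8 -> CS8+R into a direction / progression /
# recovery taxonomy, plus summary fractions and diagnostic-ion calls.

#' Classify one ion's exposure/withdrawal response pattern
#'
#' Operates on the four group mean intensities (A8, CS4, CS8, CS8+R).
#' Fold changes are taken relative to the A8 control; `change_threshold`
#' defines the multiplicative no-change band (an ion is changed when its
#' fold change exceeds the band in either direction), and
#' `progress_threshold` the minimum fold ratio for calling one effect
#' larger than another.
#'
#' * direction — `inhibited` / `stimulated` when CS8 (or, if CS8 is back
#'   in the band, CS4) lies outside the no-change band; `unchanged` when
#'   both exposures stay inside (progression and recovery are then
#'   `n/a`).
#' * progression — `transient` when CS4 is outside the band but CS8 has
#'   returned inside it; `progressive` when the CS8 effect exceeds the
#'   CS4 effect by more than `progress_threshold`; `sustained` otherwise.
#' * recovery — position of CS8+R relative to the control band and the
#'   CS8 effect: `full` when back inside the band, `partial` when moved
#'   toward the control by more than `progress_threshold` but still
#'   outside, `paradoxical` when moved further from the control by more
#'   than `progress_threshold`, `none` otherwise.
#'
#' Classification depends only on intensity ratios, so it is invariant to
#' global rescaling of the profile.
#'
#' @param group_means numeric length-4 vector of non-negative mean
#'   intensities ordered (A8, CS4, CS8, CS8+R); the A8 mean must be
#'   positive.
#' @param change_threshold no-change band half-width as a fold (> 1);
#'   default 1.25.
#' @param progress_threshold minimum fold ratio between effects (> 1);
#'   default 1.15.
#' @return A list with `direction`, `progression`, `recovery`, and the
#'   fold changes `f_cs4`, `f_cs8`, `f_csr`.
#' @export
classify_response <- function(group_means, change_threshold = 1.25,
                              progress_threshold = 1.15) {
  if (length(group_means) != 4L || any(group_means < 0))
    mc_error("group_means must be 4 non-negative intensities (A8, CS4, CS8, CS8+R)",
             "mc_degenerate_input")
  if (group_means[[1L]] <= 0)
    mc_error(paste0("A8 control mean must be positive; ions absent from ",
                    "the control belong on a presence/absence track"),
             "mc_degenerate_input")
  if (change_threshold <= 1 || progress_threshold <= 1)
    mc_error("thresholds must exceed 1", "mc_config_error")
  f4 <- group_means[[2L]] / group_means[[1L]]
  f8 <- group_means[[3L]] / group_means[[1L]]
  fr <- group_means[[4L]] / group_means[[1L]]
  # open band: a fold change exactly at the threshold counts as changed,
  # consistent with boundary handling in the concordance classes
  in_band <- function(f) f > 1 / change_threshold & f < change_threshold
  if (in_band(f4) && in_band(f8))
    return(list(direction = "unchanged", progression = "n/a",
                recovery = "n/a", f_cs4 = f4, f_cs8 = f8, f_csr = fr))
  anchor <- if (!in_band(f8)) f8 else f4
  direction <- if (anchor > 1) "stimulated" else "inhibited"
  progression <- if (in_band(f8)) "transient"
  else if (fold_dist(f8) > fold_dist(f4) * progress_threshold) "progressive"
  else "sustained"
  e8 <- fold_dist(f8); er <- fold_dist(fr)
  recovery <- if (in_band(fr)) "full"
  else if (er <= e8 / progress_threshold) "partial"
  else if (er >= e8 * progress_threshold) "paradoxical"
  else "none"
  list(direction = direction, progression = progression,
       recovery = recovery, f_cs4 = f4, f_cs8 = f8, f_csr = fr)
}

#' Classify response patterns for a table of group profiles
#'
#' @param profiles a data.frame with columns `A8`, `CS4`, `CS8`, `CS8+R`
#'   (or `CS8.R`) of group mean intensities, plus any identifier columns
#'   (carried through), e.g. from [group_profiles()].
#' @param ... passed to [classify_response()].
#' @return The input data.frame with appended columns `direction`,
#'   `progression`, `recovery`, `f_cs4`, `f_cs8`, `f_csr`.
#' @export
classify_responses <- function(profiles, ...) {
  cols <- c("A8", "CS4", "CS8",
            if ("CS8+R" %in% names(profiles)) "CS8+R" else "CS8.R")
  if (!all(cols %in% names(profiles)))
    mc_error("profiles must contain columns A8, CS4, CS8, CS8+R",
             "mc_inconsistent_input")
  res <- lapply(seq_len(nrow(profiles)), function(i)
    classify_response(as.numeric(profiles[i, cols]), ...))
  add <- do.call(rbind, lapply(res, function(r)
    data.frame(direction = r$direction, progression = r$progression,
               recovery = r$recovery, f_cs4 = r$f_cs4, f_cs8 = r$f_cs8,
               f_csr = r$f_csr, stringsAsFactors = FALSE)))
  cbind(profiles, add)
}

#' Build group mean profiles from per-group consensus peak lists
#'
#' Aligns the four group consensus peak lists of one modality into an
#' ion-by-group table of mean normalized intensities (absent = 0).
#'
#' @param group_consensus named list of `consensus_peaklist`s, one per
#'   group; names are the group labels.
#' @param cluster_tol cross-group alignment tolerance in Da.
#' @return A data.frame with columns `mz` and one column per group.
#' @export
group_profiles <- function(group_consensus, cluster_tol = 0.25) {
  mat <- build_intensity_matrix(group_consensus, cluster_tol)
  out <- data.frame(mz = attr(mat, "mz"), check.names = FALSE)
  cbind(out, as.data.frame(mat, check.names = FALSE))
}

#' Fraction of ions showing recovery after withdrawal
#'
#' Among the classified ions selected by `subset`, the fraction whose
#' recovery is `partial` or `full`.  The default subset is the
#' CS-suppressed ions with a persistent CS8 effect (direction
#' `inhibited`, progression not `transient`): for transient ions CS8 has
#' already returned to control levels, so withdrawal recovery is not a
#' meaningful attribute.
#'
#' @param patterns a classified data.frame from [classify_responses()].
#' @param subset logical vector selecting the denominator ions; defaults
#'   to suppressed non-transient ions.
#' @return The recovered fraction, in `[0, 1]`.
#' @export
recovery_fraction <- function(patterns,
                              subset = patterns$direction == "inhibited" &
                                patterns$progression != "transient") {
  sel <- patterns[subset, , drop = FALSE]
  if (!nrow(sel))
    mc_error("recovery_fraction: empty subset", "mc_degenerate_input")
  mean(sel$recovery %in% c("partial", "full"))
}

#' Identify diagnostic and internal-control ions
#'
#' Splits (shared) ions into a responsive set — candidate exposure
#' markers whose CS8 fold change versus control is at least
#' `responsive_fold` in either direction — and a stable set — candidate
#' internal negative controls whose fold changes stay within
#' `stable_band` across all exposure and withdrawal groups.  The two sets
#' are disjoint whenever `responsive_fold > stable_band`.
#'
#' @param patterns a classified data.frame from [classify_responses()]
#'   (must contain `mz`, `f_cs4`, `f_cs8`, `f_csr`).
#' @param shared_mz optional vector of shared-ion m/z values (e.g. from a
#'   `match_result`); when given, only ions matching one of them within
#'   `tol` are considered.
#' @param responsive_fold minimum CS8 fold distance for a responsive
#'   call; default 2.
#' @param stable_band maximum fold distance in every group for a stable
#'   call; default 1.25.
#' @param tol m/z tolerance for the shared filter, Da.
#' @return List with data.frames `responsive` and `stable`.
#' @export
identify_diagnostic_ions <- function(patterns, shared_mz = NULL,
                                     responsive_fold = 2,
                                     stable_band = 1.25, tol = 0.25) {
  if (responsive_fold <= stable_band)
    warning("responsive_fold <= stable_band: sets may overlap")
  p <- patterns
  if (!is.null(shared_mz) && nrow(p)) {
    keep <- vapply(p$mz, function(m) any(abs(shared_mz - m) <= tol),
                   logical(1))
    p <- p[keep, , drop = FALSE]
  }
  responsive <- p[fold_dist(p$f_cs8) >= responsive_fold, , drop = FALSE]
  stable <- p[fold_dist(p$f_cs4) <= stable_band &
                fold_dist(p$f_cs8) <= stable_band &
                fold_dist(p$f_csr) <= stable_band, , drop = FALSE]
  list(responsive = responsive, stable = stable)
}

#' Write a response-pattern table
#'
#' @param patterns classified data.frame from [classify_responses()].
#' @param path output TSV path.
#' @export
write_pattern_table <- function(patterns, path) {
  utils::write.table(patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
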