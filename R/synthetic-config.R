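#' Configuration for the synthetic study generator
#'
#' Defines the shape of a simulated comparative MALDI lipidomics study:
#' four exposure groups (A8 air control, CS4 and CS8 cigarette-smoke
#' exposure, CS8+R exposure plus recovery), six replicates per group, and
#' two modalities (lipid `extract` plated on a steel target, and `IMS`
#' summarized as one mean spectrum per tissue region).  Defaults mirror
#' the printed study design: 83 extract ions, 62 IMS ions, 25 of them
#' shared, in the m/z 600-1300 Da analysis window.
#'
#' @param n_extract_ions number of ions detectable in the extract modality.
#' @param n_ims_ions number of ions detectable by IMS.
#' @param n_shared number of ions detectable by both modalities
#'   (`n_shared <= min(n_extract_ions, n_ims_ions)`).
#' @param mz_range analysis m/z window in Da.
#' @param n_replicates replicates (animals) per group.
#' @param groups ordered group labels; A8 is the control and must come
#'   first.
#' @param effect_mix named proportions over planted response categories
#'   (`stable`, and direction x progression combinations); must sum to 1.
#' @param recovery_fraction proportion of CS-suppressed (and, mirrored,
#'   CS-stimulated) non-transient ions planted with partial or full
#'   recovery after withdrawal.
#' @param isotope_prob probability that a panel slot is filled by a C13
#'   satellite (+1.00335 Da) of the previously placed ion rather than an
#'   independent ion.  Satellites are panel members: they count toward the
#'   per-modality ion totals, as isotope peaks do in real shared-ion
#'   tables.
#' @param isotope_ratio_range range of the satellite / monoisotopic
#'   intensity ratio.
#' @param noise_sd standard deviation of the additive baseline noise
#'   (intensity units).  When positive, spectra ride on a flat baseline of
#'   `5 * noise_sd` so that robust (median/MAD) noise estimation is
#'   well-posed; at 0 the trace is the noiseless forward model.
#' @param sigma_log standard deviation (log scale) of the per-replicate
#'   lognormal intensity jitter.
#' @param peak_sigma Gaussian peak width sigma in Da.
#' @param grid_step profile m/z grid spacing in Da.
#' @param min_ion_separation minimum distance between any two planted peak
#'   positions; must exceed `2 * match_tolerance` so that cross-modality
#'   matching of planted ions is unambiguous.
#' @param isotope_guard half-width of the exclusion zone around a
#'   1.00335 Da spacing between unrelated planted peaks, so that isotope
#'   flagging on synthetic data recovers exactly the planted satellites.
#' @param match_tolerance the cross-modality matching tolerance (Da) the
#'   panel must stay resolvable under.
#' @param base_meanlog,base_sdlog lognormal parameters of per-ion,
#'   per-modality base intensities (arbitrary units).
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_extract_ions = 83L,
                             n_ims_ions = 62L,
                             n_shared = 25L,
                             mz_range = c(600, 1300),
                             n_replicates = 6L,
                             groups = GROUP_LEVELS,
                             effect_mix = c(stable = 0.12,
                                            inhibited_sustained = 0.20,
                                            inhibited_progressive = 0.18,
                                            inhibited_transient = 0.10,
                                            stimulated_sustained = 0.16,
                                            stimulated_progressive = 0.14,
                                            stimulated_transient = 0.10),
                             recovery_fraction = 0.60,
                             isotope_prob = 0.20,
                             isotope_ratio_range = c(0.3, 0.6),
                             noise_sd = 1.0,
                             sigma_log = 0.15,
                             peak_sigma = 0.05,
                             grid_step = 0.01,
                             min_ion_separation = 0.6,
                             isotope_guard = 0.25,
                             match_tolerance = 0.25,
                             base_meanlog = log(150),
                             base_sdlog = 0.5,
                             seed = 1L) {
  cfg <- list(n_extract_ions = as.integer(n_extract_ions),
              n_ims_ions = as.integer(n_ims_ions),
              n_shared = as.integer(n_shared),
              mz_range = as.numeric(mz_range),
              n_replicates = as.integer(n_replicates),
              groups = as.character(groups),
              effect_mix = effect_mix,
              recovery_fraction = recovery_fraction,
              isotope_prob = isotope_prob,
              isotope_ratio_range = as.numeric(isotope_ratio_range),
              noise_sd = noise_sd,
              sigma_log = sigma_log,
              peak_sigma = peak_sigma,
              grid_step = grid_step,
              min_ion_separation = min_ion_separation,
              isotope_guard = isotope_guard,
              match_tolerance = match_tolerance,
              base_meanlog = base_meanlog,
              base_sdlog = base_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_extract_ions) || !is_count(n_ims_ions) ||
        !is_count(n_shared))
      mc_error("ion counts must be non-negative integers", "mc_config_error")
    if (n_shared > min(n_extract_ions, n_ims_ions))
      mc_error("n_shared must not exceed min(n_extract_ions, n_ims_ions)",
               "mc_config_error")
    if (length(mz_range) != 2L || diff(mz_range) <= 0)
      mc_error("mz_range must be an increasing interval", "mc_config_error")
    if (!is_count(n_replicates) || n_replicates < 1)
      mc_error("n_replicates must be a positive integer", "mc_config_error")
    if (length(groups) < 1L || groups[[1L]] != "A8")
      mc_error("groups must start with the A8 control", "mc_config_error")
    if (recovery_fraction < 0 || recovery_fraction > 1)
      mc_error("recovery_fraction must lie in [0, 1]", "mc_config_error")
    if (abs(sum(effect_mix) - 1) > 1e-8 || any(effect_mix < 0))
      mc_error("effect_mix must be non-negative and sum to 1",
               "mc_config_error")
    known <- c("stable", "inhibited_sustained", "inhibited_progressive",
               "inhibited_transient", "stimulated_sustained",
               "stimulated_progressive", "stimulated_transient")
    if (!all(names(effect_mix) %in% known))
      mc_error("effect_mix has unknown category names", "mc_config_error")
    if (isotope_prob < 0 || isotope_prob > 1)
      mc_error("isotope_prob must lie in [0, 1]", "mc_config_error")
    if (min_ion_separation <= 2 * match_tolerance)
      mc_error("min_ion_separation must exceed 2 * match_tolerance",
               "mc_config_error")
    if (noise_sd < 0 || sigma_log < 0 || peak_sigma <= 0 || grid_step <= 0)
      mc_error("noise/width parameters out of range", "mc_config_error")
  })
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d extract / %d IMS / %d shared ",
                     "ions, m/z %.0f-%.0f, %d groups x %d replicates, ",
                     "seed %d\n"),
              x$n_extract_ions, x$n_ims_ions, x$n_shared,
              x$mz_range[1], x$mz_range[2], length(x$groups),
              x$n_replicates, x$seed))
  invisible(x)
}
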