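# Synthetic study generator: plants an ion panel with modality membership,
# C13 satellites, group-response multipliers and base intensities, then
# renders profile spectra (sum of Gaussians + baseline noise) or idealized
# centroided peak lists for every group x replicate x modality cell.

# ---- interval arithmetic for collision-free ion placement ----------------

# ints: 2-column matrix of disjoint [lo, hi) intervals
subtract_interval <- function(ints, lo, hi) {
  if (!nrow(ints) || hi <= lo) return(ints)
  out <- vector("list", nrow(ints))
  for (r in seq_len(nrow(ints))) {
    a <- ints[r, 1]; b <- ints[r, 2]
    if (hi <= a || lo >= b) { out[[r]] <- c(a, b); next }
    keep <- NULL
    if (lo > a) keep <- rbind(keep, c(a, lo))
    if (hi < b) keep <- rbind(keep, c(hi, b))
    out[[r]] <- keep
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), ncol = 2) else res
}

# feasible positions for a new monoisotopic peak within `band`, given
# already-occupied peak positions; a satellite-carrying ion also reserves
# mz + 1.00335
feasible_intervals <- function(band, occupied, with_sat, cfg) {
  s <- cfg$min_ion_separation
  ring <- cfg$isotope_guard
  d <- C13_DELTA
  edge <- 0.3
  hi_cap <- cfg$mz_range[2] - edge - if (with_sat) d else 0
  lo <- max(band[1], cfg$mz_range[1] + edge)
  hi <- min(band[2], hi_cap)
  if (hi <= lo) return(matrix(numeric(0), ncol = 2))
  ints <- matrix(c(lo, hi), ncol = 2)
  for (p in occupied) {
    ints <- subtract_interval(ints, p - s, p + s)
    ints <- subtract_interval(ints, p + d - ring, p + d + ring)
    ints <- subtract_interval(ints, p - d - ring, p - d + ring)
    if (with_sat) {
      ints <- subtract_interval(ints, p - d - s, p - d + s)
      ints <- subtract_interval(ints, p - 2 * d - ring, p - 2 * d + ring)
    }
    if (!nrow(ints)) break
  }
  ints
}

sample_from_intervals <- function(ints) {
  lens <- ints[, 2] - ints[, 1]
  tot <- sum(lens)
  if (tot <= 0) return(NA_real_)
  i <- sample.int(nrow(ints), 1L, prob = lens)
  stats::runif(1, ints[i, 1], ints[i, 2])
}

# m/z bands encoding the modality detection bias: extracts favour low/mid
# m/z, IMS the high range; shared ions sit mostly mid-range
PANEL_BANDS <- list(low = c(600, 700), mid = c(700, 800), high = c(800, 1300))
BAND_WEIGHTS <- rbind(shared       = c(0.25, 0.50, 0.25),
                      extract_only = c(0.45, 0.40, 0.15),
                      ims_only     = c(0.10, 0.15, 0.75))
colnames(BAND_WEIGHTS) <- names(PANEL_BANDS)

place_one_ion <- function(membership, occupied, with_sat, cfg) {
  bands <- lapply(PANEL_BANDS, function(b)
    c(max(b[1], cfg$mz_range[1]), min(b[2], cfg$mz_range[2])))
  w <- BAND_WEIGHTS[membership, ]
  w[vapply(bands, function(b) b[2] <= b[1], logical(1))] <- 0
  while (any(w > 0)) {
    band_i <- sample.int(3L, 1L, prob = w)
    ints <- feasible_intervals(bands[[band_i]], occupied, with_sat, cfg)
    pos <- sample_from_intervals(ints)
    if (!is.na(pos)) return(pos)
    w[band_i] <- 0
  }
  mc_error(paste0("infeasible synthetic configuration: cannot place ",
                  "more ions at the requested separation in ",
                  sprintf("[%g, %g]", cfg$mz_range[1], cfg$mz_range[2])),
           "mc_config_error")
}

# ---- planted response multipliers ---------------------------------------

draw_recovery_label <- function(category, rf) {
  if (category == "stable") return(NA_character_)
  if (endsWith(category, "transient")) return("full")
  sample(c("full", "partial", "none", "paradoxical"), 1L,
         prob = c(rf / 3, 2 * rf / 3, (1 - rf) * 0.75, (1 - rf) * 0.25))
}

# multipliers (CS4, CS8, CS8+R) relative to the A8 control; drawn in the
# inhibitory orientation and inverted for stimulated categories, so the
# two directions are exact mirrors on the fold scale
draw_multipliers <- function(category, recovery) {
  if (category == "stable") return(c(1, 1, 1))
  parts <- strsplit(category, "_", fixed = TRUE)[[1L]]
  direction <- parts[[1L]]; progression <- parts[[2L]]
  if (progression == "sustained") {
    m8 <- stats::runif(1, 0.35, 0.50)
    m4 <- m8 * stats::runif(1, 0.90, 1.00)
  } else if (progression == "progressive") {
    m8 <- stats::runif(1, 0.35, 0.50)
    m4 <- m8 * stats::runif(1, 1.45, 1.70)
  } else {                               # transient
    m4 <- stats::runif(1, 0.45, 0.62)
    m8 <- stats::runif(1, 0.95, 1.05)
  }
  r <- switch(recovery,
              full = stats::runif(1, 0.90, 1.10),
              partial = m8 + (0.8 - m8) * stats::runif(1, 0.5, 0.8),
              none = m8 * stats::runif(1, 0.97, 1.03),
              paradoxical = m8 * stats::runif(1, 1 / 1.55, 1 / 1.40))
  m <- c(m4, m8, r)
  if (direction == "stimulated") m <- 1 / m
  m
}

# project base intensities onto the subspace where every exposure group's
# total planted intensity equals the control total, so that per-spectrum
# TIC normalization leaves planted fold changes intact
balance_bases <- function(b, mult) {
  D <- mult - 1
  keep <- colSums(abs(D)) > 1e-12
  D <- D[, keep, drop = FALSE]
  if (!ncol(D)) return(b)
  floor_b <- 1e-3 * stats::median(b)
  # intensity-weighted projection: minimizes the squared *relative*
  # perturbation, so corrections scale with each base and a planted
  # satellite keeps its exact intensity ratio to its parent
  for (i in 1:25) {
    BD <- b * D
    lam <- solve(crossprod(D, BD) + diag(1e-12, ncol(D)), crossprod(D, b))
    b2 <- b - as.numeric(BD %*% lam)
    if (all(b2 > floor_b)) return(b2)
    b <- pmax(b2, floor_b)
  }
  b
}

# ---- panel generation ----------------------------------------------------

#' Generate the planted ion panel for a synthetic study
#'
#' Places `n_extract_ions` + `n_ims_ions` - `n_shared` distinct ions in the
#' configured m/z window with modality-biased band sampling (shared ions
#' mid-range, IMS-only ions biased high, extract-only low/mid), enforcing
#' the minimum pairwise separation and an exclusion zone around accidental
#' 1.00335 Da spacings.  A fraction of panel slots is filled by C13
#' satellites of the preceding ion.  Every non-satellite ion receives a
#' response category, recovery label, group multipliers and per-modality
#' base intensities; satellites inherit their parent's category and
#' multipliers at a reduced intensity.
#'
#' @param config a [synthetic_config()].
#' @return A data.frame of class `planted_truth`; one row per panel ion
#'   with columns `ion_id`, `mz`, `membership`, `category`, `recovery`,
#'   `m_cs4`, `m_cs8`, `m_csr`, `base_extract`, `base_ims`,
#'   `is_satellite`, `parent_id`, `isotope_ratio`.
#' @export
generate_ion_panel <- function(config) {
  validate_synthetic_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    counts <- c(shared = config$n_shared,
                extract_only = config$n_extract_ions - config$n_shared,
                ims_only = config$n_ims_ions - config$n_shared)
    rows <- list(); occupied <- numeric(0)
    for (membership in names(counts)) {
      remaining <- counts[[membership]]
      while (remaining > 0) {
        with_sat <- remaining >= 2 &&
          stats::runif(1) < config$isotope_prob
        pos <- place_one_ion(membership, occupied, with_sat, config)
        rows[[length(rows) + 1L]] <-
          list(mz = pos, membership = membership, is_satellite = FALSE)
        occupied <- c(occupied, pos)
        remaining <- remaining - 1L
        if (with_sat) {
          rows[[length(rows) + 1L]] <-
            list(mz = pos + C13_DELTA, membership = membership,
                 is_satellite = TRUE)
          occupied <- c(occupied, pos + C13_DELTA)
          remaining <- remaining - 1L
        }
      }
    }
    n <- length(rows)
    truth <- data.frame(
      ion_id = sprintf("ion%03d", seq_len(n)),
      mz = vapply(rows, `[[`, numeric(1), "mz"),
      membership = vapply(rows, `[[`, character(1), "membership"),
      is_satellite = vapply(rows, `[[`, logical(1), "is_satellite"),
      stringsAsFactors = FALSE)
    truth$parent_id <- NA_character_
    truth$parent_id[truth$is_satellite] <-
      truth$ion_id[which(truth$is_satellite) - 1L]

    # response categories (satellites inherit from their parent)
    parents <- which(!truth$is_satellite)
    truth$category <- NA_character_
    truth$category[parents] <- sample(names(config$effect_mix),
                                      length(parents), replace = TRUE,
                                      prob = config$effect_mix)
    truth$recovery <- NA_character_
    mult <- matrix(1, n, 3, dimnames = list(NULL, c("m_cs4", "m_cs8", "m_csr")))
    for (i in parents) {
      truth$recovery[i] <- draw_recovery_label(truth$category[i],
                                               config$recovery_fraction)
      mult[i, ] <- draw_multipliers(truth$category[i], truth$recovery[i])
    }
    sat <- which(truth$is_satellite)
    if (length(sat)) {
      truth$category[sat] <- truth$category[sat - 1L]
      truth$recovery[sat] <- truth$recovery[sat - 1L]
      mult[sat, ] <- mult[sat - 1L, , drop = FALSE]
    }
    truth <- cbind(truth, as.data.frame(mult))

    # base intensities per modality; satellites at a C13-like ratio
    truth$isotope_ratio <- NA_real_
    truth$isotope_ratio[sat] <- stats::runif(length(sat),
                                             config$isotope_ratio_range[1],
                                             config$isotope_ratio_range[2])
    truth$base_extract <- NA_real_
    truth$base_ims <- NA_real_
    for (mod in c("extract", "ims")) {
      col <- paste0("base_", mod)
      member <- truth$membership %in%
        c("shared", paste0(mod, "_only"))
      pm <- member & !truth$is_satellite
      truth[[col]][pm] <- stats::rlnorm(sum(pm), config$base_meanlog,
                                        config$base_sdlog)
      ps <- member & truth$is_satellite
      truth[[col]][ps] <- truth$isotope_ratio[ps] *
        truth[[col]][match(truth$parent_id[ps], truth$ion_id)]
      # TIC balance: exposure-group totals equal the control total
      idx <- which(member)
      truth[[col]][idx] <- balance_bases(truth[[col]][idx],
                                         mult[idx, , drop = FALSE])
    }
    # record the realized satellite/parent ratio after balancing
    if (length(sat)) {
      pidx <- match(truth$parent_id[sat], truth$ion_id)
      truth$isotope_ratio[sat] <- ifelse(
        is.na(truth$base_extract[sat]),
        truth$base_ims[sat] / truth$base_ims[pidx],
        truth$base_extract[sat] / truth$base_extract[pidx])
    }
    structure(truth, config = config,
              class = c("planted_truth", "data.frame"))
  })
}

truth_for_modality <- function(truth, modality) {
  key <- if (modality == "IMS") "ims" else "extract"
  sub <- truth[truth$membership %in% c("shared", paste0(key, "_only")), ,
               drop = FALSE]
  sub$base <- sub[[paste0("base_", key)]]
  sub[order(sub$mz), , drop = FALSE]
}

group_multiplier <- function(truth_sub, group) {
  switch(group,
         "A8" = rep(1, nrow(truth_sub)),
         "CS4" = truth_sub$m_cs4,
         "CS8" = truth_sub$m_cs8,
         "CS8+R" = truth_sub$m_csr,
         mc_error(sprintf("unknown group label: %s", group),
                  "mc_config_error"))
}

spectrum_cell_seed <- function(config, group, replicate, modality) {
  gi <- match(group, GROUP_LEVELS)
  mi <- match(modality, MODALITY_LEVELS)
  derive_seed(config$seed, 1000L + gi * 100L + mi * 10L + replicate)
}

# per-replicate expected peak heights (before baseline noise)
replicate_heights <- function(truth, group, replicate, modality, config) {
  sub <- truth_for_modality(truth, modality)
  mult <- group_multiplier(sub, group)
  with_seed(spectrum_cell_seed(config, group, replicate, modality), {
    jitter <- if (config$sigma_log > 0)
      stats::rlnorm(nrow(sub), 0, config$sigma_log) else rep(1, nrow(sub))
    list(mz = sub$mz, height = sub$base * mult * jitter,
         noise_seed = derive_seed(spectrum_cell_seed(config, group,
                                                     replicate, modality),
                                  2L))
  })
}

#' Render one synthetic profile spectrum
#'
#' Forward model: a sum of Gaussian peaks (width `peak_sigma`) at the
#' planted m/z positions of the requested modality, with heights equal to
#' base intensity x group multiplier x per-replicate lognormal jitter,
#' on top of a flat baseline (`5 * noise_sd`) with additive Gaussian noise
#' clipped at zero.  Deterministic given identical arguments.
#'
#' @param truth a `planted_truth` from [generate_ion_panel()].
#' @param group group label (one of A8, CS4, CS8, CS8+R).
#' @param replicate replicate index (1-based).
#' @param modality `"extract"` or `"IMS"`.
#' @param config the [synthetic_config()] used for the panel.
#' @return A [profile_spectrum()].
#' @export
generate_profile_spectrum <- function(truth, group, replicate, modality,
                                      config) {
  if (!group %in% config$groups)
    mc_error(sprintf("unknown group label: %s", group), "mc_config_error")
  if (!modality %in% MODALITY_LEVELS)
    mc_error(sprintf("unknown modality label: %s", modality),
             "mc_config_error")
  hp <- replicate_heights(truth, group, replicate, modality, config)
  grid <- seq(config$mz_range[1], config$mz_range[2], by = config$grid_step)
  signal <- numeric(length(grid))
  sigma <- config$peak_sigma
  half <- ceiling(6 * sigma / config$grid_step)
  for (i in seq_along(hp$mz)) {
    centre <- round((hp$mz[i] - config$mz_range[1]) / config$grid_step) + 1L
    idx <- max(1L, centre - half):min(length(grid), centre + half)
    signal[idx] <- signal[idx] +
      hp$height[i] * exp(-(grid[idx] - hp$mz[i])^2 / (2 * sigma^2))
  }
  if (config$noise_sd > 0) {
    with_seed(hp$noise_seed, {
      signal <- signal + 5 * config$noise_sd +
        stats::rnorm(length(grid), 0, config$noise_sd)
    })
  }
  profile_spectrum(grid, pmax(signal, 0),
                   sample_id = sample_cell_id(group, replicate, modality),
                   modality = modality)
}

# idealized centroided output of the same forward model (no profile
# rendering, no baseline): exact planted positions, jittered heights
generate_replicate_peaklist <- function(truth, group, replicate, modality,
                                        config) {
  hp <- replicate_heights(truth, group, replicate, modality, config)
  peak_list(hp$mz, hp$height,
            sample_id = sample_cell_id(group, replicate, modality),
            modality = modality)
}

sample_cell_id <- function(group, replicate, modality) {
  sprintf("%s_%s_r%02d", modality, gsub("+", "p", group, fixed = TRUE),
          replicate)
}

#' Generate a complete synthetic study
#'
#' Emits one data cell per group x replicate x modality (48 cells under
#' the default four-group, six-replicate design), a sample manifest, and
#' the planted truth.  With `dir = NULL` everything is returned in memory;
#' otherwise spectra/peak lists are written as two-column tabular text
#' files, the manifest as TSV, and the truth and configuration as JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @param format `"profile"` (rendered spectra; the default) or
#'   `"peaklist"` (idealized centroided lists, skipping profile rendering).
#' @return A list of class `synthetic_study` with elements `truth`,
#'   `manifest`, `data` (named list keyed by `sample_id`), `config`,
#'   `format`.
#' @export
generate_study <- function(config, dir = NULL,
                           format = c("profile", "peaklist")) {
  format <- match.arg(format)
  truth <- generate_ion_panel(config)
  cells <- expand.grid(replicate = seq_len(config$n_replicates),
                       group = config$groups,
                       modality = MODALITY_LEVELS,
                       stringsAsFactors = FALSE)
  gen <- if (format == "profile") generate_profile_spectrum else
    generate_replicate_peaklist
  data <- vector("list", nrow(cells))
  ids <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ids[i] <- sample_cell_id(cells$group[i], cells$replicate[i],
                             cells$modality[i])
    data[[i]] <- gen(truth, cells$group[i], cells$replicate[i],
                     cells$modality[i], config)
  }
  names(data) <- ids
  manifest <- data.frame(sample_id = ids,
                         group = cells$group,
                         replicate = cells$replicate,
                         modality = cells$modality,
                         path = paste0(ids, ".tsv"),
                         stringsAsFactors = FALSE)
  study <- structure(list(truth = truth, manifest = manifest, data = data,
                          config = config, format = format),
                     class = "synthetic_study")
  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                        showWarnings = FALSE)
    if (!ok) mc_error(sprintf("cannot create output directory: %s", dir),
                      "mc_io_error")
    writer <- if (format == "profile") write_profile_spectrum else
      write_peaklist
    for (i in seq_along(data))
      writer(data[[i]], file.path(dir, manifest$path[i]))
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    tr <- as.data.frame(truth)
    jsonlite::write_json(tr, file.path(dir, "planted_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d ions, %d sample cells (%s)\n",
              nrow(x$truth), nrow(x$manifest), x$format))
  invisible(x)
}
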