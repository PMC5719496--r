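#' Pipeline configuration
#'
#' Single configuration object governing an end-to-end run: data source
#' (a sample manifest of spectra/peak list files, or a
#' [synthetic_config()] to simulate), analysis window, and all stage
#' parameters.
#'
#' @param manifest path to a sample manifest (see [read_manifest()]);
#'   mutually exclusive with `synthetic`.
#' @param synthetic a [synthetic_config()]; the default simulates the
#'   standard study design.
#' @param input_format `"profile"` (peak picking applied) or
#'   `"peaklist"` (files/cells already centroided).
#' @param snr_threshold,window peak-picking parameters.
#' @param mz_min,mz_max analysis m/z window, Da.
#' @param cluster_tol,min_frequency replicate aggregation parameters.
#' @param match_tolerance cross-modality matching tolerance, Da.
#' @param isotope_tol,max_isotope_ratio isotope-flagging parameters.
#' @param change_threshold,progress_threshold response-pattern
#'   thresholds.
#' @param responsive_fold,stable_band diagnostic-ion thresholds.
#' @param linkage,k_clusters hierarchical clustering linkage and
#'   dendrogram cut size (per modality).
#' @param n_components PCA components to retain.
#' @param out_dir optional output directory for reports.
#' @param verbose emit per-stage progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL,
                            synthetic = synthetic_config(),
                            input_format = c("profile", "peaklist"),
                            snr_threshold = 3, window = 0.1,
                            mz_min = 600, mz_max = 1300,
                            cluster_tol = 0.25, min_frequency = 0.5,
                            match_tolerance = 0.25,
                            isotope_tol = 0.1, max_isotope_ratio = 1.0,
                            change_threshold = 1.25,
                            progress_threshold = 1.15,
                            responsive_fold = 2, stable_band = 1.25,
                            linkage = "complete", k_clusters = 6,
                            n_components = 3,
                            out_dir = NULL, verbose = TRUE) {
  cfg <- list(manifest = manifest, synthetic = synthetic,
              input_format = match.arg(input_format),
              snr_threshold = snr_threshold, window = window,
              mz_min = mz_min, mz_max = mz_max,
              cluster_tol = cluster_tol, min_frequency = min_frequency,
              match_tolerance = match_tolerance,
              isotope_tol = isotope_tol,
              max_isotope_ratio = max_isotope_ratio,
              change_threshold = change_threshold,
              progress_threshold = progress_threshold,
              responsive_fold = responsive_fold,
              stable_band = stable_band,
              linkage = linkage, k_clusters = k_clusters,
              n_components = n_components,
              out_dir = out_dir, verbose = verbose)
  if (any(c(cfg$snr_threshold, cfg$window, cfg$cluster_tol,
            cfg$match_tolerance, cfg$isotope_tol) <= 0))
    mc_error("tolerances and thresholds must be positive",
             "mc_config_error")
  if (cfg$mz_max <= cfg$mz_min)
    mc_error("mz_max must exceed mz_min", "mc_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(paste0("[pipeline] ", fmt), ...))
}

# load or simulate the per-cell data; returns list(manifest, data)
pipeline_ingest <- function(cfg) {
  if (!is.null(cfg$manifest)) {
    m <- read_manifest(cfg$manifest)
    reader <- if (cfg$input_format == "profile") read_profile_spectrum else
      read_peaklist
    data <- lapply(seq_len(nrow(m)), function(i)
      reader(m$path[i], sample_id = m$sample_id[i],
             modality = m$modality[i]))
    names(data) <- m$sample_id
    list(manifest = m, data = data, truth = NULL)
  } else {
    study <- generate_study(cfg$synthetic, format = cfg$input_format)
    list(manifest = study$manifest, data = study$data,
         truth = study$truth)
  }
}

#' Run the full comparative analysis pipeline
#'
#' Composes all stages: ingest or simulate -> peak picking (profile
#' input) -> TIC normalization -> replicate aggregation per group and
#' modality -> cross-modality matching on the per-modality ion unions ->
#' isotope flagging -> concordance classification -> detection summary ->
#' intensity matrices, row z-scoring, hierarchical clustering and PCA per
#' modality -> response-pattern classification and diagnostic-ion calls.
#' Conservation identities (total = extract + IMS - shared; category
#' tallies partition the shared set) are enforced before any output is
#' written.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `summary`
#'   (machine-readable run summary), `detection`, `concordance`,
#'   `patterns` (per modality), `clustering`, `pca`, `diagnostic`,
#'   `consensus`, `truth` (for synthetic runs), `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    mc_error("run_pipeline expects a pipeline_config", "mc_config_error")
  ing <- pipeline_ingest(config)
  manifest <- ing$manifest
  groups <- intersect(GROUP_LEVELS, unique(manifest$group))
  modalities <- intersect(MODALITY_LEVELS, unique(manifest$modality))
  pipe_log(config, "ingested %d cells (%d groups x %d modalities)",
           nrow(manifest), length(groups), length(modalities))

  # pick + normalize per cell
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    mc_error(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
             "mc_stage_error"))
  peaklists <- stage("peak picking/normalization", {
    lapply(ing$data, function(cell) {
      pl <- if (inherits(cell, "profile_spectrum"))
        pick_peaks(cell, config$snr_threshold, config$window,
                   config$mz_min, config$mz_max) else cell
      tic_normalize(pl)
    })
  })

  # consensus per group x modality
  consensus <- list()
  for (mod in modalities) for (g in groups) {
    ids <- manifest$sample_id[manifest$group == g &
                                manifest$modality == mod]
    consensus[[mod]][[g]] <- stage(
      sprintf("aggregation %s/%s", mod, g),
      aggregate_replicates(peaklists[ids], config$cluster_tol,
                           config$min_frequency, group = g))
  }
  pipe_log(config, "aggregated consensus peak lists")

  # per-modality ion union across groups, with A8 intensities for matching
  profiles <- lapply(modalities, function(mod)
    group_profiles(consensus[[mod]], config$cluster_tol))
  names(profiles) <- modalities

  result <- list(consensus = consensus, profiles = profiles,
                 truth = ing$truth, config = config)

  if (all(c("extract", "IMS") %in% modalities)) {
    union_list <- lapply(modalities, function(mod) {
      pr <- profiles[[mod]]
      gcols <- intersect(c(groups, "CS8.R"), names(pr))
      peak_list(pr$mz, rowMeans(pr[, gcols, drop = FALSE]),
                modality = mod, normalized = FALSE)
    })
    names(union_list) <- modalities
    # matched on the union of ions; concordance intensities from A8
    match <- stage("cross-modality matching",
                   match_peaklists(union_list$extract, union_list$IMS,
                                   config$match_tolerance))
    a8_int <- function(mod, mzs) {
      pr <- profiles[[mod]]
      pr$A8[vapply(mzs, function(m) which.min(abs(pr$mz - m)), integer(1))]
    }
    conc_pairs <- match$pairs
    conc_pairs$extract_intensity <- a8_int("extract",
                                           conc_pairs$extract_mz)
    conc_pairs$ims_intensity <- a8_int("IMS", conc_pairs$ims_mz)
    pos <- conc_pairs$extract_intensity > 0 & conc_pairs$ims_intensity > 0
    match_conc <- match; match_conc$pairs <- conc_pairs[pos, , drop = FALSE]
    records <- stage("concordance classification",
                     concordance_records(match_conc,
                                         extract = union_list$extract,
                                         ims = union_list$IMS,
                                         isotope_tol = config$isotope_tol,
                                         max_ratio = config$max_isotope_ratio))
    detection <- summarize_detection(match)
    tallies <- table(factor(records$category,
                            levels = names(CATEGORY_GLYPHS)))
    stopifnot(detection$total ==
                detection$n_extract + detection$n_ims - detection$shared,
              sum(tallies) == nrow(records))
    result$match <- match
    result$concordance <- records
    result$detection <- detection
    pipe_log(config,
             "matched: %d total / %d extract / %d IMS / %d shared",
             detection$total, detection$n_extract, detection$n_ims,
             detection$shared)
  } else {
    pipe_log(config, "single modality present; matching skipped")
  }

  # multivariate per modality: ion x group z-scores, clustering, PCA
  result$clustering <- list(); result$pca <- list()
  for (mod in modalities) {
    pr <- profiles[[mod]]
    gcols <- setdiff(names(pr), "mz")
    mat <- as.matrix(pr[, gcols, drop = FALSE])
    rownames(mat) <- sprintf("%.4f", pr$mz)
    if (length(gcols) >= 2 && nrow(mat) >= 2) {
      z <- suppressWarnings(zscore_rows(mat))
      dend <- hierarchical_cluster(z, config$linkage)
      k <- min(config$k_clusters, nrow(mat))
      result$clustering[[mod]] <-
        list(dendrogram = dend, clusters = cut_dendrogram(dend, k))
    }
    # PCA at sample level: observations are replicates, variables ions
    ids <- manifest$sample_id[manifest$modality == mod]
    smat <- build_intensity_matrix(peaklists[ids], config$cluster_tol)
    if (nrow(smat) >= 2 && length(ids) >= 3)
      result$pca[[mod]] <- tryCatch(
        suppressWarnings(
          pca(t(smat), n_components = min(config$n_components,
                                          length(ids) - 1, nrow(smat)))),
        mc_config_error = function(e) {    # e.g. rank-deficient input
          pipe_log(config, "PCA skipped for %s: %s", mod,
                   conditionMessage(e))
          NULL
        })
  }

  # response patterns per modality (needs the full 4-group design)
  if (all(GROUP_LEVELS %in% groups)) {
    result$patterns <- list(); result$diagnostic <- list()
    rec_frac <- list()
    for (mod in modalities) {
      pr <- profiles[[mod]]
      pr <- pr[pr$A8 > 0, , drop = FALSE]
      pat <- stage(sprintf("response classification %s", mod),
                   classify_responses(pr, config$change_threshold,
                                      config$progress_threshold))
      result$patterns[[mod]] <- pat
      shared_mz <- if (!is.null(result$match))
        (result$match$pairs$extract_mz + result$match$pairs$ims_mz) / 2
      result$diagnostic[[mod]] <-
        identify_diagnostic_ions(pat, shared_mz = shared_mz,
                                 responsive_fold = config$responsive_fold,
                                 stable_band = config$stable_band)
      supp <- pat$direction == "inhibited" & pat$progression != "transient"
      rec_frac[[mod]] <- if (any(supp)) recovery_fraction(pat) else NA_real_
    }
    result$recovery <- rec_frac
  } else {
    pipe_log(config,
             "incomplete group design; response-pattern stage skipped")
  }

  result$summary <- pipeline_summary(result)
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

pipeline_summary <- function(result) {
  s <- list(schema_version = "1.0")
  if (!is.null(result$detection)) {
    d <- result$detection
    s$detection <- list(total = d$total, n_extract = d$n_extract,
                        n_ims = d$n_ims, shared = d$shared,
                        extract_only = d$extract_only,
                        ims_only = d$ims_only,
                        shared_of_total = d$shared_of_total,
                        shared_of_sum = d$shared_of_sum)
    s$concordance_tallies <-
      as.list(table(factor(result$concordance$category,
                           levels = names(CATEGORY_GLYPHS))))
  }
  if (!is.null(result$recovery))
    s$recovery_fraction <- result$recovery
  if (!is.null(result$diagnostic))
    s$diagnostic <- lapply(result$diagnostic, function(d)
      list(responsive_mz = round(d$responsive$mz, 4),
           stable_mz = round(d$stable$mz, 4)))
  cfg <- result$config
  s$provenance <- list(
    package_version = as.character(utils::packageVersion("maldiconcord")),
    seed = if (is.null(cfg$manifest)) cfg$synthetic$seed else NULL,
    parameters = cfg[setdiff(names(cfg),
                             c("manifest", "synthetic", "out_dir",
                               "verbose"))])
  s
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) mc_error(sprintf("cannot create output directory: %s", dir),
                    "mc_io_error")
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(result$concordance))
    write_concordance_report(result$concordance,
                             file.path(dir, "concordance.tsv"))
  for (mod in names(result$patterns %||% list()))
    write_pattern_table(result$patterns[[mod]],
                        file.path(dir, sprintf("patterns_%s.tsv", mod)))
  for (mod in names(result$clustering %||% list())) {
    cl <- result$clustering[[mod]]$clusters
    utils::write.table(data.frame(ion = names(cl), cluster = cl),
                       file.path(dir, sprintf("clusters_%s.tsv", mod)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (mod in names(result$pca %||% list()))
    utils::write.table(
      data.frame(sample = rownames(result$pca[[mod]]$scores),
                 result$pca[[mod]]$scores),
      file.path(dir, sprintf("pca_scores_%s.tsv", mod)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$detection)) print(x$detection)
  if (!is.null(x$recovery))
    for (mod in names(x$recovery))
      cat(sprintf("  recovery fraction (%s): %s\n", mod,
                  ifelse(is.na(x$recovery[[mod]]), "n/a",
                         sprintf("%.1f%%", 100 * x$recovery[[mod]]))))
  invisible(x)
}
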