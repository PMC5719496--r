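# Exposure/withdrawal response taxonomy: worked examples, invariances,
# planted-truth recovery, and diagnostic-ion calls.

test_that("worked trajectory examples classify as described", {
  r <- classify_response(c(100, 50, 50, 50))
  expect_identical(r$direction, "inhibited")
  expect_identical(r$progression, "sustained")
  expect_identical(r$recovery, "none")

  r <- classify_response(c(100, 70, 40, 80))
  expect_identical(r$direction, "inhibited")
  expect_identical(r$progression, "progressive")
  expect_identical(r$recovery, "partial")

  r <- classify_response(c(100, 100, 100, 100))
  expect_identical(r$direction, "unchanged")
  expect_identical(r$progression, "n/a")
  expect_identical(r$recovery, "n/a")

  # transient: changed at CS4, back in the band by CS8
  r <- classify_response(c(100, 55, 100, 100))
  expect_identical(r$direction, "inhibited")
  expect_identical(r$progression, "transient")
  # stimulated mirror with paradoxical overshoot after withdrawal
  r <- classify_response(c(100, 180, 180, 260))
  expect_identical(r$direction, "stimulated")
  expect_identical(r$progression, "sustained")
  expect_identical(r$recovery, "paradoxical")
  # full normalization after withdrawal
  r <- classify_response(c(100, 50, 40, 100))
  expect_identical(r$recovery, "full")
})

test_that("classification contracts and degenerate inputs", {
  expect_error(classify_response(c(0, 1, 1, 1)),
               class = "mc_degenerate_input")
  expect_error(classify_response(c(1, 1, 1)), class = "mc_degenerate_input")
  expect_error(classify_response(c(1, 1, 1, 1), change_threshold = 1),
               class = "mc_config_error")
})

test_that("classification is invariant to global rescaling", {
  withr::with_seed(8, {
    for (rep in 1:50) {
      means <- stats::rlnorm(4, 0, 0.7)
      base <- classify_response(means)
      for (c_scale in c(1e-4, 0.3, 7, 1e5)) {
        scaled <- classify_response(means * c_scale)
        expect_identical(scaled$direction, base$direction)
        expect_identical(scaled$progression, base$progression)
        expect_identical(scaled$recovery, base$recovery)
      }
    }
  })
})

test_that("the taxonomy is exhaustive and exclusive on positive profiles", {
  withr::with_seed(14, {
    for (rep in 1:200) {
      r <- classify_response(stats::rlnorm(4, 0, 0.8))
      expect_true(r$direction %in% c("inhibited", "stimulated", "unchanged"))
      if (r$direction == "unchanged") {
        expect_identical(r$progression, "n/a")
        expect_identical(r$recovery, "n/a")
      } else {
        expect_true(r$progression %in%
                      c("sustained", "progressive", "transient"))
        expect_true(r$recovery %in%
                      c("full", "partial", "none", "paradoxical"))
      }
    }
  })
})

test_that("recovery fractions count partial-or-full recoveries", {
  pat <- data.frame(direction = rep("inhibited", 10),
                    progression = rep("sustained", 10),
                    recovery = c(rep("partial", 4), rep("full", 2),
                                 rep("none", 3), "paradoxical"))
  expect_equal(recovery_fraction(pat), 0.6)
  pat$recovery <- "none"
  expect_equal(recovery_fraction(pat), 0)
  expect_error(recovery_fraction(pat, subset = rep(FALSE, 10)),
               class = "mc_degenerate_input")
})

test_that("planted categories are recovered perfectly at zero noise", {
  for (seed in 1:3) {
    cfg <- synthetic_config(noise_sd = 0, sigma_log = 0, seed = seed)
    study <- generate_study(cfg, format = "peaklist")
    truth <- study$truth
    ims_ids <- study$manifest[study$manifest$modality == "IMS", ]
    cons <- lapply(split(ims_ids$sample_id, ims_ids$group), function(ids)
      aggregate_replicates(lapply(study$data[ids], tic_normalize)))
    pat <- classify_responses(
      group_profiles(cons[c("A8", "CS4", "CS8", "CS8+R")]))
    tr <- truth[truth$membership %in% c("shared", "ims_only"), ]
    tr <- tr[order(tr$mz), ]
    expect_identical(nrow(pat), nrow(tr))
    got <- ifelse(pat$direction == "unchanged", "stable",
                  paste(pat$direction, pat$progression, sep = "_"))
    expect_identical(got, tr$category)
    # recovery axis also exact at zero noise for persistent responses
    persist <- !grepl("transient", tr$category) & tr$category != "stable"
    expect_identical(pat$recovery[persist], tr$recovery[persist])
  }
})

test_that("planted categories are recovered >= 90% at default noise", {
  hits <- c(); total <- c()
  for (seed in 1:20) {
    cfg <- synthetic_config(seed = seed)   # sigma_log 0.15, n = 6
    study <- generate_study(cfg, format = "peaklist")
    truth <- study$truth
    ims_ids <- study$manifest[study$manifest$modality == "IMS", ]
    cons <- lapply(split(ims_ids$sample_id, ims_ids$group), function(ids)
      aggregate_replicates(lapply(study$data[ids], tic_normalize)))
    cons <- cons[c("A8", "CS4", "CS8", "CS8+R")]
    pat <- classify_responses(group_profiles(cons))
    tr <- truth[truth$membership %in% c("shared", "ims_only"), ]
    tr <- tr[order(tr$mz), ]
    idx <- vapply(pat$mz, function(m) which.min(abs(tr$mz - m)), integer(1))
    ok <- abs(tr$mz[idx] - pat$mz) < 0.3
    got <- ifelse(pat$direction == "unchanged", "stable",
                  paste(pat$direction, pat$progression, sep = "_"))
    agree <- got[ok] == tr$category[idx[ok]]
    by_cat <- split(agree, tr$category[idx[ok]])
    hits <- c(hits, vapply(by_cat, sum, numeric(1)))
    total <- c(total, vapply(by_cat, length, numeric(1)))
  }
  rates <- tapply(hits, names(hits), sum) / tapply(total, names(total), sum)
  expect_true(all(rates >= 0.90))
})

test_that("diagnostic and internal-control calls mirror the planted truth", {
  cfg <- synthetic_config(noise_sd = 0, sigma_log = 0, seed = 6)
  res <- run_pipeline(pipeline_config(synthetic = cfg, verbose = FALSE))
  truth <- res$truth
  shared_tr <- truth[truth$membership == "shared", ]
  shared_tr <- shared_tr[order(shared_tr$mz), ]
  diag <- res$diagnostic$IMS
  # planted stable shared ions are exactly the stable set
  expect_setequal(round(diag$stable$mz, 2),
                  round(shared_tr$mz[shared_tr$category == "stable"], 2))
  # persistently suppressed/stimulated shared ions are responsive
  strong <- pmax(shared_tr$m_cs8, 1 / shared_tr$m_cs8) >= 2
  expect_setequal(round(diag$responsive$mz, 2),
                  round(shared_tr$mz[strong], 2))
  expect_length(intersect(diag$responsive$mz, diag$stable$mz), 0)
})
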