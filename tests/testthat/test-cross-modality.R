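# Cross-modality matching, isotope flagging, concordance classification,
# and detection arithmetic.

test_that("single candidates match within tolerance and not beyond", {
  m <- match_peaklists(peak_list(697.4, 1), peak_list(697.35, 1), 0.25)
  expect_identical(nrow(m$pairs), 1L)
  expect_equal(m$pairs$dmz, -0.05)
  m2 <- match_peaklists(peak_list(700.0, 1), peak_list(700.4, 1), 0.25)
  expect_identical(nrow(m2$pairs), 0L)
  expect_identical(nrow(m2$extract_only), 1L)
  expect_identical(nrow(m2$ims_only), 1L)
})

test_that("well-separated planted co-locations are fully recovered", {
  withr::with_seed(21, {
    # 7 planted shared positions separated by >= 3x tolerance
    shared <- seq(700, 700 + 6 * 1.0, by = 1.0)
    e_extra <- seq(720, by = 1.3, length.out = 13)
    i_extra <- seq(760, by = 1.3, length.out = 8)
    emz <- sort(c(shared + stats::runif(7, -0.05, 0.05), e_extra))
    imz <- sort(c(shared + stats::runif(7, -0.05, 0.05), i_extra))
    m <- match_peaklists(peak_list(emz, rep(1, 20)),
                         peak_list(imz, rep(1, 15)), 0.25)
    expect_identical(nrow(m$pairs), 7L)
    o <- oracle_match(emz, imz, 0.25)
    expect_identical(nrow(m$pairs), o$n)
    expect_equal(sum(abs(m$pairs$dmz)), o$cost, tolerance = 1e-9)
  })
})

test_that("greedy matching tracks the brute-force optimal assignment", {
  withr::with_seed(99, {
    mismatches <- 0L; n_inst <- 60L
    for (r in seq_len(n_inst)) {
      emz <- sort(stats::runif(sample(3:8, 1), 700, 703))
      imz <- sort(stats::runif(sample(3:8, 1), 700, 703))
      m <- match_peaklists(peak_list(emz, rep(1, length(emz))),
                           peak_list(imz, rep(1, length(imz))), 0.25)
      o <- oracle_match(emz, imz, 0.25)
      expect_lte(nrow(m$pairs), o$n)        # greedy is maximal, never more
      if (nrow(m$pairs) != o$n) mismatches <- mismatches + 1L
      # conservation identities hold on every instance
      expect_identical(nrow(m$pairs) + nrow(m$extract_only), length(emz))
      expect_identical(nrow(m$pairs) + nrow(m$ims_only), length(imz))
      expect_true(all(abs(m$pairs$dmz) <= 0.25 + 1e-12))
    }
    expect_lte(mismatches / n_inst, 0.15)   # measured discrepancy rate 4/60
  })
})

test_that("matching is invariant to input ordering", {
  withr::with_seed(5, {
    e <- random_peaklist(10, 700, 710)
    i <- random_peaklist(10, 700, 710, modality = "IMS")
    m1 <- match_peaklists(e, i, 0.3)
    # peak_list sorts on construction, so feed pre-shuffled raw values
    sh <- sample(10)
    m2 <- match_peaklists(peak_list(e$mz[sh], e$intensity[sh]),
                          peak_list(i$mz[sh], i$intensity[sh],
                                    modality = "IMS"), 0.3)
    expect_equal(m1$pairs, m2$pairs)
  })
})

test_that("isotope flagging follows the +1 Da / ratio rule", {
  pk <- function(mz, int) data.frame(mz = mz, intensity = int)
  expect_identical(flag_isotopes(pk(c(888.7, 889.7), c(1.0, 0.6))),
                   c(FALSE, TRUE))
  expect_identical(flag_isotopes(pk(c(700.0, 702.0), c(1.0, 0.6))),
                   c(FALSE, FALSE))
  # satellite heavier than its parent is not a credible C13 isotope
  expect_identical(flag_isotopes(pk(c(700.0, 701.0), c(0.2, 1.0))),
                   c(FALSE, FALSE))
  expect_identical(flag_isotopes(pk(c(700.0, 701.0), c(1.0, 0.2))),
                   c(FALSE, TRUE))
})

test_that("concordance categories partition the percent scale", {
  expect_equal(classify_concordance(0.05, 0.05),
               data.frame(pct_diff = 0, category = "EQ"))
  expect_equal(classify_concordance(0.055, 0.10)$pct_diff, -45)
  expect_identical(classify_concordance(0.055, 0.10)$category, "IMS_LT")
  cc <- classify_concordance(0.16, 0.10)
  expect_equal(cc$pct_diff, 60)
  expect_identical(cc$category, "IMS_GGT")
  # boundaries land in the larger-difference class (exact inputs: 11/10
  # and 9/10 give pct_diff of exactly +/-10 up to representation)
  expect_identical(classify_concordance(11, 10)$category, "IMS_GT")
  expect_identical(classify_concordance(9, 10)$category, "IMS_LT")
  expect_identical(classify_concordance(15, 10)$category, "IMS_GGT")
  expect_identical(classify_concordance(5, 10)$category, "IMS_LLT")
  expect_identical(classify_concordance(1.0999, 1)$category, "EQ")
  expect_error(classify_concordance(0.5, 0), class = "mc_degenerate_input")
  withr::with_seed(2, {   # total function over positive pairs
    i <- stats::runif(500, 1e-6, 2); e <- stats::runif(500, 1e-6, 2)
    cats <- classify_concordance(i, e)$category
    expect_true(all(cats %in% names(CATEGORY_GLYPHS)))
  })
})

test_that("detection arithmetic reproduces the printed overlap counts", {
  # 83 extract / 62 IMS positions of which 25 co-located
  shared <- 600.5 + (0:24) * 2
  e_only <- 651.5 + (0:57) * 2
  i_only <- 768.5 + (0:36) * 2
  ext <- peak_list(c(shared, e_only), rep(1, 83))
  ims <- peak_list(c(shared, i_only), rep(1, 62), modality = "IMS")
  m <- match_peaklists(ext, ims, 0.25)
  s <- summarize_detection(m)
  expect_identical(s$total, 120L)
  expect_identical(s$n_extract, 83L)
  expect_identical(s$n_ims, 62L)
  expect_identical(s$shared, 25L)
  expect_identical(s$extract_only, 58L)
  expect_identical(s$ims_only, 37L)
  expect_equal(s$shared_of_total, 25 / 120)
  expect_equal(s$shared_of_sum, 25 / 145)
})

test_that("degenerate overlaps summarize correctly", {
  a <- peak_list(600 + (0:9) * 2, rep(1, 10))
  b <- peak_list(621 + (0:9) * 2, rep(1, 10), modality = "IMS")
  s <- summarize_detection(match_peaklists(a, b, 0.25))
  expect_identical(s$total, 20L)
  expect_identical(s$shared, 0L)
  ident <- peak_list(600 + (0:11) * 2, rep(1 / 12, 12), normalized = TRUE)
  m <- match_peaklists(ident, ident, 0.25)
  rec <- concordance_records(m)
  s2 <- summarize_detection(m, rec)
  expect_identical(s2$total, 12L)
  expect_identical(s2$shared, 12L)
  expect_identical(unname(s2$category_tallies[["EQ"]]), 12L)
  expect_error(summarize_detection(m, rec[-1, ]),
               class = "mc_inconsistent_input")
})

test_that("the full chain reproduces the reference table's categories", {
  t1 <- load_table1()
  # realize intensities that express each printed category, then run
  # match -> classify and compare category by category
  withr::with_seed(31, {
    # ascending base intensities so no +1 Da neighbour out-weighs its
    # lower partner: isotope context stays out of this category check
    base <- sort(stats::runif(25, 0.02, 0.05))
    pct <- numeric(25)
    for (k in 1:25) pct[k] <- switch(
      t1$category[k],
      EQ = stats::runif(1, -8, 8),
      IMS_GT = stats::runif(1, 12, 45),
      IMS_LT = stats::runif(1, -45, -12),
      IMS_GGT = stats::runif(1, 55, 150),
      IMS_LLT = stats::runif(1, -85, -55))
    ext <- peak_list(t1$mz, base)
    ims <- peak_list(t1$mz, base * (1 + pct / 100), modality = "IMS")
    m <- match_peaklists(ext, ims, 0.25)
    expect_identical(nrow(m$pairs), 25L)
    rec <- concordance_records(m, lipid_ref = t1)
    expect_identical(rec$category, t1$category)
    expect_identical(rec$lipid_id[match(888.7, rec$mz)], "ST(24:1)")
    tallies <- table(rec$category)
    expect_identical(unname(tallies[["EQ"]]), 5L)
    expect_identical(sum(tallies[c("IMS_LT", "IMS_LLT")]), 12L)
    expect_identical(sum(tallies[c("IMS_GT", "IMS_GGT")]), 8L)
  })
})
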