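# Row z-scoring, agglomerative clustering vs brute-force oracles,
# dendrogram cutting, and PCA vs an independent eigen-decomposition.

test_that("row z-scores have the closed-form and moment properties", {
  expect_equal(as.numeric(zscore_rows(matrix(1:3, 1))), c(-1, 0, 1))
  expect_warning(z0 <- zscore_rows(matrix(5, 1, 3)), "constant")
  expect_equal(as.numeric(z0), c(0, 0, 0))
  withr::with_seed(4, {
    m <- matrix(stats::rlnorm(80), 20, 4)
    z <- zscore_rows(m)
    expect_true(all(abs(rowMeans(z)) < 1e-9))
    expect_true(all(abs(apply(z, 1, stats::sd) - 1) < 1e-9))
    expect_equal(zscore_rows(z), z, tolerance = 1e-9)   # idempotent
  })
  expect_error(zscore_rows(matrix(1, 3, 1)), class = "mc_degenerate_input")
})

test_that("nearest rows merge first and heights behave", {
  m <- matrix(c(0, 1, 10), 3, 1)
  d <- hierarchical_cluster(m)
  expect_equal(d$merge[1, ], c(-2, -1))
  expect_equal(d$height[1], 1)
  expect_equal(d$height[2], 10)
  same <- hierarchical_cluster(matrix(1, 4, 2))
  expect_true(all(same$height == 0))
  expect_error(hierarchical_cluster(matrix(c(1, NA), 2, 1)),
               class = "mc_degenerate_input")
})

test_that("merge sequences equal the naive O(n^3) oracle", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      m <- matrix(stats::rnorm(n * 5), n, 5)
      for (linkage in c("complete", "average", "single")) {
        d <- hierarchical_cluster(m, linkage)
        o <- oracle_hclust(m, linkage)
        expect_identical(d$merge, o$merge)
        expect_equal(d$height, o$height, tolerance = 1e-12)
      }
    }
  })
})

test_that("clustering agrees with stats::hclust partitions", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      m <- matrix(stats::rnorm(10 * 4), 10, 4)
      mine <- hierarchical_cluster(m, "complete")
      ref <- stats::hclust(stats::dist(m), method = "complete")
      expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
      for (k in c(2, 4, 7))
        expect_identical(partition_signature(cut_dendrogram(mine, k)),
                         partition_signature(stats::cutree(ref, k)))
    }
  })
})

test_that("clustering is invariant to row permutation", {
  withr::with_seed(29, {
    m <- matrix(stats::rnorm(8 * 3), 8, 3)
    perm <- sample(8)
    d1 <- cut_dendrogram(hierarchical_cluster(m), 3)
    d2 <- cut_dendrogram(hierarchical_cluster(m[perm, ]), 3)
    expect_identical(partition_signature(d1),
                     partition_signature(d2[order(perm)]))
  })
})

test_that("complete-linkage heights are non-decreasing", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      d <- hierarchical_cluster(matrix(stats::rnorm(36), 9, 4))
      expect_true(all(diff(d$height) >= -1e-12))
    }
  })
})

test_that("dendrogram cuts produce exactly k stable clusters", {
  m <- matrix(c(0, 1, 10), 3, 1)
  d <- hierarchical_cluster(m)
  expect_identical(unname(cut_dendrogram(d, 2)), c(1L, 1L, 2L))
  expect_identical(length(unique(cut_dendrogram(d, 1))), 1L)
  expect_identical(unname(cut_dendrogram(d, 3)), 1:3)
  expect_error(cut_dendrogram(d, 0), class = "mc_config_error")
  expect_error(cut_dendrogram(d, 4), class = "mc_config_error")
})

test_that("PCA matches an independent eigen-decomposition", {
  withr::with_seed(13, {
    x <- matrix(stats::rnorm(12 * 30), 12, 30)
    p <- pca(x, scale. = FALSE)
    # oracle: eigen-decomposition of the covariance of centered data
    xc <- scale(x, scale = FALSE)
    ev <- eigen(stats::cov(xc), symmetric = TRUE)
    r <- p$rank
    expect_equal(p$sdev^2, ev$values[seq_len(r)], tolerance = 1e-8)
    expect_equal(p$explained_variance,
                 ev$values[seq_len(r)] / sum(ev$values[seq_len(r)]),
                 tolerance = 1e-8)
    for (k in seq_len(3))    # scores equal up to component sign
      expect_equal(abs(p$scores[, k]), abs(xc %*% ev$vectors[, k])[, 1],
                   tolerance = 1e-8)
    # loadings orthonormal; full-rank reconstruction
    expect_equal(crossprod(p$loadings), diag(r), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(p$scores %*% t(p$loadings), xc,
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(p$explained_variance) <= 1e-12))
    expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  })
})

test_that("PCA handles degenerate geometry and bad requests", {
  line <- cbind(1:5, 2 * (1:5))     # collinear points
  p <- pca(line, scale. = FALSE)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca(line, n_components = 3), class = "mc_config_error")
  expect_error(pca(matrix(1, 1, 3)), class = "mc_degenerate_input")
})

test_that("intensity matrices align ions across columns", {
  a <- peak_list(c(700.0, 800.0), c(1, 2))
  b <- peak_list(c(700.1, 900.0), c(3, 4))
  m <- build_intensity_matrix(list(s1 = a, s2 = b), cluster_tol = 0.25)
  expect_identical(dim(m), c(3L, 2L))
  expect_equal(unname(m[1, ]), c(1, 3))    # 700.0/700.1 aligned
  expect_equal(unname(m[2, ]), c(2, 0))    # absent-as-zero
  expect_equal(attr(m, "mz")[1], 700.05)
  expect_error(build_intensity_matrix(list(a, b)),
               class = "mc_inconsistent_input")
})

test_that("group separation is visible in PCA of planted IMS studies", {
  # strong planted CS effects should separate A8 from CS4/CS8 in the
  # sample-level score space; asserted on average over seeds
  seps <- vapply(1:3, function(seed) {
    study <- generate_study(synthetic_config(seed = seed),
                            format = "peaklist")
    ids <- study$manifest[study$manifest$modality == "IMS", ]
    pls <- lapply(study$data[ids$sample_id], tic_normalize)
    mat <- build_intensity_matrix(pls)
    p <- pca(t(mat), n_components = 2)
    sc <- p$scores
    grp <- ids$group[match(rownames(sc), ids$sample_id)]
    cent <- rbind(colMeans(sc[grp == "A8", , drop = FALSE]),
                  colMeans(sc[grp %in% c("CS4", "CS8"), , drop = FALSE]))
    between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
    within <- mean(vapply(c("A8", "CS4", "CS8"), function(g) {
      s <- sc[grp == g, , drop = FALSE]
      mean(sqrt(rowSums(sweep(s, 2, colMeans(s))^2)))
    }, numeric(1)))
    between / within
  }, numeric(1))
  expect_gt(mean(seps), 1)
})
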