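#' Row z-scoring of an intensity matrix
#'
#' Subtracts the row mean from every cell and divides by the row standard
#' deviation (sample convention, n-1 denominator), so every row has mean 0
#' and standard deviation 1.  Constant rows have no defined z-score and
#' are returned as all-zero with a warning.
#'
#' @param x numeric matrix (ions in rows, samples/groups in columns) with
#'   at least 2 columns.
#' @return The z-scored matrix.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    mc_error("row z-scoring needs at least 2 columns", "mc_degenerate_input")
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sprintf("%d constant row(s) z-scored to all zero", sum(flat)))
    sd[flat] <- 1
  }
  z <- sweep(sweep(x, 1L, mu, "-"), 1L, sd, "/")
  z[flat, ] <- 0
  z
}

#' Agglomerative hierarchical clustering of matrix rows
#'
#' Euclidean-distance agglomeration of the rows (ions) of an intensity
#' matrix with complete (default), average or single linkage.
#' Deterministic: distance ties are broken toward the lowest-index
#' cluster pair.  The merge encoding follows the `stats::hclust`
#' convention (negative entries are leaves, positive entries earlier
#' merges).
#'
#' @param x numeric matrix with >= 2 rows; all values finite.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An object of class `ion_dendrogram` with elements `merge`,
#'   `height`, `order`, `labels`, `linkage`.  Convert with
#'   [as.hclust.ion_dendrogram()] for plotting.
#' @export
hierarchical_cluster <- function(x, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L)
    mc_error("clustering needs at least 2 rows", "mc_degenerate_input")
  if (any(!is.finite(x)))
    mc_error("clustering input contains non-finite values",
             "mc_degenerate_input")
  D <- as.matrix(stats::dist(x, method = "euclidean"))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)              # hclust codes of the cluster in each slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    Ds <- D[idx, idx, drop = FALSE]
    best <- min(Ds)
    w <- which(Ds == best, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
    i <- idx[w[1L, 1L]]; j <- idx[w[1L, 2L]]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best
    others <- setdiff(which(active), c(i, j))
    D[i, others] <- D[others, i] <- switch(
      linkage,
      complete = pmax(D[i, others], D[j, others]),
      single = pmin(D[i, others], D[j, others]),
      average = (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j]))
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- step
  }
  structure(list(merge = merge, height = height,
                 order = dendro_leaf_order(merge),
                 labels = rownames(x), linkage = linkage, n = n),
            class = "ion_dendrogram")
}

dendro_leaf_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.ion_dendrogram <- function(x, ...) {
  cat(sprintf("<ion_dendrogram> %d leaves, %s linkage, heights %.3g-%.3g\n",
              x$n, x$linkage, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert an ion dendrogram to a stats::hclust object
#'
#' @param x an `ion_dendrogram`.
#' @param ... unused.
#' @return A `stats::hclust` object.
#' @export
as.hclust.ion_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels,
                 method = x$linkage, dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Severs the k-1 highest merges: the first n-k merges are replayed and
#' the resulting connected groups are the clusters.  Labels are assigned
#' in order of each cluster's first leaf, so the labelling does not depend
#' on the display order of the leaves.
#'
#' @param dendro an `ion_dendrogram`.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return Integer cluster labels (1..k) per leaf, named by the leaf
#'   labels when available.
#' @export
cut_dendrogram <- function(dendro, k) {
  n <- dendro$n
  if (!is_count(k) || k < 1 || k > n)
    mc_error(sprintf("k must be between 1 and %d", n), "mc_config_error")
  assign_cl <- rep(NA_integer_, n)
  groups <- as.list(seq_len(n))      # leaf members of each merge product
  membership <- seq_len(n)
  for (step in seq_len(n - k)) {
    a <- dendro$merge[step, 1L]; b <- dendro$merge[step, 2L]
    ma <- if (a < 0) -a else groups[[n + a]]
    mb <- if (b < 0) -b else groups[[n + b]]
    groups[[n + step]] <- c(ma, mb)
    membership[c(ma, mb)] <- n + step
  }
  # relabel clusters 1..k in order of first leaf index
  first <- tapply(seq_len(n), membership, min)
  lab_map <- stats::setNames(rank(first), names(first))
  labels <- as.integer(lab_map[as.character(membership)])
  names(labels) <- dendro$labels
  labels
}

#' Principal component analysis of an intensity matrix
#'
#' Column-centered (and by default unit-variance-scaled, since peak
#' intensities span decades) singular value decomposition.  Observations
#' (samples) are rows and variables (ions) are columns; transpose an
#' ion-by-sample intensity matrix before calling.  Explained-variance
#' fractions are reported over the full rank, so they sum to 1.
#'
#' @param x numeric observation-by-variable matrix with >= 2 rows.
#' @param n_components number of components to return; defaults to the
#'   rank of the centered matrix.  Requesting more than the rank is an
#'   error.
#' @param center,scale. logical; column centering and unit-variance
#'   scaling (constant columns are left unscaled with a warning).
#' @return An object of class `pca_result`: `scores` (obs x comp),
#'   `loadings` (var x comp, orthonormal), `sdev`,
#'   `explained_variance` (fractions over full rank), `center`, `scale`.
#' @export
pca <- function(x, n_components = NULL, center = TRUE, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    mc_error("PCA needs at least 2 observations", "mc_degenerate_input")
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2L, ctr, "-")
  scl <- rep(1, ncol(x))
  if (scale.) {
    scl <- apply(x, 2L, stats::sd)
    flat <- scl == 0 | !is.finite(scl)
    if (any(flat)) {
      warning(sprintf("%d constant column(s) left unscaled", sum(flat)))
      scl[flat] <- 1
    }
    xc <- sweep(xc, 2L, scl, "/")
  }
  sv <- svd(xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (is.null(n_components)) n_components <- rank
  if (!is_count(n_components) || n_components < 1L)
    mc_error("n_components must be a positive integer", "mc_config_error")
  if (n_components > rank)
    mc_error(sprintf("n_components (%d) exceeds matrix rank (%d)",
                     n_components, rank), "mc_config_error")
  d2 <- sv$d[seq_len(rank)]^2
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores, loadings = loadings,
                 sdev = sv$d[seq_len(n_components)] / sqrt(max(1, nrow(x) - 1)),
                 explained_variance = d2 / sum(d2),
                 center = ctr, scale = scl, rank = rank),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance[seq_len(min(3, length(x$explained_variance)))]
  cat(sprintf("<pca_result> %d x %d scores; explained variance %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * ev), collapse = ", ")))
  invisible(x)
}

#' Align peak collections into an ion-by-sample intensity matrix
#'
#' Pools the peaks of several (consensus) peak lists, chains them into
#' consensus ions by single linkage within `cluster_tol`, and returns the
#' ion-by-column intensity matrix with absent ions as 0.  When a column
#' contributes several pooled peaks to one ion, the most intense is used.
#'
#' @param peaklists named list of peak collections (columns).
#' @param cluster_tol alignment tolerance in Da.
#' @return Numeric matrix with one row per consensus ion (rownames are
#'   the consensus m/z, also in attribute `mz`) and one column per list.
#' @export
build_intensity_matrix <- function(peaklists, cluster_tol = 0.25) {
  if (is.null(names(peaklists)) || any(!nzchar(names(peaklists))) ||
      anyDuplicated(names(peaklists)))
    mc_error("peaklists must be uniquely named", "mc_inconsistent_input")
  pooled <- do.call(rbind, lapply(names(peaklists), function(nm)
    data.frame(mz = peaklists[[nm]]$mz,
               intensity = peaklists[[nm]]$intensity, col = nm)))
  if (is.null(pooled) || !nrow(pooled))
    return(matrix(numeric(0), 0, length(peaklists),
                  dimnames = list(NULL, names(peaklists))))
  pooled <- pooled[order(pooled$mz), ]
  cl <- cumsum(c(1L, diff(pooled$mz) > cluster_tol))
  ions <- split(pooled, cl)
  mat <- matrix(0, length(ions), length(peaklists),
                dimnames = list(NULL, names(peaklists)))
  mzs <- numeric(length(ions))
  for (r in seq_along(ions)) {
    d <- ions[[r]]
    mzs[r] <- mean(d$mz)
    d <- d[order(-d$intensity), ]
    d <- d[!duplicated(d$col), ]
    mat[r, d$col] <- d$intensity
  }
  rownames(mat) <- sprintf("%.4f", mzs)
  attr(mat, "mz") <- mzs
  mat
}

#' Export a clustered z-score heat map
#'
#' Thin rendering layer over [zscore_rows()] and
#' [hierarchical_cluster()]: rows are z-scored, clipped to [-1, 1],
#' ordered by the row dendrogram and drawn with a 6-color diverging
#' palette.  Uses `pheatmap` when installed, else base graphics.
#'
#' @param x intensity matrix (ions x samples/groups).
#' @param file optional PNG path; when given the plot is written there.
#' @param linkage linkage for the row dendrogram.
#' @return Invisibly, the clipped z-score matrix in plotted row order.
#' @export
plot_heatmap <- function(x, file = NULL, linkage = "complete") {
  z <- zscore_rows(x)
  z <- pmin(pmax(z, -1), 1)
  dend <- hierarchical_cluster(z, linkage = linkage)
  z <- z[dend$order, , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(6)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 900)
    on.exit(grDevices::dev.off())
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = pal, breaks = seq(-1, 1, length.out = 7),
                       border_color = NA)
  } else {
    graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                    col = pal, axes = FALSE,
                    main = "row z-scores (clipped to [-1, 1])")
  }
  invisible(z)
}
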