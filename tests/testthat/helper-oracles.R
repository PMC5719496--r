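# Independent brute-force oracles used to validate the package's own
# implementations on small instances.

# maximum-cardinality, then minimum total |dmz|, assignment within
# tolerance by exhaustive recursion (feasible for <= ~8 peaks per side)
oracle_match <- function(emz, imz, tol) {
  best <- list(n = -1L, cost = Inf)
  rec <- function(i, used, np, cost) {
    if (i > length(emz)) {
      if (np > best$n || (np == best$n && cost < best$cost))
        best <<- list(n = np, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used, np, cost)
    for (j in which(!used & abs(imz - emz[i]) <= tol)) {
      u <- used; u[j] <- TRUE
      rec(i + 1L, u, np + 1L, cost + abs(imz[j] - emz[i]))
    }
  }
  rec(1L, rep(FALSE, length(imz)), 0L, 0)
  best
}

# naive O(n^3) agglomeration: recompute every cluster-pair distance from
# the raw pairwise distances at every step; merged cluster replaces the
# lower slot, ties broken toward the lowest-index pair
oracle_hclust <- function(x, linkage) {
  n <- nrow(x)
  d0 <- as.matrix(stats::dist(x))
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  pair_dist <- function(a, b) {
    d <- d0[a, b, drop = FALSE]
    switch(linkage, complete = max(d), single = min(d), average = mean(d))
  }
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(length(members) - 1L))
      for (j in (i + 1L):length(members)) {
        d <- pair_dist(members[[i]], members[[j]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    merge[step, ] <- sort(c(code[bi], code[bj]))
    height[step] <- best
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
    code[bi] <- step
    code <- code[-bj]
  }
  list(merge = merge, height = height)
}

# local maxima of a trace by direct scan (for peak-picking cross-checks)
oracle_local_maxima <- function(y) {
  mid <- 2:(length(y) - 1L)
  mid[y[mid] > y[mid - 1L] & y[mid] > y[mid + 1L]]
}

# small random normalized peak list
random_peaklist <- function(n, mz_lo = 600, mz_hi = 1300,
                            modality = "extract", normalized = FALSE) {
  mz <- sort(stats::runif(n, mz_lo, mz_hi))
  while (any(diff(mz) < 1e-6)) mz <- sort(stats::runif(n, mz_lo, mz_hi))
  pl <- peak_list(mz, stats::runif(n, 0.5, 10), modality = modality)
  if (normalized) tic_normalize(pl) else pl
}

# canonical partition signature, invariant to label permutation
partition_signature <- function(labels) {
  unname(split(seq_along(labels), labels)[order(
    vapply(split(seq_along(labels), labels), min, numeric(1)))])
}

# small fast study configuration used across tests
small_config <- function(...) {
  args <- list(n_extract_ions = 12L, n_ims_ions = 10L, n_shared = 5L,
               noise_sd = 0, sigma_log = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}
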