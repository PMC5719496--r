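# internal helpers shared across modules

mc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "maldiconcord_error")))
}

# multiplicative distance from 1: max(x, 1/x); >= 1 always
fold_dist <- function(x) pmax(x, 1 / x)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# derive a reproducible sub-seed (< 2^31) from a base seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629)
}

GROUP_LEVELS <- c("A8", "CS4", "CS8", "CS8+R")
MODALITY_LEVELS <- c("extract", "IMS")
C13_DELTA <- 1.00335
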