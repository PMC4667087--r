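#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans median mad rnorm runif optim sd cov
#'   model.matrix pf pt qlogis plogis complete.cases setNames var cor
#'   quantile contrasts<-
#' @importFrom utils write.csv read.csv packageVersion tail
NULL

TISSUES <- c("CSF", "GM", "WM", "LESION")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls do not perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation; keeps results < 2^31.
derive_seed <- function(master, offset) {
  (as.integer(master) + 7919L * as.integer(offset)) %% 2147483629L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# mm coordinates of every voxel center, 0-based indexing convention.
voxel_centers_mm <- function(dim, voxel_size_mm) {
  list(x = (seq_len(dim[1]) - 1) * voxel_size_mm[1],
       y = (seq_len(dim[2]) - 1) * voxel_size_mm[2],
       z = (seq_len(dim[3]) - 1) * voxel_size_mm[3])
}
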