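#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Hierarchical seeding: a master seed plus a path of small integers (e.g.
#' participant index, condition index) is folded into a single 31-bit seed,
#' so any recording or permutation stream can be regenerated in isolation.
#'
#' @param master Integer master seed.
#' @param ... Integers identifying the sub-stream (participant, condition, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  abort_if(!is.numeric(master) || length(master) != 1L || !is.finite(master),
           "`master` must be a single finite number")
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  x <- abs(master) %% m
  for (k in c(...)) {
    x <- (x * 69069 + abs(k) %% m + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Package-level cache (population-score grids etc.).
.infantfc_cache <- new.env(parent = emptyenv())

cache_get_or_compute <- function(key, compute) {
  if (!is.null(.infantfc_cache[[key]])) return(.infantfc_cache[[key]])
  val <- compute()
  assign(key, val, envir = .infantfc_cache)
  val
}
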