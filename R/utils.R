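# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a named stream
#'
#' Every source of randomness in the package draws from a stream derived
#' deterministically from a single master seed plus string/integer labels,
#' so that stages of the pipeline can be re-run independently without
#' perturbing each other's draws.
#'
#' @param seed master integer seed
#' @param ... stream labels (character or integer scalars)
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()]
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (part in list(...)) {
    bytes <- utf8ToInt(paste0("|", as.character(part)))
    for (b in bytes) h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# local RNG scope: runs expr under a derived seed without touching the
# caller's .Random.seed
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

stop_if_not_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# rescale a non-constant vector to [lo, hi]
rescale01 <- function(x, lo = 0, hi = 1) {
  r <- range(x)
  if (r[1] == r[2]) stop("cannot rescale a constant vector", call. = FALSE)
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

# absolute cosine between two mean-centred vectors
centred_abs_cosine <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
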