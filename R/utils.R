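# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# C1-smooth step from 0 at x = a to 1 at x = b.
smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# Smooth positive profile through control points, zero outside [min(z), max(z)].
# Used by the synthetic body generator; clamps spline undershoot at 0.
profile_fun <- function(z_ctrl, v_ctrl) {
  ord <- order(z_ctrl)
  z_ctrl <- z_ctrl[ord]
  v_ctrl <- v_ctrl[ord]
  function(z) {
    out <- numeric(length(z))
    inside <- z >= z_ctrl[1] & z <= z_ctrl[length(z_ctrl)]
    if (any(inside)) {
      s <- stats::spline(z_ctrl, v_ctrl, xout = z[inside], method = "natural")$y
      out[inside] <- pmax(s, 0)
    }
    out
  }
}

# md5 of an arbitrary R object via its serialization (manifest provenance).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
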