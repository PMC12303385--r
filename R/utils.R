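# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Parabolic refinement of a grid argmin: vertex of the parabola through the
# three points bracketing the minimum. Returns the boundary point (flagged)
# when the minimum is not bracketed.
refine_argmin <- function(x, y) {
  i <- which.min(y)
  if (i == 1L || i == length(x)) {
    return(list(x = x[i], bracketed = FALSE))
  }
  x0 <- x[(i - 1):(i + 1)]
  y0 <- y[(i - 1):(i + 1)]
  d1 <- (x0[2] - x0[1]) * (y0[2] - y0[3])
  d2 <- (x0[2] - x0[3]) * (y0[2] - y0[1])
  denom <- d1 - d2
  if (abs(denom) < .Machine$double.eps * max(abs(y0))) {
    return(list(x = x0[2], bracketed = TRUE))
  }
  xv <- x0[2] - 0.5 * ((x0[2] - x0[1]) * d1 - (x0[2] - x0[3]) * d2) / denom
  # guard: stay inside the bracketing interval
  xv <- min(max(xv, x0[1]), x0[3])
  list(x = xv, bracketed = TRUE)
}
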