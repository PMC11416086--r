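# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
shift_logical <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- 1L + max(0L, dr)
  r1 <- nr + min(0L, dr)
  c0 <- 1L + max(0L, dc)
  c1 <- nc + min(0L, dc)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- m[(r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  }
  out
}
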