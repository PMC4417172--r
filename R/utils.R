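# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Strand as +1 / -1 multiplier for transcription-direction arithmetic.
strand_dir <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  ifelse(strand == "+", 1L, -1L)
}

# Repeatedly redraw entries of a vector that fail `valid_fun` using
# `draw_fun(n)`, up to `max_redraws` rounds; used by the read/fragment
# simulators whose offset distributions can produce out-of-window molecules.
redraw_until <- function(n, draw_fun, valid_fun, max_redraws = 1000L,
                         what = "draw") {
  x <- draw_fun(n)
  bad <- !valid_fun(x)
  rounds <- 0L
  while (any(bad)) {
    rounds <- rounds + 1L
    if (rounds > max_redraws) {
      stop(sprintf(
        "could not produce a valid %s after %d redraws; the configured distributions are incompatible with the validity window",
        what, max_redraws
      ), call. = FALSE)
    }
    x[bad] <- draw_fun(sum(bad))
    bad <- !valid_fun(x)
  }
  x
}
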