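# Internal helpers shared across modules.

# Round half away from zero; base round() uses banker's rounding, but reported
# lambda-max values follow the "nearest whole integer" (half-up) convention.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All synthetic generators route through this so they are pure
# functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x),
         call. = FALSE)
  }
  invisible(x)
}

# Package-level cache environment (template normalization scales, data tables).
.visadapt_cache <- new.env(parent = emptyenv())

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "visadapt")
  if (!nzchar(path)) stop("cannot locate extdata file: ", file, call. = FALSE)
  path
}
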