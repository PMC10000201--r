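# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators route through this so
# that simulation is a pure function of (parameters, seed).
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Read lines from either a file path or an already-split character vector.
# A single string containing newlines is treated as inline text.
as_lines <- function(x, what = "input") {
  if (!is.character(x)) {
    stop(what, " must be a file path or a character vector of lines")
  }
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# round() half-away-from-zero, used when reconstructing integer counts from
# printed percentages (base round() is round-half-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Population-style standard deviation (denominator n, not n - 1).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
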