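#' @keywords internal
"_PACKAGE"

# Run `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package internals never perturb the
# user's random stream.
with_local_seed <- function(seed, code) {
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
  force(code)
}

# Deterministic sub-seed derivation: one global seed fans out to named
# substreams. Kept well below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(part))) {
      h <- (h * 131 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
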