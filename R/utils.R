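# Internal helpers shared across modules: classed errors, deterministic
# hashing for seed derivation, and RNG-preserving evaluation.

gb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pairGBERT_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit rolling hash of a string; locale-independent.
# Used to key per-protein and per-stream RNG seeds without global state.
str_hash31 <- function(s) {
  codes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

# Mix a base seed with a stream name into a 31-bit seed.
stream_seed <- function(seed, stream) {
  as.integer((as.double(seed %% 2147483647L) * 2654435761 +
                str_hash31(stream)) %% 2147483647)
}

# Evaluate expr with a private RNG seeded by `seed`; caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  expr
}

# Byte-wise (C-collation) string minimum/maximum, locale independent.
lex_sorted <- function(a, b) sort(c(a, b), method = "radix")
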