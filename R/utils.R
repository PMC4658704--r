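# internal numerical helpers

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic per-stage seed derivation from one global seed. Stages re-run
# independently must not share streams; a string hash keeps the mapping stable
# across call orders. Result kept in [1, 2^31 - 2].
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(as.integer(charToRaw(as.character(stage))) *
             (seq_along(charToRaw(as.character(stage))) %% 31L + 1L))
  val <- (as.double(seed) * 48271 + h * 16807) %% 2147483646
  as.integer(val) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}
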