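# Deterministic, namespaced randomness.
#
# Every stochastic draw in the simulator is keyed by (seed, embryo, event tag)
# so that adding or removing events never shifts the draws of unrelated
# events.  The key is reduced to a 31-bit stream seed with a polynomial
# string hash computed in double precision (exact for moduli < 2^26 * 2^5).

.SL_HASH_MOD <- 2147483629   # largest prime < 2^31 - 1 used as hash modulus

#' @keywords internal
.hashString <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% .SL_HASH_MOD
  h
}

#' Derive a stream seed for a namespaced event
#' @keywords internal
.eventSeed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  (as.double(seed %% .SL_HASH_MOD) * 7919 + .hashString(tag)) %% .SL_HASH_MOD
}

#' Draw from a namespaced stream without disturbing the global RNG state
#' beyond this draw.
#' @keywords internal
.eventDraw <- function(seed, tag, fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.eventSeed(seed, tag))
  fun()
}
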