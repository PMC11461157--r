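#' Derive a per-person, per-purpose RNG substream seed
#'
#' The whole pipeline is driven by one master seed. Every person and every
#' purpose ("natural history", one stream per screening regimen, the forest,
#' ...) gets its own deterministic 31-bit substream seed derived from
#' `(seed, person_id, stream)`. Because the per-person seed does not depend on
#' cohort size, a cohort of `n` persons is always a prefix of a larger cohort
#' simulated with the same master seed, and identical natural-history draws
#' can be reused across screening strategies (common random numbers).
#'
#' @param seed master integer seed.
#' @param person person index (1-based); 0 for cohort-level streams.
#' @param stream integer stream identifier (see [stream_id()]).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @seealso [stream_id()]
#' @export
substream_seed <- function(seed, person = 0L, stream = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(person) * 16807 +
    (as.numeric(stream) %% m) * 69621
  x <- x %% m
  x <- (x * 16807 + 12345) %% m
  as.integer(x)
}

#' Integer stream identifier from a label
#'
#' Hashes a character label (e.g. a screening regimen's clinical signature)
#' into a 31-bit integer for [substream_seed()]. The label deliberately
#' excludes economic attributes such as the unit test cost, so that regimens
#' differing only in price share identical screening randomness.
#'
#' @param label character scalar.
#' @return integer stream id.
#' @export
stream_id <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}
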