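#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single top-level seed. Each
#' component (kinematics, selections, questionnaire, per-trial Monte-Carlo
#' nulls, ...) draws from its own named substream so that stages are
#' reproducible independently of one another and of evaluation order.
#'
#' @param seed integer master seed.
#' @param stream character label of the substream.
#' @param index optional non-negative integer (e.g. a trial index) to split a
#'   stream further.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1L, "kinematics")
#' derive_seed(1L, "null", index = 17)
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps the state an exact double throughout
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(stream)) h <- (h * 69069 + ch) %% m
  h <- (h * 69069 + as.double(index) %% m) %% m
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state (restores .Random.seed, or removes it if it did not exist).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Tiny FNV-1a style hash of a character scalar; used for config fingerprints
# in run manifests. Not cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
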