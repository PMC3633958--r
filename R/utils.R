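# Internal helpers: seeded substreams and small numeric utilities.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (fold draws,
#' permutation streams, simulators) never disturb the caller's RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a deterministic substream seed from a master seed and a tag
#'
#' A multiplicative polynomial hash over the integer tag, kept below 2^31 so the
#' result is a valid `set.seed()` argument.  Used so that fold construction,
#' each combination's permutation stream and the simulator draw from
#' independent, order-independent streams of one master seed.
#' @noRd
derive_seed <- function(seed, tag) {
  m <- 2147483647 # 2^31 - 1; exact in doubles
  h <- as.numeric(seed) %% m
  for (t in as.numeric(tag)) {
    h <- (h * 1009 + t + 1) %% m
  }
  as.integer(h)
}

#' Ratio with a vacuous-class fallback
#'
#' Balanced-accuracy class terms: when the evaluation set holds no score mass
#' of one sign the class is vacuously half-credited (0.5) so the statistic
#' stays defined on tiny folds.
#' @noRd
safe_ratio <- function(num, den) {
  out <- num / den
  out[den <= 0] <- 0.5
  out
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "f")
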