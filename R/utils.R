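#' Canonical activity vocabulary
#'
#' The five activity classes every harmonized corpus is mapped onto:
#' walking, running, sitting, standing and stairs (ascending and descending
#' merged, since direction of vertical displacement is not recoverable from
#' an accelerometer alone).
#'
#' @return Character vector of the five canonical labels.
#' @export
canonical_activities <- function() {
  c("walk", "run", "sit", "stand", "stairs")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  expr
}

# Frequency (Hz) of the dominant non-DC spectral peak of a real signal.
dominant_frequency <- function(x, rate) {
  n <- length(x)
  if (n < 4) return(0)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(floor(n / 2) + 1)]
  freqs <- (seq_along(half) - 1) * rate / n
  half[1] <- 0  # drop DC
  if (all(half <= 0)) return(0)
  freqs[which.max(half)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
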