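# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded operations (K-means restarts, synthetic data)
#' never disturb the user's random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
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

# Stop with the calling function's name in the message.
stop_wavehrv <- function(...) {
  stop(..., call. = FALSE)
}

# Nearest power of two to a positive rate; ties resolved upward to avoid
# losing bandwidth.
nearest_pow2 <- function(fs) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  k_lo <- floor(log2(fs))
  lo <- 2^k_lo
  hi <- 2^(k_lo + 1)
  if ((fs - lo) < (hi - fs)) lo else hi
}

# Frequency of the largest FFT magnitude (one-sided, DC excluded).
dominant_frequency <- function(values, fs) {
  n <- length(values)
  sp <- abs(stats::fft(values - mean(values)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1L) * fs / n
  freqs[which.max(sp)]
}
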