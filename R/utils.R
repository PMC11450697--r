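# Internal helpers shared across modules.

# Run expr with a private RNG stream; caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Zero-phase FFT convolution of x with a kernel given as (center value,
# positive-lag tail, negative-lag tail implied by Hermitian placement).
# `kernel` is a full odd-length vector with its center at index (L+1).
# Returns a vector aligned with x (same length).
fft_convolve_centered <- function(x, kernel, nfft = NULL) {
  n <- length(x)
  lk <- length(kernel)
  stopifnot(lk %% 2L == 1L)
  half <- (lk - 1L) / 2L
  if (is.null(nfft)) nfft <- stats::nextn(n + lk - 1L, 2L)
  kp <- complex(nfft)
  kp[1L] <- kernel[half + 1L]
  if (half > 0L) {
    kp[2L:(half + 1L)] <- kernel[(half + 2L):lk]
    kp[(nfft - half + 1L):nfft] <- kernel[1L:half]
  }
  xp <- c(x, numeric(nfft - n))
  y <- stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE) / nfft
  y[seq_len(n)]
}

# Spectrum of a centered kernel on an nfft grid (for reuse across many signals).
kernel_spectrum <- function(kernel, nfft) {
  lk <- length(kernel)
  stopifnot(lk %% 2L == 1L)
  half <- (lk - 1L) / 2L
  kp <- complex(nfft)
  kp[1L] <- kernel[half + 1L]
  if (half > 0L) {
    kp[2L:(half + 1L)] <- kernel[(half + 2L):lk]
    kp[(nfft - half + 1L):nfft] <- kernel[1L:half]
  }
  stats::fft(kp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
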