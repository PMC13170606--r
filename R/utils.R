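# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One top-level seed deterministically derives per-stage, per-session
# sub-seeds so partial reruns agree with full runs. Kept below 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_code * 257 + index) %%
               2147483629)
}

# FFT-based linear convolution, full length (length(x) + length(y) - 1).
fft_convolve <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  z <- Re(stats::fft(stats::fft(c(x, rep(0, nf - length(x)))) *
                     stats::fft(c(y, rep(0, nf - length(y)))), inverse = TRUE)) / nf
  z[seq_len(n)]
}

# FFT-based circular convolution/correlation against a sparse filter whose
# taps sit at 0-based positions `pos` (mod n) with values `val`.
circ_apply <- function(fx, pos, val, n, conj = FALSE) {
  h <- numeric(n)
  idx <- (pos %% n) + 1L
  for (k in seq_along(idx)) h[idx[k]] <- h[idx[k]] + val[k]
  H <- stats::fft(h)
  if (conj) H <- Conj(H)
  Re(stats::fft(fx * H, inverse = TRUE)) / n
}
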