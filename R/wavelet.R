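# Symlet-4 (sym4) decomposition filter, least-asymmetric Daubechies family
# with 4 vanishing moments (standard published coefficients).
.sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851,
                  0.49761866763201545, 0.80373875180591614,
                  0.29785779560527736, -0.09921954357684722,
                  -0.01260396726203783, 0.03222310060404270)
.sym4_dec_hi <- c(-0.03222310060404270, -0.01260396726203783,
                  0.09921954357684722, 0.29785779560527736,
                  -0.80373875180591614, 0.49761866763201545,
                  0.02963552764599851, -0.07576571478927333)

wavelet_filters <- function(family = "sym4") {
  if (!identical(family, "sym4"))
    stop("only the Symlet-4 ('sym4') family is provided")
  list(lo = .sym4_dec_lo / sqrt(2), hi = .sym4_dec_hi / sqrt(2))
}

#' Wavelet denoising specification
#'
#' Parameters of the wavelet-denoising stage: a maximal-overlap discrete
#' wavelet transform (MODWT) with a Symlet-4 wavelet, decomposition to
#' `levels` levels, and zeroing of the detail coefficients listed in
#' `removed_details` before reconstruction. With the defaults (10 levels,
#' details D1-D5 removed) the retained content at a 10.2 Hz sampling rate
#' lies below roughly 0.16 Hz, removing motion and other high-frequency
#' artifacts while preserving slow hemodynamic trends.
#'
#' @param family wavelet family; only `"sym4"` is provided.
#' @param levels decomposition depth.
#' @param removed_details integer vector of detail levels to zero.
#' @param boundary boundary rule; the transform is circular (`"periodic"`).
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "sym4", levels = 10,
                         removed_details = 1:5, boundary = "periodic") {
  if (!all(removed_details %in% seq_len(levels)))
    stop("removed_details must be a subset of 1..levels")
  structure(list(family = family, levels = as.integer(levels),
                 removed_details = as.integer(removed_details),
                 boundary = boundary),
            class = "wavelet_spec")
}

# Maximal-overlap DWT (Percival & Walden), circular boundary.
# Returns details W[[1..J]] and final smooth V, all of length(x).
modwt <- function(x, levels, family = "sym4") {
  f <- wavelet_filters(family)
  L <- length(f$lo)
  n <- length(x)
  min_n <- (L - 1L) * 2^(levels - 1L) + 1L
  if (n < min_n)
    stop(sprintf(paste0("series too short for %d-level decomposition: ",
                        "need at least %d samples, got %d"),
                 levels, min_n, n))
  W <- vector("list", levels)
  V <- x
  l <- seq_len(L) - 1L
  for (j in seq_len(levels)) {
    pos <- l * 2^(j - 1L)
    fV <- stats::fft(V)
    W[[j]] <- circ_apply(fV, pos, f$hi, n)
    V <- circ_apply(fV, pos, f$lo, n)
  }
  list(W = W, V = V, levels = levels, family = family, n = n)
}

# Inverse MODWT: exact reconstruction from untouched coefficients.
imodwt <- function(dec) {
  f <- wavelet_filters(dec$family)
  L <- length(f$lo)
  l <- seq_len(L) - 1L
  V <- dec$V
  for (j in rev(seq_len(dec$levels))) {
    pos <- l * 2^(j - 1L)
    V <- circ_apply(stats::fft(V), pos, f$lo, dec$n, conj = TRUE) +
      circ_apply(stats::fft(dec$W[[j]]), pos, f$hi, dec$n, conj = TRUE)
  }
  V
}

#' Wavelet-denoise a signal
#'
#' Decomposes the signal with a Symlet-4 MODWT to `spec$levels` levels,
#' zeroes the detail coefficients at the levels in `spec$removed_details`,
#' and reconstructs. Output length always equals input length. If the series
#' is too short for the requested depth the level count is reduced with a
#' warning (never silently).
#'
#' @param x numeric signal.
#' @param spec a [wavelet_spec()].
#' @return Denoised numeric vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, spec = wavelet_spec()) {
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  f <- wavelet_filters(spec$family)
  L <- length(f$lo)
  levels <- spec$levels
  max_lev <- if (length(x) >= L) floor(log2((length(x) - 1) / (L - 1))) + 1L
    else 0L
  if (max_lev < 1L)
    stop(sprintf("series too short to decompose: need at least %d samples",
                 L))
  if (levels > max_lev) {
    warning(sprintf("series supports only %d levels (requested %d); reducing",
                    max_lev, levels))
    levels <- max_lev
  }
  dec <- modwt(x, levels, spec$family)
  for (d in spec$removed_details[spec$removed_details <= levels])
    dec$W[[d]] <- numeric(dec$n)
  imodwt(dec)
}
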