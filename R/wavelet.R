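# Biorthogonal CDF 9/7 wavelet via the lifting scheme (the JPEG2000
# irreversible filter pair), 1-D and separable 2-D, with soft-threshold
# shrinkage at the universal level. Lifting guarantees perfect
# reconstruction for any boundary handling as long as forward and inverse
# use the same neighbour rule; edges are clamped (whole-sample symmetric).

.cdf97 <- list(alpha = -1.586134342059924, beta = -0.052980118572961,
               gamma = 0.882911075530934, delta = 0.443506852043971,
               zeta = 1.230174104914001)

# One forward lifting level applied to every column of M (even row count).
# Returns rbind(approx, detail), each nrow(M)/2 rows.
cdf97_fwd_cols <- function(M) {
  n <- nrow(M); m <- n %/% 2L
  s <- M[seq(1L, n, 2L), , drop = FALSE]
  d <- M[seq(2L, n, 2L), , drop = FALSE]
  nxt <- pmin(seq_len(m) + 1L, m)   # clamp at the right edge
  prv <- pmax(seq_len(m) - 1L, 1L)  # clamp at the left edge
  k <- .cdf97
  d <- d + k$alpha * (s + s[nxt, , drop = FALSE])
  s <- s + k$beta * (d[prv, , drop = FALSE] + d)
  d <- d + k$gamma * (s + s[nxt, , drop = FALSE])
  s <- s + k$delta * (d[prv, , drop = FALSE] + d)
  rbind(s * k$zeta, d / k$zeta)
}

cdf97_inv_cols <- function(M) {
  n <- nrow(M); m <- n %/% 2L
  s <- M[seq_len(m), , drop = FALSE] / .cdf97$zeta
  d <- M[m + seq_len(m), , drop = FALSE] * .cdf97$zeta
  nxt <- pmin(seq_len(m) + 1L, m)
  prv <- pmax(seq_len(m) - 1L, 1L)
  k <- .cdf97
  s <- s - k$delta * (d[prv, , drop = FALSE] + d)
  d <- d - k$gamma * (s + s[nxt, , drop = FALSE])
  s <- s - k$beta * (d[prv, , drop = FALSE] + d)
  d <- d - k$alpha * (s + s[nxt, , drop = FALSE])
  out <- matrix(0, n, ncol(M))
  out[seq(1L, n, 2L), ] <- s
  out[seq(2L, n, 2L), ] <- d
  out
}

# Symmetric padding of a length to the next multiple of 2^levels.
pad_len <- function(n, levels) {
  u <- 2L^levels
  as.integer(ceiling(n / u) * u)
}

pad_sym <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  extra <- n_out - n
  if (n == 1L) return(c(x, rep(x, extra)))
  refl <- x[seq(n - 1L, by = -1L, length.out = min(extra, n - 1L))]
  while (length(refl) < extra) refl <- c(refl, rev(refl))[seq_len(extra)]
  c(x, refl[seq_len(extra)])
}

#' Multi-level 2-D CDF 9/7 forward transform
#'
#' @param img numeric matrix; padded internally to a multiple of
#'   `2^levels` by symmetric reflection.
#' @param levels decomposition depth.
#' @return list with the in-place coefficient matrix (`coef`), the original
#'   size, and `levels`.
#' @keywords internal
cdf97_fwd2d <- function(img, levels) {
  r0 <- nrow(img); c0 <- ncol(img)
  rp <- pad_len(r0, levels); cp <- pad_len(c0, levels)
  A <- matrix(0, rp, cp)
  for (j in seq_len(c0)) A[, j] <- pad_sym(img[, j], rp)
  for (i in seq_len(rp)) A[i, ] <- pad_sym(A[i, seq_len(c0)], cp)
  r <- rp; cc <- cp
  for (l in seq_len(levels)) {
    A[seq_len(r), seq_len(cc)] <- cdf97_fwd_cols(A[seq_len(r), seq_len(cc), drop = FALSE])
    A[seq_len(r), seq_len(cc)] <- t(cdf97_fwd_cols(t(A[seq_len(r), seq_len(cc), drop = FALSE])))
    r <- r %/% 2L; cc <- cc %/% 2L
  }
  list(coef = A, rows = r0, cols = c0, levels = levels)
}

cdf97_inv2d <- function(w) {
  A <- w$coef
  rp <- nrow(A); cp <- ncol(A)
  sizes <- lapply(seq_len(w$levels), function(l) c(rp %/% 2L^(l - 1L),
                                                   cp %/% 2L^(l - 1L)))
  for (l in rev(seq_len(w$levels))) {
    r <- sizes[[l]][1]; cc <- sizes[[l]][2]
    A[seq_len(r), seq_len(cc)] <- t(cdf97_inv_cols(t(A[seq_len(r), seq_len(cc), drop = FALSE])))
    A[seq_len(r), seq_len(cc)] <- cdf97_inv_cols(A[seq_len(r), seq_len(cc), drop = FALSE])
  }
  A[seq_len(w$rows), seq_len(w$cols), drop = FALSE]
}

# Soft threshold the detail coefficients (everything outside the final LL
# block) at the universal level sigma*sqrt(2 log N), sigma estimated from
# the finest diagonal subband via the MAD rule.
cdf97_shrink2d <- function(w) {
  A <- w$coef
  rp <- nrow(A); cp <- ncol(A)
  hh <- A[(rp %/% 2L + 1L):rp, (cp %/% 2L + 1L):cp]
  sigma <- stats::median(abs(hh)) / 0.6745
  thr <- sigma * sqrt(2 * log(rp * cp))
  rl <- rp %/% 2L^w$levels; cl <- cp %/% 2L^w$levels
  keep <- matrix(FALSE, rp, cp)
  keep[seq_len(rl), seq_len(cl)] <- TRUE
  det <- A[!keep]
  A[!keep] <- sign(det) * pmax(abs(det) - thr, 0)
  w$coef <- A
  w
}

#' Denoise one image plane by CDF 9/7 wavelet shrinkage
#' @param img numeric matrix.
#' @param levels decomposition depth (0 returns the input unchanged).
#' @return denoised matrix of the same size.
#' @keywords internal
wavelet_denoise2d <- function(img, levels = 2L) {
  if (levels <= 0L) return(img)
  cdf97_inv2d(cdf97_shrink2d(cdf97_fwd2d(img, levels)))
}

#' Wavelet-smooth a reference spectrum
#'
#' 1-D CDF 9/7 decomposition, soft-thresholding of all detail coefficients
#' at the universal threshold (noise scale from the finest detail band by
#' the MAD rule), and reconstruction. Spectra shorter than 8 samples are
#' returned unchanged with a warning.
#'
#' @param spectrum numeric vector (one value per channel).
#' @param levels decomposition depth.
#' @return smoothed vector of the same length.
#' @export
smooth_reference <- function(spectrum, levels = 3L) {
  n <- length(spectrum)
  if (n < 8L) {
    warnf("spectrum of length %d is too short to smooth; returned unchanged", n)
    return(spectrum)
  }
  np <- pad_len(n, levels)
  A <- matrix(pad_sym(spectrum, np), ncol = 1L)
  r <- np
  for (l in seq_len(levels)) {   # multi-level 1-D analysis
    A[seq_len(r), 1L] <- cdf97_fwd_cols(A[seq_len(r), 1L, drop = FALSE])
    r <- r %/% 2L
  }
  fine <- A[(np %/% 2L + 1L):np, 1L]
  sigma <- stats::median(abs(fine)) / 0.6745
  thr <- sigma * sqrt(2 * log(np))
  rl <- np %/% 2L^levels
  det <- A[(rl + 1L):np, 1L]
  A[(rl + 1L):np, 1L] <- sign(det) * pmax(abs(det) - thr, 0)
  for (l in rev(seq_len(levels))) {
    r <- np %/% 2L^(l - 1L)
    A[seq_len(r), 1L] <- cdf97_inv_cols(A[seq_len(r), 1L, drop = FALSE])
  }
  A[seq_len(n), 1L]
}
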