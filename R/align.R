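# Core alignment primitives: decorrelation pre-filtering and sub-pixel phase
# correlation scored by normalized cross-correlation.

#' Replicate-pad a matrix
#'
#' @param m matrix.
#' @param r pad radius in pixels.
#' @return padded matrix with edge rows/columns replicated.
#' @keywords internal
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

#' Separable Gaussian blur with replicate boundary handling
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix, same shape.
#' @keywords internal
gaussian_blur <- function(image, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(image)
  p <- pad_replicate(image, r)
  acc <- matrix(0, d[1], d[2] + 2L * r)
  for (i in seq_along(k)) {
    acc <- acc + k[i] * p[i:(i + d[1] - 1L), , drop = FALSE]
  }
  out <- matrix(0, d[1], d[2])
  for (i in seq_along(k)) {
    out <- out + k[i] * acc[, i:(i + d[2] - 1L), drop = FALSE]
  }
  out
}

#' Whiten an image by Laplacian (or Laplacian-of-Gaussian) filtering
#'
#' High-pass pre-filter that removes the low-frequency autocorrelation of
#' tissue images so that phase-correlation peaks reflect genuine feature
#' alignment rather than shared background structure. With `sigma = 0` the
#' discrete 5-point Laplacian is applied; with `sigma > 0` the image is first
#' smoothed by a Gaussian of that bandwidth (LoG), which suppresses pixel
#' noise before differentiation.
#'
#' Boundary pixels are handled by edge replication, so a constant image maps
#' to exactly zero everywhere.
#'
#' @param image numeric matrix, at least 3x3.
#' @param sigma Gaussian bandwidth in pixels; 0 disables smoothing.
#' @return filtered matrix of the same shape, approximately zero-mean.
#' @export
#' @examples
#' whiten(matrix(runif(100), 10, 10))
whiten <- function(image, sigma = 0) {
  d <- dim(image)
  if (is.null(d) || length(d) != 2L || min(d) < 3L)
    stop("image must be a matrix of at least 3x3 pixels")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma > 0) image <- gaussian_blur(image, sigma)
  p <- pad_replicate(image, 1L)
  n1 <- d[1]; n2 <- d[2]
  p[1:n1, 2:(n2 + 1L)] + p[3:(n1 + 2L), 2:(n2 + 1L)] +
    p[2:(n1 + 1L), 1:n2] + p[2:(n1 + 1L), 3:(n2 + 2L)] - 4 * image
}

# Integer DFT sample frequencies, numpy fftfreq(n) * n.
fft_freq <- function(n) {
  f <- 0:(n - 1L)
  hi <- f >= ceiling(n / 2)
  f[hi] <- f[hi] - n
  f
}

#' Translate an image by a (possibly fractional) shift using the Fourier
#' shift theorem
#'
#' The content is displaced by `+shift` (y, x) pixels with periodic wrap;
#' `fourier_shift(img, s)[y, x] == img[y - s1, x - s2]` for integer shifts.
#' Used by the synthetic generator and by tests to construct images with an
#' exactly known sub-pixel translation.
#'
#' @param image numeric matrix.
#' @param shift length-2 numeric (dy, dx) in pixels.
#' @return shifted matrix (real part of the inverse transform).
#' @export
fourier_shift <- function(image, shift) {
  d <- dim(image)
  fy <- fft_freq(d[1]) / d[1]
  fx <- fft_freq(d[2]) / d[2]
  ph <- exp(-2i * pi * (outer(fy * shift[1], rep(1, d[2])) +
                        outer(rep(1, d[1]), fx * shift[2])))
  Re(stats::fft(stats::fft(image) * ph, inverse = TRUE)) / prod(d)
}

# Upsampled discrete Fourier transform over a small neighborhood, evaluated
# by matrix multiplication (the standard efficient sub-pixel refinement of
# cross-correlation). `data` is a frequency-domain matrix; the result samples
# its inverse transform on a grid of `size` points per axis with spacing
# 1/upsample pixels, offset by `offsets` (y, x).
upsampled_dft <- function(data, size, upsample, offsets) {
  d <- dim(data)
  kern <- function(n, off) {
    exp(-2i * pi / (n * upsample) *
          outer(seq.int(0L, size - 1L) - off, fft_freq(n)))
  }
  k1 <- kern(d[1], offsets[1])
  k2 <- kern(d[2], offsets[2])
  k1 %*% data %*% t(k2)
}

#' Normalized cross-correlation of the overlap of two images at a given shift
#'
#' Pearson correlation of the mutually overlapping pixels of `ref` and
#' `moving` once `moving` is interpreted as `ref` translated by
#' `shift` (rounded to integer pixels). Images are expected to be whitened by
#' the caller; the same convention is used for the permutation-test threshold
#' so scores are comparable.
#'
#' @param ref,moving numeric matrices of identical shape.
#' @param shift length-2 numeric (dy, dx) pixels; rounded to integers.
#' @return correlation in [-1, 1], or `NA` if the overlap is smaller than
#'   2x2 pixels or has zero variance in either image.
#' @export
nccw <- function(ref, moving, shift) {
  d <- dim(ref)
  if (!identical(dim(moving), d)) stop("images must have identical shape")
  s <- round(as.numeric(shift))
  r0 <- max(1, 1 + s[1]); r1 <- min(d[1], d[1] + s[1])
  c0 <- max(1, 1 + s[2]); c1 <- min(d[2], d[2] + s[2])
  if (r1 - r0 < 1 || c1 - c0 < 1) return(NA_real_)
  a <- ref[(r0 - s[1]):(r1 - s[1]), (c0 - s[2]):(c1 - s[2])]
  b <- moving[r0:r1, c0:c1]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

# Floor for NCC before taking -log, keeping E_NCC finite and ordered for
# spanning-tree weights.
.ncc_floor <- 1e-10

# Convert an NCC value to the E_NCC error metric (lower is better).
ncc_to_error <- function(ncc) {
  if (is.na(ncc)) return(Inf)
  -log(min(max(ncc, .ncc_floor), 1))
}

#' Sub-pixel phase correlation
#'
#' Estimates the translation between two equally shaped images by phase
#' correlation: the normalized cross-power spectrum is inverted to find the
#' integer-pixel correlation peak, which is then refined to 1/`upsample`
#' pixel resolution by sampling the cross-correlation on an upsampled grid
#' around the peak via a local matrix-multiply DFT. Both images should be
#' whitened (`whiten()`) by the caller; the alignment quality is reported as
#' `E_NCC = -log(NCC)` of the overlap at the (integer-rounded) recovered
#' shift, computed on the inputs as given.
#'
#' The returned shift `s` satisfies `moving(x) ~= ref(x - s)`: it is the
#' displacement of the moving image's content relative to the reference, so
#' translating `moving` by `-s` aligns it to `ref`.
#'
#' @param ref,moving numeric matrices of identical shape, at least 8x8.
#' @param upsample integer >= 1; sub-pixel resolution is 1/upsample pixels
#'   (default 10, i.e. 0.1 px).
#' @return a list of class `alignment` with elements `shift` (dy, dx in
#'   pixels), `ncc`, and `error` (E_NCC; `Inf` when the overlap carries no
#'   information).
#' @export
#' @examples
#' a <- matrix(runif(64 * 64), 64, 64)
#' w <- whiten(a)
#' phase_correlate(w, w)$shift  # c(0, 0)
phase_correlate <- function(ref, moving, upsample = 10L) {
  d <- dim(ref)
  if (!identical(dim(moving), d)) stop("images must have identical shape")
  if (min(d) < 8L) stop("images must be at least 8x8 pixels")
  upsample <- max(1L, as.integer(upsample))
  f1 <- stats::fft(ref)
  f2 <- stats::fft(moving)
  cp <- f1 * Conj(f2)
  m <- Mod(cp)
  mmax <- max(m)
  if (!is.finite(mmax) || mmax == 0) {
    return(structure(list(shift = c(0, 0), ncc = NA_real_, error = Inf),
                     class = "alignment"))
  }
  cpn <- cp / pmax(m, mmax * 1e-15)
  cc <- Re(stats::fft(cpn, inverse = TRUE))
  pk <- arrayInd(which.max(cc), d) - 1L
  peak <- ifelse(pk > d %/% 2, pk - d, pk)
  if (upsample > 1L) {
    peak <- round(peak * upsample) / upsample
    size <- ceiling(upsample * 1.5)
    dftshift <- floor(size / 2)
    off <- dftshift - peak * upsample
    ups <- upsampled_dft(Conj(cpn), size, upsample, off)
    mx <- arrayInd(which.max(Mod(ups)), dim(ups)) - 1L
    peak <- peak + (mx - dftshift) / upsample
  }
  shift <- -as.numeric(peak)
  ncc <- nccw(ref, moving, shift)
  structure(list(shift = shift, ncc = ncc, error = ncc_to_error(ncc)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: shift (dy, dx) = (%.3f, %.3f) px, E_NCC = %.4f\n",
              x$shift[1], x$shift[2], x$error))
  invisible(x)
}
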