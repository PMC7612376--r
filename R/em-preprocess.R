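#' Background correction and FFT bandpass filtering of a micrograph
#'
#' Subtracts a large-scale background estimate (Gaussian blur at `bgScale`),
#' then applies a radial FFT bandpass keeping structure with periods between
#' `bandSmall` and `bandLarge` pixels (linear roll-offs of 25% relative
#' width at both cut-offs; the DC component is always removed). The output
#' is rescaled to zero mean and unit variance.
#'
#' @param image a [Micrograph-class].
#' @param bgScale Gaussian sigma of the background estimate in px.
#' @param bandSmall,bandLarge kept period range in px;
#'   `bandSmall < bandLarge < min(dim)`.
#' @param standardize rescale the output to zero mean, unit variance
#'   (default TRUE; disable to inspect raw filter amplitudes).
#' @return A [Micrograph-class] with filtered, standardized pixels (same
#'   pixel size and polarity).
#' @examples
#' im <- micrograph(matrix(rnorm(64^2), 64, 64), 0.5)
#' preprocessMicrograph(im, bgScale = 16, bandSmall = 2, bandLarge = 20)
#' @export
preprocessMicrograph <- function(image, bgScale = 40, bandSmall = 2,
                                 bandLarge = 40, standardize = TRUE) {
  stopifnot(is(image, "Micrograph"))
  A <- image@pixels
  nr <- nrow(A); nc <- ncol(A)
  if (!(bandSmall < bandLarge && bandLarge < min(nr, nc)))
    stop("need bandSmall < bandLarge < min(image dims)")
  maxRadius <- 2 * floor((min(nr, nc) - 1) / 2) + 1
  radius <- min(2 * ceiling(2.5 * bgScale) + 1, maxRadius)
  bg <- EBImage::gblur(A, sigma = bgScale, radius = radius,
                       boundary = "replicate")
  x <- A - bg
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  f <- sqrt(outer(fy^2, fx^2, `+`))
  fLo <- 1 / bandLarge; fHi <- 1 / bandSmall
  up <- pmin(1, pmax(0, (f - 0.75 * fLo) / (0.5 * fLo)))
  down <- pmin(1, pmax(0, (1.25 * fHi - f) / (0.5 * fHi)))
  mask <- matrix(up * down, nr, nc)  # pmin/pmax drop the dim attributes
  mask[1L, 1L] <- 0
  out <- Re(fft(fft(x) * mask, inverse = TRUE)) / (nr * nc)
  if (standardize) {
    s <- sd(out)
    out <- if (s > 0) (out - mean(out)) / s else out * 0
  }
  micrograph(out, image@pixelSize, image@polarity)
}
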