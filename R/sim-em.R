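#' Recipe for a synthetic negative-stain-like micrograph
#'
#' Fibres are laid down as persistent random-walk polylines, each drawn from
#' one of the hierarchy's width classes, and rendered as rectangular
#' cross-profiles convolved with a Gaussian point-spread function on a
#' slowly varying noisy background. Default class widths follow the 2-nm and
#' 4-nm fibre populations (means at the taxonomy's nominal widths, spreads
#' of 0.4 and 1.0 nm); fibre lengths are drawn from the discrete allowed
#' lengths of the end-to-end assembly rule.
#'
#' @param sizePx image side in pixels (square image).
#' @param pixelSize nm per pixel.
#' @param counts named integer vector of fibres per class; names must index
#'   rows of `classes`.
#' @param classes data.frame with columns `label`, `meanWidth`, `sdWidth`
#'   (nm).
#' @param persistence persistence length of the fibre walk in nm.
#' @param contrast fibre peak amplitude relative to background units.
#' @param bgAmplitude amplitude of the smooth background gradient.
#' @param noiseSd white-noise standard deviation.
#' @param psfSigma Gaussian PSF sigma in px.
#' @param polarity `"DARK_RIDGES"` or `"BRIGHT_RIDGES"`.
#' @param nSubunitRange integer range of end-to-end subunit counts from
#'   which fibre lengths are drawn via [predictFibreLength()].
#' @param minSeparation minimum centreline separation between fibres in nm.
#' @param rule the [AssemblyRule-class] defining the allowed lengths.
#' @param seed integer RNG seed.
#' @return A validated recipe (list with class `"MicrographRecipe"`).
#' @seealso [simulateMicrograph()]
#' @examples
#' micrographRecipe(sizePx = 256, counts = c("2:2-fibre" = 3))
#' @export
micrographRecipe <- function(sizePx = 512L, pixelSize = 0.5,
                             counts = c("2:2-fibre" = 8L, "4:4-fibre" = 8L),
                             classes = data.frame(
                               label = c("2:2-fibre", "4:4-fibre",
                                         "10-nm fibre"),
                               meanWidth = c(2, 4, 10),
                               sdWidth = c(0.4, 1.0, 2.4)),
                             persistence = 2000, contrast = 1,
                             bgAmplitude = 0.2, noiseSd = 0.05,
                             psfSigma = 1,
                             polarity = c("DARK_RIDGES", "BRIGHT_RIDGES"),
                             nSubunitRange = c(2L, 6L),
                             minSeparation = 8, rule = assemblyRule(),
                             seed = 1L) {
  polarity <- match.arg(polarity)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(names(counts) %in% classes$label))
    stop("counts names must match class labels")
  if (any(classes$meanWidth <= 0)) stop("class widths must be positive")
  if (persistence <= 0) stop("persistence must be positive")
  maxLenPx <- predictFibreLength(max(nSubunitRange), rule) / pixelSize
  if (maxLenPx > 0.85 * sizePx)
    stop("image too small for the requested fibre lengths")
  structure(list(sizePx = as.integer(sizePx), pixelSize = pixelSize,
                 counts = counts, classes = classes,
                 persistence = persistence, contrast = contrast,
                 bgAmplitude = bgAmplitude, noiseSd = noiseSd,
                 psfSigma = psfSigma, polarity = polarity,
                 nSubunitRange = as.integer(nSubunitRange),
                 minSeparation = minSeparation, rule = rule,
                 seed = as.integer(seed)),
            class = "MicrographRecipe")
}

# Minimum distance from points P (m x 2, columns x/y) to a polyline.
.distToPolyline <- function(P, poly) {
  dmin <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(poly) - 1L)) {
    p1 <- poly[i, ]; seg <- poly[i + 1L, ] - p1
    len2 <- sum(seg^2)
    if (len2 == 0) next
    t <- pmin(1, pmax(0, ((P[, 1L] - p1[1L]) * seg[1L] +
                          (P[, 2L] - p1[2L]) * seg[2L]) / len2))
    dx <- P[, 1L] - (p1[1L] + t * seg[1L])
    dy <- P[, 2L] - (p1[2L] + t * seg[2L])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

# Arc length of a polyline in px.
.polyLength <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(rowSums(diff(poly)^2)))
}

#' Render fibre profiles onto a pixel grid
#'
#' Deterministically renders fibres (polyline centrelines with per-fibre
#' widths, px) as rectangular cross-profiles convolved with a Gaussian PSF:
#' at signed distance d from the centreline the profile is
#' `pnorm((w/2 - d)/s) - pnorm((-w/2 - d)/s)`. Overlapping fibres add.
#'
#' @param polylines list of m x 2 (x, y) matrices in px.
#' @param widthsPx per-fibre rendered widths in px.
#' @param sizePx image side in px.
#' @param psfSigma PSF sigma in px.
#' @return A `sizePx` x `sizePx` numeric matrix (rows = y, columns = x).
#' @export
renderFibreField <- function(polylines, widthsPx, sizePx, psfSigma = 1) {
  field <- matrix(0, sizePx, sizePx)
  for (i in seq_along(polylines)) {
    poly <- polylines[[i]]
    w <- widthsPx[i]
    pad <- ceiling(w / 2 + 4 * psfSigma + 1)
    xr <- max(1L, floor(min(poly[, 1L])) - pad):min(sizePx, ceiling(max(poly[, 1L])) + pad)
    yr <- max(1L, floor(min(poly[, 2L])) - pad):min(sizePx, ceiling(max(poly[, 2L])) + pad)
    P <- cbind(rep(xr, each = length(yr)), rep(yr, times = length(xr)))
    d <- .distToPolyline(P, poly)
    prof <- pnorm((w / 2 - d) / psfSigma) - pnorm((-w / 2 - d) / psfSigma)
    field[cbind(P[, 2L], P[, 1L])] <- field[cbind(P[, 2L], P[, 1L])] + prof
  }
  field
}

# One persistent random-walk polyline of given arc length, retried until it
# stays inside the margin and clears existing fibres.
.sampleWalk <- function(lengthPx, sizePx, margin, minSepPx, existing,
                        stepPx, turnSd, maxTries = 500L) {
  n <- max(2L, ceiling(lengthPx / stepPx) + 1L)
  for (try in seq_len(maxTries)) {
    start <- runif(2L, margin, sizePx - margin)
    theta <- runif(1L, 0, 2 * pi) + cumsum(c(0, rnorm(n - 1L, 0, turnSd)))
    poly <- cbind(start[1L] + cumsum(c(0, stepPx * cos(theta[-1L]))),
                  start[2L] + cumsum(c(0, stepPx * sin(theta[-1L]))))
    if (any(poly < margin) || any(poly > sizePx - margin)) next
    ok <- TRUE
    for (ex in existing) {
      if (min(.distToPolyline(poly, ex)) < minSepPx) { ok <- FALSE; break }
    }
    if (ok) return(poly)
  }
  stop("could not place a fibre; image too small or too crowded")
}

#' Simulate a negative-stain-like micrograph with ground truth
#'
#' @param recipe a [micrographRecipe()].
#' @return A list with `image` (a [Micrograph-class]), `truth` (data.frame
#'   `id`, `class`, `widthNm`, `lengthNm`) and `polylines` (list of px
#'   centrelines). Re-rendering the truth with [renderFibreField()]
#'   reproduces the noise-free fibre field exactly.
#' @examples
#' sim <- simulateMicrograph(micrographRecipe(sizePx = 256,
#'                                            counts = c("2:2-fibre" = 2)))
#' sim$truth
#' @export
simulateMicrograph <- function(recipe) {
  stopifnot(inherits(recipe, "MicrographRecipe"))
  withr::with_seed(recipe$seed, {
    stepPx <- 2
    turnSd <- sqrt(stepPx * recipe$pixelSize / recipe$persistence)
    labels <- rep(names(recipe$counts), times = recipe$counts)
    widths <- vapply(labels, function(lab) {
      cls <- recipe$classes[recipe$classes$label == lab, ]
      w <- -1
      while (w < 0.5) w <- rnorm(1L, cls$meanWidth, cls$sdWidth)
      w
    }, numeric(1L))
    nsub <- sample(seq(recipe$nSubunitRange[1L], recipe$nSubunitRange[2L]),
                   length(labels), replace = TRUE)
    targetLen <- if (length(labels)) predictFibreLength(nsub, recipe$rule)
                 else numeric()
    # place the longest fibres first: they are the hardest to fit
    ord <- order(targetLen, decreasing = TRUE)
    polylines <- vector("list", length(labels))
    for (i in ord) {
      wPx <- widths[i] / recipe$pixelSize
      margin <- ceiling(wPx / 2 + 4 * recipe$psfSigma + 2)
      polylines[[i]] <- .sampleWalk(
        targetLen[i] / recipe$pixelSize, recipe$sizePx, margin,
        recipe$minSeparation / recipe$pixelSize,
        Filter(Negate(is.null), polylines), stepPx, turnSd)
    }
    lengths <- vapply(polylines, .polyLength, numeric(1L)) * recipe$pixelSize
    field <- renderFibreField(polylines,
                              widths / recipe$pixelSize,
                              recipe$sizePx, recipe$psfSigma)
    n <- recipe$sizePx
    gdir <- runif(2L, -1, 1)
    X <- matrix(rep(seq_len(n), each = n), n, n)  # column index = x
    Y <- matrix(rep(seq_len(n), times = n), n, n)
    bg <- 0.5 + recipe$bgAmplitude * (gdir[1L] * X + gdir[2L] * Y) / n
    sgn <- if (recipe$polarity == "DARK_RIDGES") -1 else 1
    px <- bg + sgn * recipe$contrast * field +
      matrix(rnorm(n * n, 0, recipe$noiseSd), n, n)
    truth <- data.frame(id = seq_along(labels), class = labels,
                        widthNm = widths, lengthNm = lengths,
                        stringsAsFactors = FALSE)
    list(image = micrograph(px, recipe$pixelSize, recipe$polarity),
         truth = truth, polylines = polylines)
  })
}
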