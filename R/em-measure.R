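#' Tabulate detected fibre traces in physical units
#'
#' @param traces list of [FibreTrace-class] objects (lengths and widths
#'   already in nm, as produced by [detectRidges()]).
#' @param pixelSize nm per pixel; only used when a trace carries pixel
#'   units (lengths stored as `NA`), kept for interface completeness.
#' @param minLengthNm traces shorter than this are dropped (default 0).
#' @return A data.frame sorted by id: `id`, `length_nm`, `mean_width_nm`,
#'   `n_points`.
#' @examples
#' measureFibres(list(), 0.5)
#' @export
measureFibres <- function(traces, pixelSize = 1, minLengthNm = 0) {
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (!length(traces))
    return(data.frame(id = integer(), length_nm = numeric(),
                      mean_width_nm = numeric(), n_points = integer()))
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(id = tr@id, length_nm = tr@length,
               mean_width_nm = tr@meanWidth,
               n_points = nrow(tr@centerline))
  }))
  tab <- tab[tab$length_nm >= minLengthNm, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Histogram of fibre widths in fixed-size bins
#'
#' Left-closed, right-open bins starting at zero; total counts equal the
#' number of widths.
#'
#' @param widths fibre widths in nm.
#' @param bin bin width in nm (0.5 for fine population plots, 2 for survey
#'   histograms).
#' @return A data.frame `lower`, `upper`, `count` covering only occupied
#'   range; zero rows for empty input.
#' @examples
#' widthHistogram(c(2.3, 2.4, 3.6), bin = 0.5)
#' @export
widthHistogram <- function(widths, bin = 0.5) {
  if (bin <= 0) stop("bin must be positive")
  widths <- widths[is.finite(widths)]
  if (!length(widths))
    return(data.frame(lower = numeric(), upper = numeric(),
                      count = integer()))
  idx <- floor(widths / bin)
  edges <- 0:(max(idx) + 1L)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.frame(lower = edges[-length(edges)] * bin,
             upper = edges[-1L] * bin, count = counts)
}

#' Fit Gaussian width populations to measured fibre widths
#'
#' Fits a one-dimensional `k`-component Gaussian mixture with
#' unequal variances (mclust model "V", deterministic model-based
#' initialization) and reports each component's mean, standard deviation
#' and hard-assigned fibre count; components are sorted by mean and hard
#' counts sum to the number of fibres. With `k = 1` the sample mean and
#' (n-1 denominator) standard deviation are returned exactly.
#'
#' @param widths fibre widths in nm, at least `2k` values.
#' @param k number of components.
#' @param seed unused by the deterministic fit; kept so recipes carrying a
#'   seed can pass it through.
#' @return A data.frame `label`, `mean`, `sd`, `n`, plus attribute
#'   `classification` (per-fibre hard assignment, components in mean
#'   order).
#' @importFrom mclust Mclust mclustBIC
#' @examples
#' set.seed(1)
#' w <- c(rnorm(60, 2, 0.4), rnorm(60, 4, 1))
#' fitWidthPopulations(w, k = 2)
#' @export
fitWidthPopulations <- function(widths, k, seed = NULL) {
  widths <- as.numeric(widths)
  if (length(widths) < 2 * k) stop("need at least 2k widths")
  if (length(unique(widths)) < k || sd(widths) == 0)
    stop("degenerate fit: fewer distinct widths than components")
  if (k == 1L) {
    out <- data.frame(label = "population 1", mean = mean(widths),
                      sd = sd(widths), n = length(widths))
    attr(out, "classification") <- rep(1L, length(widths))
    return(out)
  }
  fit <- tryCatch(
    Mclust(widths, G = k, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    stop("degenerate fit: mixture estimation failed")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  sig <- rep_len(sig, k)
  ord <- order(mu)
  cls <- match(fit$classification, ord)
  out <- data.frame(label = paste("population", seq_len(k)),
                    mean = mu[ord], sd = sig[ord],
                    n = as.integer(tabulate(cls, nbins = k)))
  attr(out, "classification") <- cls
  out
}

#' End-to-end micrograph quantification
#'
#' Convenience pipeline: [preprocessMicrograph()], [detectRidges()],
#' [measureFibres()], [widthHistogram()] and (when `k > 0` and enough
#' fibres are found) [fitWidthPopulations()].
#'
#' @param image a raw [Micrograph-class].
#' @param expectedWidthNm expected fibre width used to set the detection
#'   scale `sigma = w_px / (2 sqrt(3))`.
#' @param bgScale,bandSmall,bandLarge preprocessing parameters (px).
#' @param highThresh,lowThresh,minLengthNm detection parameters.
#' @param bin histogram bin in nm.
#' @param k mixture components (0 to skip population fitting).
#' @return List with `fibres` (measurement table), `histogram`,
#'   `populations` (or NULL) and `traces`.
#' @examples
#' sim <- simulateMicrograph(micrographRecipe(sizePx = 256,
#'                                            counts = c("4:4-fibre" = 2)))
#' qn <- quantifyMicrograph(sim$image, expectedWidthNm = 4, k = 0)
#' qn$fibres
#' @export
quantifyMicrograph <- function(image, expectedWidthNm = 4, bgScale = 40,
                               bandSmall = 2, bandLarge = 40,
                               highThresh = NULL, lowThresh = NULL,
                               minLengthNm = 15, bin = 0.5, k = 2L) {
  pre <- preprocessMicrograph(image, bgScale, bandSmall, bandLarge)
  sigma <- (expectedWidthNm / image@pixelSize) / (2 * sqrt(3))
  traces <- detectRidges(pre, sigma = sigma, highThresh = highThresh,
                         lowThresh = lowThresh,
                         minLength = minLengthNm / image@pixelSize)
  fib <- measureFibres(traces, image@pixelSize, minLengthNm)
  hist <- widthHistogram(fib$mean_width_nm, bin)
  pops <- NULL
  if (k > 0L && nrow(fib) >= 2L * k)
    pops <- tryCatch(fitWidthPopulations(fib$mean_width_nm, k),
                     error = function(e) NULL)
  list(fibres = fib, histogram = hist, populations = pops, traces = traces)
}
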