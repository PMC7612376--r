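# Self-consistent low-q window fit shared by the overall and cross-sectional
# Guinier analyses. `slope2R` maps the fitted slope to the size parameter in
# Angstrom. Within the converged q*R window the limiting q^2 slope is taken
# from a second-order fit (y ~ q^2 + q^4) whenever the quadratic departure
# from Guinier linearity is statistically significant: rod-like curves bend
# within the conventional window and a plain linear fit then biases R low by
# several percent, while on featureless noisy data the second-order term is
# insignificant and the plain linear fit is kept.
.guinierEngine <- function(q, y, qLow, limit, slope2R, minPoints, what,
                           useQuad = TRUE, initFull = FALSE) {
  usable <- which(is.finite(y) & q > qLow)
  if (length(usable) < minPoints)
    stop("insufficient usable points for ", what, " analysis")
  estimate <- function(sel) {
    x <- q[sel]^2
    lf <- lm(y[sel] ~ x)
    slope <- coef(lf)[[2L]]
    out <- list(slope = slope, intercept = coef(lf)[[1L]],
                r2 = suppressWarnings(summary(lf)$r.squared), quad = FALSE)
    if (useQuad && length(sel) >= minPoints + 3L) {
      qf <- tryCatch(lm(y[sel] ~ x + I(x^2)), error = function(e) NULL)
      cf <- if (is.null(qf)) NULL
            else tryCatch(suppressWarnings(summary(qf)$coefficients),
                          error = function(e) NULL)
      if (!is.null(cf) && nrow(cf) == 3L && is.finite(cf[3L, 3L]) &&
          abs(cf[3L, 3L]) > 3 && is.finite(coef(qf)[[2L]])) {
        out$slope <- coef(qf)[[2L]]
        out$intercept <- coef(qf)[[1L]]
        out$quad <- TRUE
      }
    }
    out
  }
  toR <- function(slope) {
    if (!is.finite(slope) || slope > 1e-12)
      stop("no ", what, " region: non-negative low-q slope")
    if (slope > -1e-12) 0 else slope2R(slope)
  }
  # start either from the full usable range (cross-section: the window top
  # is found by shrinking) or from a minimal low-q window widened until the
  # slope is non-positive (tiny windows can be noise-dominated)
  if (initFull) {
    sel <- usable
    slope <- coef(lm(y[sel] ~ I(q[sel]^2)))[[2L]]
    if (!is.finite(slope) || slope > 1e-12)
      stop("no ", what, " region: non-negative low-q slope")
  } else {
    n0 <- min(max(minPoints, 8L), length(usable))
    sel <- usable[seq_len(n0)]
    repeat {
      slope <- coef(lm(y[sel] ~ I(q[sel]^2)))[[2L]]
      if (is.finite(slope) && slope <= 1e-12) break
      if (length(sel) == length(usable))
        stop("no ", what, " region: non-negative low-q slope")
      sel <- usable[seq_len(min(2L * length(sel), length(usable)))]
    }
  }
  # extend/shrink until the q*R ceiling is self-consistent
  lastSel <- integer()
  est <- NULL
  for (iter in 1:100) {
    est <- estimate(sel)
    R <- toR(est$slope)
    newSel <- if (R > 0) usable[q[usable] <= limit / R] else usable
    if (length(newSel) < minPoints) newSel <- usable[seq_len(minPoints)]
    if (identical(newSel, sel) || identical(newSel, lastSel)) {
      sel <- newSel
      break
    }
    lastSel <- sel
    sel <- newSel
  }
  est <- estimate(sel)
  R <- toR(est$slope)
  list(R = R, intercept = est$intercept,
       qWindow = range(q[sel]), maxQR = max(q[sel]) * R,
       r2 = est$r2, n = length(sel))
}

#' Guinier analysis: radius of gyration from the low-q region
#'
#' Fits `ln I` against `q^2` over the largest low-q window that satisfies
#' `q * Rg < qRgLimit` under self-consistent re-fitting, starting from the
#' lowest usable point. `Rg = sqrt(-3 * slope)`.
#'
#' @param curve a [SAXSCurve-class].
#' @param qRgLimit the q*Rg validity ceiling (default 1.3, the usual
#'   criterion for rod-like particles).
#' @param minPoints minimum usable low-q points (default 5).
#' @return A [GuinierFit-class] (Rg in nm).
#' @examples
#' q <- seq(0.002, 0.05, by = 0.001)
#' guinierFit(saxsCurve(q, exp(-q^2 * 49^2 / 3)))  # Rg = 4.9 nm
#' @export
guinierFit <- function(curve, qRgLimit = 1.3, minPoints = 5L) {
  stopifnot(is(curve, "SAXSCurve"))
  q <- curve@q
  y <- rep(NA_real_, length(q))
  pos <- curve@I > 0
  y[pos] <- log(curve@I[pos])
  res <- .guinierEngine(q, y, qLow = 0, limit = qRgLimit,
                        slope2R = function(s) sqrt(-3 * s),
                        minPoints = minPoints, what = "Guinier")
  new("GuinierFit", Rg = res$R / 10, I0 = exp(res$intercept),
      qWindow = res$qWindow, maxQRg = res$maxQR, r2 = res$r2,
      nPoints = as.integer(res$n))
}

#' Cross-sectional Guinier analysis of a rod-like particle
#'
#' Fits `ln(q I)` against `q^2` over an intermediate-q window with
#' `q * Rc < qRcLimit`, excluding the overall-size regime below
#' `rgExclusion / Rg`. `Rc = sqrt(-2 * slope)`; for a uniform cylinder of
#' radius R, `Rc = R / sqrt(2)`.
#'
#' @param curve a [SAXSCurve-class]; must extend beyond the rod's overall
#'   Guinier region.
#' @param qRcLimit the q*Rc ceiling (default 1.3).
#' @param Rg overall radius of gyration in nm used to set the window's lower
#'   bound; computed by [guinierFit()] when omitted.
#' @param rgExclusion lower bound of the window as a multiple of 1/Rg
#'   (default 1.3).
#' @param minPoints minimum points in the window.
#' @return A [CrossSectionFit-class] (Rc in nm).
#' @examples
#' cv <- cylinderIntensity(19, 1.7, seq(0.004, 0.25, by = 0.002))
#' crossSectionFit(cv)  # Rc ~ 1.7/sqrt(2)
#' @export
crossSectionFit <- function(curve, qRcLimit = 1.3, Rg = NULL,
                            rgExclusion = 1.3, minPoints = 5L) {
  stopifnot(is(curve, "SAXSCurve"))
  if (is.null(Rg)) Rg <- guinierFit(curve)@Rg
  q <- curve@q
  y <- rep(NA_real_, length(q))
  pos <- curve@I > 0 & q > 0
  y[pos] <- log(q[pos] * curve@I[pos])
  # the rod regime needs q well above both the overall-size rolloff
  # (rgExclusion/Rg) and the finite-length rolloff (~1.5 * 2 pi / L); the
  # rod length is estimated from Rg (and refined once Rc is known via
  # Rg^2 = L^2/12 + Rc^2). The length bound is relaxed stepwise if it
  # leaves too few points.
  RgA <- Rg * 10
  Lest <- sqrt(12) * RgA
  res <- NULL
  for (pass in 1:2) {
    for (cFac in c(1.5, 1.0, 0.5, 0.25, 0)) {
      qLow <- max(rgExclusion / RgA, cFac * 2 * pi / Lest)
      res <- tryCatch(
        .guinierEngine(q, y, qLow = qLow, limit = qRcLimit,
                       slope2R = function(s) sqrt(-2 * s),
                       minPoints = minPoints, what = "cross-section",
                       useQuad = FALSE, initFull = TRUE),
        error = function(e) e)
      if (!inherits(res, "error") || grepl("non-negative", conditionMessage(res)))
        break
    }
    if (inherits(res, "error")) stop(res)
    Lest <- sqrt(max(12 * (RgA^2 - res$R^2), (2 * RgA)^2 / 100))
  }
  new("CrossSectionFit", Rc = res$R / 10, qWindow = res$qWindow,
      maxQRc = res$maxQR, r2 = res$r2, nPoints = as.integer(res$n))
}

#' Least-squares scale and reduced chi-square of a model against data
#'
#' The scale `c` minimizing `sum(((c * Imodel - Idata) / sigma)^2)` has the
#' closed form `sum(Im Id / s^2) / sum(Im^2 / s^2)`; the reduced chi-square
#' divides the minimum by `N - 1`.
#'
#' @param modelCurve model [SAXSCurve-class]; its q range must cover the
#'   data's (it is linearly interpolated onto the data grid).
#' @param dataCurve data [SAXSCurve-class] with sigma.
#' @return A list with elements `scale` and `chi2`.
#' @examples
#' q <- seq(0.01, 0.2, by = 0.01)
#' m <- saxsCurve(q, exp(-10 * q))
#' d <- saxsCurve(q, 3.7 * exp(-10 * q), sigma = rep(0.01, length(q)))
#' chi2Fit(m, d)
#' @export
chi2Fit <- function(modelCurve, dataCurve) {
  stopifnot(is(modelCurve, "SAXSCurve"), is(dataCurve, "SAXSCurve"))
  if (!length(dataCurve@sigma)) stop("data curve must carry sigma")
  if (any(dataCurve@sigma <= 0)) stop("sigma must be strictly positive")
  if (min(dataCurve@q) < min(modelCurve@q) - 1e-12 ||
      max(dataCurve@q) > max(modelCurve@q) + 1e-12)
    stop("model q range does not cover the data q range")
  Im <- approx(modelCurve@q, modelCurve@I, xout = dataCurve@q)$y
  Id <- dataCurve@I
  s2 <- dataCurve@sigma^2
  sc <- sum(Im * Id / s2) / sum(Im^2 / s2)
  chi2 <- sum((sc * Im - Id)^2 / s2) / (length(Id) - 1L)
  list(scale = sc, chi2 = chi2)
}
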