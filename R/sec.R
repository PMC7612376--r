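#' Frame-by-frame rod analysis of a SEC-SAXS elution series
#'
#' Applies [guinierFit()], [crossSectionFit()] and [iftPofr()] to each frame
#' of an elution series and tabulates forward intensity, Rg, Rc and Dmax.
#' Dmax is reported as `NA` ("undetermined") whenever the Shannon criterion
#' flags the selected Dmax as unreliable for the frame's q range. Per-frame
#' failures are recorded in the `status` column and never abort the series.
#'
#' @param frames list of [SAXSCurve-class] objects, in elution order.
#' @param dmaxCandidates candidate Dmax grid in nm passed to [iftPofr()].
#' @param qRgLimit,qRcLimit Guinier validity ceilings.
#' @param ... further arguments passed to [iftPofr()].
#' @return A data.frame with one row per frame: `frame`, `I0`, `Rg`, `Rc`,
#'   `Dmax`, `shannonReliable`, `status` (`"ok"` or the failure message).
#' @examples
#' cv <- cylinderIntensity(19, 1.9, seq(0.004, 0.25, by = 0.002))
#' obs <- simulateSAXS(cv, noiseModel(seed = 1))
#' analyzeSECSeries(list(obs), dmaxCandidates = seq(12, 30, by = 1))
#' @export
analyzeSECSeries <- function(frames, dmaxCandidates = seq(10, 90, by = 1),
                             qRgLimit = 1.3, qRcLimit = 1.3, ...) {
  if (length(frames) < 1L) stop("need at least one frame")
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    row <- data.frame(frame = i, I0 = NA_real_, Rg = NA_real_, Rc = NA_real_,
                      Dmax = NA_real_, shannonReliable = NA, status = "ok",
                      stringsAsFactors = FALSE)
    status <- character()
    gf <- tryCatch(guinierFit(fr, qRgLimit = qRgLimit),
                   error = function(e) e)
    if (inherits(gf, "error")) {
      status <- c(status, conditionMessage(gf))
    } else {
      row$I0 <- gf@I0; row$Rg <- gf@Rg
      cf <- tryCatch(crossSectionFit(fr, qRcLimit = qRcLimit, Rg = gf@Rg),
                     error = function(e) e)
      if (inherits(cf, "error")) status <- c(status, conditionMessage(cf))
      else row$Rc <- cf@Rc
      pr <- tryCatch(iftPofr(fr, dmaxCandidates = dmaxCandidates, ...),
                     error = function(e) e)
      if (inherits(pr, "error")) {
        status <- c(status, conditionMessage(pr))
      } else {
        sh <- attr(pr, "shannon")
        row$shannonReliable <- sh$reliable
        row$Dmax <- if (sh$reliable) pr@Dmax else NA_real_
      }
    }
    if (length(status)) row$status <- paste(status, collapse = "; ")
    row
  })
  do.call(rbind, rows)
}
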