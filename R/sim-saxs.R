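#' Add Gaussian counting-like noise to a model SAXS curve
#'
#' Observed intensities are `I + e` with `e ~ Normal(0, s(q))` and
#' `s(q) = relativeSd * I(q) + floorSd`; the sigma column of the returned
#' curve is set to `s(q)`. The draw is reproducible under the noise model's
#' seed.
#'
#' @param curve a model [SAXSCurve-class].
#' @param noise a [NoiseModel-class].
#' @return A [SAXSCurve-class] with sigma.
#' @examples
#' cv <- cylinderIntensity(19, 1.7, seq(0.005, 0.2, by = 0.005))
#' simulateSAXS(cv, noiseModel(seed = 42))
#' @export
simulateSAXS <- function(curve, noise = noiseModel()) {
  stopifnot(is(curve, "SAXSCurve"), is(noise, "NoiseModel"))
  s <- noise@relativeSd * abs(curve@I) + noise@floorSd
  Iobs <- withr::with_seed(noise@seed, curve@I + rnorm(length(curve@I), 0, s))
  saxsCurve(curve@q, Iobs, sigma = s)
}

#' Recipe for a simulated SEC-SAXS elution series
#'
#' @param mixtures list with one element per frame; each element is a list
#'   of `list(spec = <FibreModelSpec>, fraction = <weight>)` entries whose
#'   fractions sum to 1.
#' @param qGrid shared q grid in inverse Angstrom.
#' @param noise a [NoiseModel-class]; frame f is drawn with `seed + f`.
#' @return A validated recipe object (list with class
#'   `"SECSeriesRecipe"`).
#' @seealso [simulateSECSeries()]
#' @examples
#' r44 <- fibreModelSpec(subunitSpec("FOUR_FOUR"), 1)
#' secSeriesRecipe(list(list(list(spec = r44, fraction = 1))),
#'                 qGrid = seq(0.004, 0.2, by = 0.002))
#' @export
secSeriesRecipe <- function(mixtures, qGrid, noise = noiseModel()) {
  if (length(mixtures) < 1L) stop("need at least one frame")
  for (f in seq_along(mixtures)) {
    fr <- mixtures[[f]]
    fracs <- vapply(fr, `[[`, numeric(1L), "fraction")
    if (any(fracs < 0) || abs(sum(fracs) - 1) > 1e-9)
      stop("frame ", f, ": fractions must be non-negative and sum to 1")
    for (sp in fr) stopifnot(is(sp$spec, "FibreModelSpec"))
  }
  structure(list(mixtures = mixtures, qGrid = qGrid, noise = noise),
            class = "SECSeriesRecipe")
}

#' Standard elution ladder of assembly species for a SEC-SAXS sweep
#'
#' Five frames emulating a size-exclusion elution peak of a fibre-forming
#' sample: early frames are dominated by long, thin 2:2 fibres (four, then
#' three, then two end-to-end subunits) and late frames by the single 4:4
#' complex, so the series shows the characteristic decreasing Dmax and
#' increasing cross-sectional radius.
#'
#' @param rule an [AssemblyRule-class].
#' @return A list of per-frame mixtures suitable for [secSeriesRecipe()].
#' @examples
#' length(elutionLadderMixtures())
#' @export
elutionLadderMixtures <- function(rule = assemblyRule()) {
  f22 <- function(n) fibreModelSpec(subunitSpec("TWO_TWO"), n, rule = rule)
  s44 <- fibreModelSpec(subunitSpec("FOUR_FOUR"), 1L, rule = rule)
  list(
    list(list(spec = f22(4L), fraction = 1)),
    list(list(spec = f22(3L), fraction = 0.75),
         list(spec = s44, fraction = 0.25)),
    list(list(spec = f22(2L), fraction = 0.5),
         list(spec = s44, fraction = 0.5)),
    list(list(spec = f22(2L), fraction = 0.2),
         list(spec = s44, fraction = 0.8)),
    list(list(spec = s44, fraction = 1)))
}

#' Simulate a SEC-SAXS elution series of assembly-species mixtures
#'
#' Each frame's model intensity is the fraction-weighted sum of the Debye
#' curves of its species' bead models (species curves are computed once and
#' cached across frames), to which [simulateSAXS()] noise is added with a
#' per-frame seed.
#'
#' @param recipe a [secSeriesRecipe()].
#' @param beadRadius bead radius passed to [buildFibreBeads()].
#' @return List of [SAXSCurve-class] frames with sigma.
#' @examples
#' r44 <- fibreModelSpec(subunitSpec("FOUR_FOUR"), 1)
#' rec <- secSeriesRecipe(list(list(list(spec = r44, fraction = 1))),
#'                        qGrid = seq(0.004, 0.2, by = 0.002))
#' simulateSECSeries(rec)
#' @export
simulateSECSeries <- function(recipe, beadRadius = 0.25) {
  stopifnot(inherits(recipe, "SECSeriesRecipe"))
  cache <- new.env(parent = emptyenv())
  speciesCurve <- function(spec) {
    key <- sprintf("%s|%d|%d|%g", spec@subunit@kind, spec@nSubunits,
                   spec@lateralCopies, beadRadius)
    if (is.null(cache[[key]]))
      cache[[key]] <- debyeIntensity(buildFibreBeads(spec, beadRadius),
                                     recipe$qGrid)@I
    cache[[key]]
  }
  lapply(seq_along(recipe$mixtures), function(f) {
    fr <- recipe$mixtures[[f]]
    I <- Reduce(`+`, lapply(fr, function(sp) sp$fraction * speciesCurve(sp$spec)))
    nm <- recipe$noise
    simulateSAXS(saxsCurve(recipe$qGrid, I),
                 noiseModel(nm@relativeSd, nm@floorSd, nm@seed + f))
  })
}
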