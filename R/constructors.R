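#' Construct a building-block specification
#'
#' Defaults are the calibrated crystallographic dimensions: a 14-nm core that
#' extends to 19 nm with the C-terminal S2C/Ctip helices, 2-nm width and
#' thickness for the 2:2 complex, and a doubled 4-nm width for the laterally
#' tessellated 4:4 complex.
#'
#' @param kind `"TWO_TWO"` or `"FOUR_FOUR"`.
#' @param coreLength,extendedLength,width,thickness rod dimensions in nm;
#'   defaults depend on `kind`.
#' @param chainStoichiometry copies of (SYCE2, TEX12).
#' @return A [SubunitSpec-class].
#' @examples
#' subunitSpec("FOUR_FOUR")
#' @export
subunitSpec <- function(kind = c("TWO_TWO", "FOUR_FOUR"),
                        coreLength = 14, extendedLength = 19,
                        width = NULL, thickness = 2,
                        chainStoichiometry = NULL) {
  kind <- match.arg(kind)
  if (is.null(width)) width <- if (kind == "TWO_TWO") 2 else 4
  if (is.null(chainStoichiometry))
    chainStoichiometry <- if (kind == "TWO_TWO") c(2L, 2L) else c(4L, 4L)
  new("SubunitSpec", kind = kind, coreLength = coreLength,
      extendedLength = extendedLength, width = width, thickness = thickness,
      chainStoichiometry = as.integer(chainStoichiometry))
}

#' Construct an assembly rule
#'
#' @param initialLength nm of the first subunit (default 20).
#' @param increment nm per additional subunit (default 15).
#' @param latticeTranslation long-axis crystallographic translation in
#'   Angstrom (default 156).
#' @param lateralSpacing lateral repeat in nm (default 5).
#' @param tenNmFibreNominal,bundleMax nominal 10-nm fibre width and maximum
#'   bundle width in nm.
#' @return An [AssemblyRule-class].
#' @examples
#' assemblyRule()
#' @export
assemblyRule <- function(initialLength = 20, increment = 15,
                         latticeTranslation = 156, lateralSpacing = 5,
                         tenNmFibreNominal = 10, bundleMax = 40) {
  new("AssemblyRule", initialLength = initialLength, increment = increment,
      latticeTranslation = latticeTranslation, lateralSpacing = lateralSpacing,
      tenNmFibreNominal = tenNmFibreNominal, bundleMax = bundleMax)
}

#' Construct a width taxonomy
#'
#' The default boundaries sit between the nominal class widths (2, 4, 10 and
#' up to 40 nm): 2:2 fibres below 3 nm, 4:4 fibres in \[3, 7) nm, 10-nm
#' fibres in \[7, 20) nm and bundles in \[20, 40\] nm. Intervals are
#' left-closed, right-open (the bundle class closes at `bundleMax`).
#'
#' @param label,nominal,lower,upper parallel vectors defining the classes.
#' @return A [WidthTaxonomy-class].
#' @examples
#' widthTaxonomy()
#' @export
widthTaxonomy <- function(label = c("2:2-fibre", "4:4-fibre",
                                    "10-nm fibre", "bundled fibre"),
                          nominal = c(2, 4, 10, 40),
                          lower = c(0, 3, 7, 20),
                          upper = c(3, 7, 20, 40 + 1e-9)) {
  new("WidthTaxonomy", label = label, nominal = nominal,
      lower = lower, upper = upper)
}

#' Construct an SC mass model
#'
#' @param crossSectionSide side of the square cross-section in nm.
#' @param solventFraction solvent volume fraction in \[0, 1\].
#' @param proteinDensity protein density in g/cm^3.
#' @return A [MassModel-class].
#' @examples
#' massModel(solventFraction = 0.8)
#' @export
massModel <- function(crossSectionSide = 100, solventFraction = 0.5,
                      proteinDensity = 1.33) {
  new("MassModel", crossSectionSide = crossSectionSide,
      solventFraction = solventFraction, proteinDensity = proteinDensity)
}

#' Construct a bead model
#'
#' @param coords n x 3 matrix of bead centres in nm (x, y, z).
#' @param radius bead radii in nm (recycled).
#' @param weight scattering weights (recycled).
#' @param label model label.
#' @return A [BeadModel-class].
#' @examples
#' beadModel(rbind(c(0, 0, 0), c(0, 0, 10)), radius = 0.5)
#' @export
beadModel <- function(coords, radius = 0.25, weight = 1, label = "beads") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  new("BeadModel", coords = unname(coords),
      radius = rep_len(radius, n), weight = rep_len(weight, n), label = label)
}

#' Construct a fibre model specification
#'
#' @param subunit a [SubunitSpec-class].
#' @param nSubunits end-to-end subunit count.
#' @param lateralCopies laterally associated copies (default 1).
#' @param rule an [AssemblyRule-class].
#' @return A [FibreModelSpec-class].
#' @examples
#' fibreModelSpec(subunitSpec("FOUR_FOUR"), nSubunits = 2)
#' @export
fibreModelSpec <- function(subunit, nSubunits, lateralCopies = 1L,
                           rule = assemblyRule()) {
  new("FibreModelSpec", subunit = subunit, nSubunits = as.integer(nSubunits),
      lateralCopies = as.integer(lateralCopies), rule = rule)
}

#' Construct a unit cell
#'
#' @param a,b,c axes in Angstrom.
#' @param alpha,beta,gamma angles in degrees.
#' @param lattice label, e.g. a space-group string.
#' @return A [UnitCell-class].
#' @examples
#' unitCell(42.67, 59.68, 156.49)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                     lattice = "") {
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma, lattice = lattice)
}

#' Construct a SAXS curve
#'
#' @param q momentum transfer in inverse Angstrom.
#' @param I intensities.
#' @param sigma optional per-point uncertainties.
#' @return A [SAXSCurve-class].
#' @examples
#' saxsCurve(q = seq(0.01, 0.3, by = 0.01), I = exp(-seq(0.01, 0.3, by = 0.01)))
#' @export
saxsCurve <- function(q, I, sigma = numeric()) {
  new("SAXSCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

#' Construct a micrograph
#'
#' @param pixels numeric intensity matrix (rows = y, columns = x).
#' @param pixelSize nm per pixel.
#' @param polarity `"DARK_RIDGES"` (default, stain-excluding fibres appear
#'   dark) or `"BRIGHT_RIDGES"`.
#' @return A [Micrograph-class].
#' @examples
#' micrograph(matrix(0, 16, 16), pixelSize = 0.5)
#' @export
micrograph <- function(pixels, pixelSize,
                       polarity = c("DARK_RIDGES", "BRIGHT_RIDGES")) {
  new("Micrograph", pixels = as.matrix(pixels), pixelSize = pixelSize,
      polarity = match.arg(polarity))
}

#' Construct a SAXS noise model
#'
#' @param relativeSd noise sd as a fraction of I(q).
#' @param floorSd additive noise floor (intensity units).
#' @param seed integer RNG seed.
#' @return A [NoiseModel-class].
#' @examples
#' noiseModel(relativeSd = 0.02, seed = 7)
#' @export
noiseModel <- function(relativeSd = 0.02, floorSd = 1e-6, seed = 1L) {
  new("NoiseModel", relativeSd = relativeSd, floorSd = floorSd,
      seed = as.integer(seed))
}

# -- show methods -------------------------------------------------------------

setMethod("show", "SubunitSpec", function(object) {
  cat(sprintf("SubunitSpec %s: core %g nm, extended %g nm, %g x %g nm cross-section (%d:%d)\n",
              object@kind, object@coreLength, object@extendedLength,
              object@width, object@thickness,
              object@chainStoichiometry[1L], object@chainStoichiometry[2L]))
})

setMethod("show", "AssemblyRule", function(object) {
  cat(sprintf("AssemblyRule: %g nm initial + %g nm increments; lateral %g nm; lattice %g A\n",
              object@initialLength, object@increment, object@lateralSpacing,
              object@latticeTranslation))
})

setMethod("show", "WidthTaxonomy", function(object) {
  cat("WidthTaxonomy:\n")
  print(as.data.frame(object))
})

#' @export
#' @method as.data.frame WidthTaxonomy
as.data.frame.WidthTaxonomy <- function(x, ...) {
  data.frame(label = x@label, nominal = x@nominal, lower = x@lower,
             upper = x@upper, stringsAsFactors = FALSE)
}

setMethod("show", "MassModel", function(object) {
  cat(sprintf("MassModel: %g nm square cross-section, %g%% solvent, %g g/cm^3\n",
              object@crossSectionSide, 100 * object@solventFraction,
              object@proteinDensity))
})

setMethod("show", "BeadModel", function(object) {
  cat(sprintf("BeadModel '%s': %d beads, Dmax %.2f nm\n", object@label,
              nrow(object@coords), modelDmax(object)))
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell %s: a=%g b=%g c=%g A, alpha=%g beta=%g gamma=%g deg\n",
              object@lattice, object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "SAXSCurve", function(object) {
  cat(sprintf("SAXSCurve: %d points, q %.4g-%.4g A^-1%s\n", length(object@q),
              min(object@q), max(object@q),
              if (length(object@sigma)) ", with sigma" else ""))
})

setMethod("show", "GuinierFit", function(object) {
  cat(sprintf("GuinierFit: Rg = %.3f nm (I0 = %.4g, %d pts, max qRg = %.2f, r2 = %.4f)\n",
              object@Rg, object@I0, object@nPoints, object@maxQRg, object@r2))
})

setMethod("show", "CrossSectionFit", function(object) {
  cat(sprintf("CrossSectionFit: Rc = %.3f nm (%d pts, max qRc = %.2f, r2 = %.4f)\n",
              object@Rc, object@nPoints, object@maxQRc, object@r2))
})

setMethod("show", "PofR", function(object) {
  cat(sprintf("PofR: Dmax = %.2f nm, Rg = %.3f nm (%d grid points)\n",
              object@Dmax, object@RgFromPr, length(object@r)))
})

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px at %g nm/px (%s)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              object@polarity))
})

setMethod("show", "FibreTrace", function(object) {
  cat(sprintf("FibreTrace %d: %d points, length %.1f nm, mean width %.2f nm\n",
              object@id, nrow(object@centerline), object@length,
              object@meanWidth))
})

setMethod("show", "HeptadAssignment", function(object) {
  cat(sprintf("HeptadAssignment (offset %d):\n", object@registerOffset))
  print(data.frame(residue = object@residue, letter = object@letter,
                   core = object@core))
})

# -- accessors ---------------------------------------------------------------

#' Accessors for curve and model slots
#'
#' Small read-only accessors for the central data classes.
#'
#' @param object a package object.
#' @return The requested component.
#' @name accessors
#' @examples
#' qValues(saxsCurve(q = c(0.01, 0.02), I = c(2, 1)))
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setMethod("qValues", "SAXSCurve", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "SAXSCurve", function(object) object@I)

#' @rdname accessors
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setMethod("sigmas", "SAXSCurve", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("beadCoords", function(object) standardGeneric("beadCoords"))
#' @rdname accessors
#' @export
setMethod("beadCoords", "BeadModel", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("beadRadii", function(object) standardGeneric("beadRadii"))
#' @rdname accessors
#' @export
setMethod("beadRadii", "BeadModel", function(object) object@radius)

#' @rdname accessors
#' @export
setGeneric("beadWeights", function(object) standardGeneric("beadWeights"))
#' @rdname accessors
#' @export
setMethod("beadWeights", "BeadModel", function(object) object@weight)

#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(object) standardGeneric("pixelMatrix"))
#' @rdname accessors
#' @export
setMethod("pixelMatrix", "Micrograph", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(object) object@pixelSize)
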