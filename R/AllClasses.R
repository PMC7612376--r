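#' @import methods
#' @importFrom stats approx dist lm coef rnorm runif sd
NULL

# Unified atomic mass constant in grams per dalton (CODATA).
.GRAMS_PER_DALTON <- 1.66053906660e-24

#' Calibrated dimensions of a 2:2 or 4:4 coiled-coil building block
#'
#' A `SubunitSpec` holds the rod geometry of one SYCE2-TEX12 building block:
#' the 2:2 hetero-tetramer (2 nm wide) or the laterally tessellated 4:4
#' hetero-octamer (4 nm wide). Both are 14 nm long in their structured core
#' and extend to 19 nm when the C-terminal S2C/Ctip helices are included.
#'
#' @slot kind either `"TWO_TWO"` or `"FOUR_FOUR"`.
#' @slot coreLength,extendedLength rod length in nm without/with C-terminal
#'   helical extensions.
#' @slot width,thickness cross-sectional dimensions in nm.
#' @slot chainStoichiometry integer vector of length 2: copies of SYCE2 and
#'   TEX12 in the complex.
#' @seealso [subunitSpec()], [buildSubunitBeads()]
#' @export
setClass("SubunitSpec",
  representation(kind = "character", coreLength = "numeric",
                 extendedLength = "numeric", width = "numeric",
                 thickness = "numeric", chainStoichiometry = "integer"))

setValidity("SubunitSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("TWO_TWO", "FOUR_FOUR"))
    msg <- c(msg, "kind must be 'TWO_TWO' or 'FOUR_FOUR'")
  if (object@coreLength > object@extendedLength)
    msg <- c(msg, "coreLength must not exceed extendedLength")
  if (object@width <= 0 || object@thickness <= 0)
    msg <- c(msg, "width and thickness must be positive")
  if (length(object@chainStoichiometry) != 2L ||
      any(object@chainStoichiometry < 0L))
    msg <- c(msg, "chainStoichiometry must be two non-negative integers")
  if (length(msg)) msg else TRUE
})

#' End-to-end and lateral assembly constants of the fibre lattice
#'
#' Fibres grow end-to-end from a 20-nm initial subunit in 15-nm increments
#' (the 156 Angstrom crystallographic translation along the fibre axis), and
#' associate laterally as 5-nm repeating units. 10-nm fibres and bundles of
#' up to 40 nm complete the hierarchy.
#'
#' @slot initialLength nm contributed by the first subunit (default 20).
#' @slot increment nm added per further subunit (default 15).
#' @slot latticeTranslation crystallographic long-axis translation in
#'   Angstrom (default 156).
#' @slot lateralSpacing lateral repeat in nm (default 5).
#' @slot tenNmFibreNominal nominal width of the laterally-associated fibre
#'   class in nm (default 10).
#' @slot bundleMax maximum bundled-fibre width in nm (default 40).
#' @seealso [assemblyRule()], [predictFibreLength()]
#' @export
setClass("AssemblyRule",
  representation(initialLength = "numeric", increment = "numeric",
                 latticeTranslation = "numeric", lateralSpacing = "numeric",
                 tenNmFibreNominal = "numeric", bundleMax = "numeric"))

setValidity("AssemblyRule", function(object) {
  msg <- character()
  if (object@increment <= 0) msg <- c(msg, "increment must be positive")
  if (object@increment > object@initialLength)
    msg <- c(msg, "increment must not exceed initialLength")
  if (abs(object@latticeTranslation / 10 - object@increment) >= 1)
    msg <- c(msg, "latticeTranslation (A) and increment (nm) must agree to within 1 nm")
  if (object@lateralSpacing <= 0) msg <- c(msg, "lateralSpacing must be positive")
  if (length(msg)) msg else TRUE
})

#' Width classes of the fibre hierarchy
#'
#' Ordered, non-overlapping width intervals assigning a measured fibre width
#' to one of the hierarchy's classes (2:2 fibre, 4:4 fibre, 10-nm fibre,
#' bundled fibre).
#'
#' @slot label class labels, ascending by width.
#' @slot nominal nominal class widths in nm.
#' @slot lower,upper class interval bounds in nm; intervals are
#'   left-closed, right-open.
#' @seealso [widthTaxonomy()], [classifyFibreWidth()]
#' @export
setClass("WidthTaxonomy",
  representation(label = "character", nominal = "numeric",
                 lower = "numeric", upper = "numeric"))

setValidity("WidthTaxonomy", function(object) {
  n <- length(object@label)
  if (length(object@nominal) != n || length(object@lower) != n ||
      length(object@upper) != n)
    return("label, nominal, lower and upper must have equal length")
  if (any(object@upper <= object@lower))
    return("each upper bound must exceed its lower bound")
  if (is.unsorted(object@nominal, strictly = TRUE))
    return("nominal widths must be strictly ascending")
  if (n > 1L && any(object@lower[-1L] < object@upper[-n]))
    return("class intervals must not overlap")
  TRUE
})

#' Mass-per-length model of the synaptonemal complex
#'
#' Treats the SC as a solvated protein prism of square cross-section to turn
#' its overall dimensions into a molecular weight per micrometre of length.
#'
#' @slot crossSectionSide side of the square cross-section in nm (default 100).
#' @slot solventFraction volume fraction of solvent, in \[0, 1\].
#' @slot proteinDensity protein density in g/cm^3 (default 1.33).
#' @seealso [massModel()], [scMassPerMicron()]
#' @export
setClass("MassModel",
  representation(crossSectionSide = "numeric", solventFraction = "numeric",
                 proteinDensity = "numeric"))

setValidity("MassModel", function(object) {
  msg <- character()
  if (object@crossSectionSide <= 0) msg <- c(msg, "crossSectionSide must be positive")
  if (object@solventFraction < 0 || object@solventFraction > 1)
    msg <- c(msg, "solventFraction must lie in [0, 1]")
  if (object@proteinDensity <= 0) msg <- c(msg, "proteinDensity must be positive")
  if (length(msg)) msg else TRUE
})

#' Heptad register assignment of coiled-coil residues
#'
#' Maps 1-based residue indices to heptad position letters a-g under a fixed
#' register offset; positions a and d form the hydrophobic core.
#'
#' @slot registerOffset integer in 0-6.
#' @slot residue integer residue indices.
#' @slot letter heptad position letter per residue.
#' @slot core logical, `TRUE` iff the letter is a or d.
#' @seealso [heptadRegister()], [classifyInterfaceResidues()]
#' @export
setClass("HeptadAssignment",
  representation(registerOffset = "integer", residue = "integer",
                 letter = "character", core = "logical"))

setValidity("HeptadAssignment", function(object) {
  n <- length(object@residue)
  if (length(object@letter) != n || length(object@core) != n)
    return("residue, letter and core must have equal length")
  if (n == 0L) return("assignment must contain at least one residue")
  if (object@registerOffset < 0L || object@registerOffset > 6L)
    return("registerOffset must lie in 0-6")
  if (!all(object@letter %in% letters[1:7]))
    return("letters must be among a-g")
  cong <- (object@residue + object@registerOffset) %% 7L
  if (any(tapply(object@letter, cong, function(x) length(unique(x))) != 1L))
    return("indices congruent mod 7 must share a letter")
  TRUE
})

#' Coarse-grained bead model of an assembly state
#'
#' A set of spherical beads (coordinates in nm, per-bead radius and
#' scattering weight) standing in for a fibre or building block in forward
#' scattering and maximum-dimension calculations.
#'
#' @slot coords n x 3 numeric matrix of bead centres (nm), columns x, y, z;
#'   the fibre axis is +z.
#' @slot radius bead radii in nm.
#' @slot weight dimensionless scattering weights.
#' @slot label free-text model label.
#' @seealso [beadModel()], [buildFibreBeads()], [debyeIntensity()]
#' @export
setClass("BeadModel",
  representation(coords = "matrix", radius = "numeric",
                 weight = "numeric", label = "character"))

setValidity("BeadModel", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("a BeadModel needs at least one bead")
  if (ncol(object@coords) != 3L) return("coords must have three columns")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@radius) != n || length(object@weight) != n)
    return("radius and weight must match the number of beads")
  if (any(object@radius <= 0)) return("all radii must be positive")
  if (any(object@weight <= 0)) return("all weights must be positive")
  TRUE
})

#' Specification of a modelled fibre
#'
#' @slot subunit a [SubunitSpec-class].
#' @slot nSubunits number of end-to-end subunits (>= 1).
#' @slot lateralCopies laterally associated protofibre copies (1 for plain
#'   2-nm/4-nm fibres).
#' @slot rule an [AssemblyRule-class].
#' @seealso [fibreModelSpec()], [buildFibreBeads()]
#' @export
setClass("FibreModelSpec",
  representation(subunit = "SubunitSpec", nSubunits = "integer",
                 lateralCopies = "integer", rule = "AssemblyRule"))

setValidity("FibreModelSpec", function(object) {
  msg <- character()
  if (object@nSubunits < 1L) msg <- c(msg, "nSubunits must be >= 1")
  if (object@lateralCopies < 1L) msg <- c(msg, "lateralCopies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Crystallographic unit cell
#'
#' @slot a,b,c axis lengths in Angstrom.
#' @slot alpha,beta,gamma angles in degrees.
#' @slot lattice free-text lattice label.
#' @seealso [unitCell()], [dSpacing()]
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 lattice = "character"))

setValidity("UnitCell", function(object) {
  ax <- c(object@a, object@b, object@c)
  an <- c(object@alpha, object@beta, object@gamma)
  if (any(ax <= 0)) return("axes must be positive")
  if (any(an <= 0) || any(an >= 180)) return("angles must lie in (0, 180)")
  TRUE
})

#' One-dimensional small-angle scattering curve
#'
#' @slot q momentum transfer in inverse Angstrom, strictly increasing.
#' @slot I intensities in arbitrary units.
#' @slot sigma per-point uncertainties (same units as `I`); `numeric(0)`
#'   for model curves without errors.
#' @seealso [saxsCurve()], [guinierFit()], [readSAXSDat()]
#' @export
setClass("SAXSCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric"))

setValidity("SAXSCurve", function(object) {
  if (length(object@q) != length(object@I))
    return("q and I must have equal length")
  if (length(object@q) && any(object@q < 0)) return("q must be non-negative")
  if (length(object@q) > 1L && is.unsorted(object@q, strictly = TRUE))
    return("q must be strictly increasing")
  if (length(object@sigma) &&
      (length(object@sigma) != length(object@q) || any(object@sigma <= 0)))
    return("sigma must be empty, or positive and of the same length as q")
  TRUE
})

#' Guinier fit of a scattering curve
#'
#' @slot Rg radius of gyration in nm.
#' @slot I0 forward-scattering intercept.
#' @slot qWindow fitted q window, inverse Angstrom.
#' @slot maxQRg largest q*Rg in the window (dimensionless).
#' @slot r2 coefficient of determination of the linear fit.
#' @slot nPoints number of fitted points.
#' @seealso [guinierFit()]
#' @export
setClass("GuinierFit",
  representation(Rg = "numeric", I0 = "numeric", qWindow = "numeric",
                 maxQRg = "numeric", r2 = "numeric", nPoints = "integer"))

#' Cross-sectional Guinier fit of a rod-like particle
#'
#' @slot Rc cross-sectional radius of gyration in nm.
#' @slot qWindow fitted q window, inverse Angstrom.
#' @slot maxQRc largest q*Rc in the window.
#' @slot r2 coefficient of determination.
#' @slot nPoints number of fitted points.
#' @seealso [crossSectionFit()]
#' @export
setClass("CrossSectionFit",
  representation(Rc = "numeric", qWindow = "numeric", maxQRc = "numeric",
                 r2 = "numeric", nPoints = "integer"))

#' Pair-distance distribution P(r)
#'
#' @slot r distances in nm on \[0, Dmax\].
#' @slot p distribution values, non-negative, zero at both endpoints,
#'   normalized to unit area.
#' @slot Dmax maximum particle dimension in nm.
#' @slot RgFromPr real-space radius of gyration in nm,
#'   Rg^2 = integral(p r^2)/(2 integral(p)).
#' @seealso [pofrFromBeads()], [iftPofr()]
#' @export
setClass("PofR",
  representation(r = "numeric", p = "numeric", Dmax = "numeric",
                 RgFromPr = "numeric"))

setValidity("PofR", function(object) {
  if (length(object@r) != length(object@p))
    return("r and p must have equal length")
  if (any(object@p < -1e-12)) return("p must be non-negative")
  if (length(object@p) &&
      (abs(object@p[1L]) > 1e-9 || abs(object@p[length(object@p)]) > 1e-9))
    return("p must vanish at r = 0 and r = Dmax")
  TRUE
})

#' Grayscale electron micrograph
#'
#' @slot pixels numeric matrix of intensities, row-major with origin at the
#'   top-left; rows are y (increasing downward), columns are x.
#' @slot pixelSize physical pixel size in nm per pixel.
#' @slot polarity `"DARK_RIDGES"` if fibres are darker than background,
#'   `"BRIGHT_RIDGES"` otherwise.
#' @seealso [micrograph()], [preprocessMicrograph()], [detectRidges()]
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric",
                 polarity = "character"))

setValidity("Micrograph", function(object) {
  if (!is.numeric(object@pixels) || !all(is.finite(object@pixels)))
    return("pixels must be finite numeric")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (!object@polarity %in% c("DARK_RIDGES", "BRIGHT_RIDGES"))
    return("polarity must be 'DARK_RIDGES' or 'BRIGHT_RIDGES'")
  TRUE
})

#' A detected curvilinear fibre trace
#'
#' @slot id integer trace identifier.
#' @slot centerline m x 2 matrix of sub-pixel (x, y) centreline points, px.
#' @slot width per-point width in px (`NA` where no valid edge pair).
#' @slot length arc length in nm.
#' @slot meanWidth mean of valid per-point widths in nm.
#' @seealso [detectRidges()], [measureFibres()]
#' @export
setClass("FibreTrace",
  representation(id = "integer", centerline = "matrix", width = "numeric",
                 length = "numeric", meanWidth = "numeric"))

setValidity("FibreTrace", function(object) {
  if (nrow(object@centerline) < 2L)
    return("a trace needs at least two centreline points")
  if (ncol(object@centerline) != 2L)
    return("centerline must have two columns (x, y)")
  if (length(object@width) != nrow(object@centerline))
    return("width must match the number of centreline points")
  if (any(!is.na(object@width) & object@width <= 0))
    return("widths must be positive where defined")
  TRUE
})

#' Gaussian noise model for simulated SAXS curves
#'
#' @slot relativeSd noise standard deviation as a fraction of I(q)
#'   (default 0.02).
#' @slot floorSd additive noise floor in intensity units.
#' @slot seed integer RNG seed.
#' @seealso [noiseModel()], [simulateSAXS()]
#' @export
setClass("NoiseModel",
  representation(relativeSd = "numeric", floorSd = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (object@relativeSd < 0) return("relativeSd must be >= 0")
  if (object@floorSd <= 0) return("floorSd must be positive")
  TRUE
})
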