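#' Predicted length of an end-to-end fibre of n subunits
#'
#' Fibre length follows an arithmetic rule: the first subunit contributes its
#' full 20 nm, and every further subunit adds one 15-nm lattice repeat (the
#' 5-nm difference is the overlap consumed by the end-to-end C-terminal
#' bundle junction).
#'
#' @param n positive integer subunit count (vectorised).
#' @param rule an [AssemblyRule-class].
#' @return Fibre length(s) in nm.
#' @examples
#' predictFibreLength(1:4)  # 20 35 50 65
#' @export
predictFibreLength <- function(n, rule = assemblyRule()) {
  if (length(n) == 0L || any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("n must consist of positive integers")
  rule@initialLength + rule@increment * (n - 1)
}

#' Enumerate the allowed discrete fibre lengths
#'
#' @param rule an [AssemblyRule-class].
#' @param nMax largest subunit count to enumerate.
#' @return Strictly increasing numeric vector of `nMax` lengths in nm.
#' @examples
#' enumerateAllowedLengths(nMax = 4)
#' @export
enumerateAllowedLengths <- function(rule = assemblyRule(), nMax) {
  if (length(nMax) != 1L || !is.finite(nMax) || nMax < 1 || nMax != round(nMax))
    stop("nMax must be a positive integer")
  predictFibreLength(seq_len(nMax), rule)
}

#' Classify a fibre width into the hierarchy's width classes
#'
#' @param width fibre width(s) in nm, positive.
#' @param taxonomy a [WidthTaxonomy-class].
#' @return Character vector of class labels; `"UNASSIGNED"` where the width
#'   falls in no class interval.
#' @examples
#' classifyFibreWidth(c(2.3, 9.6, 100))
#' @export
classifyFibreWidth <- function(width, taxonomy = widthTaxonomy()) {
  if (any(!is.finite(width)) || any(width <= 0))
    stop("width must be positive and finite")
  vapply(width, function(w) {
    hit <- which(w >= taxonomy@lower & w < taxonomy@upper)
    if (length(hit) == 1L) taxonomy@label[hit] else "UNASSIGNED"
  }, character(1L))
}

#' Dry protein mass of the SC per micrometre of length
#'
#' Mass of a `side x side x 1000 nm` volume of protein at the model density,
#' discounted by the solvent fraction and converted to daltons via the
#' unified atomic mass constant.
#'
#' @param model a [MassModel-class].
#' @return Mass per micrometre in GDa.
#' @examples
#' scMassPerMicron(massModel(solventFraction = 0.8))  # ~1.6 GDa/um
#' @export
scMassPerMicron <- function(model = massModel()) {
  stopifnot(is(model, "MassModel"))
  volume_nm3 <- model@crossSectionSide^2 * 1000
  mass_g <- volume_nm3 * 1e-21 * model@proteinDensity *
    (1 - model@solventFraction)
  mass_g / .GRAMS_PER_DALTON / 1e9
}

#' Total SC mass for a given length
#'
#' @param model a [MassModel-class].
#' @param lengthUm SC length in micrometres, positive.
#' @return Total mass in GDa.
#' @examples
#' scTotalMass(massModel(solventFraction = 0.2), 24)  # ~154 GDa
#' @export
scTotalMass <- function(model = massModel(), lengthUm) {
  if (any(!is.finite(lengthUm)) || any(lengthUm <= 0))
    stop("lengthUm must be positive")
  scMassPerMicron(model) * lengthUm
}

.heptadCoreCount <- function(indices, offset) {
  sum(((indices + offset) %% 7L) %in% c(0L, 3L))
}

#' Assign heptad register letters to residue indices
#'
#' Letters a-g are assigned as `(index + offset) mod 7`, with positions a and
#' d flagged as hydrophobic core. When `offset` is missing, the register is
#' chosen to place as many of the supplied indices as possible on core
#' positions (ties broken towards the smallest offset). Only the a/d-core
#' property is register-convention dependent; congruence classes are not.
#'
#' @param residueIndices non-empty vector of 1-based residue indices.
#' @param offset optional register offset in 0-6.
#' @return A [HeptadAssignment-class].
#' @examples
#' heptadRegister(c(110, 114, 117, 121))  # the Ctip LFIL core residues
#' @export
heptadRegister <- function(residueIndices, offset = NULL) {
  if (length(residueIndices) == 0L)
    stop("residueIndices must be non-empty")
  idx <- as.integer(residueIndices)
  if (is.null(offset)) {
    hits <- vapply(0:6, function(o) .heptadCoreCount(idx, o), integer(1L))
    offset <- which.max(hits) - 1L
  } else {
    offset <- as.integer(offset)
    if (offset < 0L || offset > 6L) stop("offset must lie in 0-6")
  }
  pos <- (idx + offset) %% 7L
  new("HeptadAssignment", registerOffset = offset, residue = idx,
      letter = letters[pos + 1L], core = pos %in% c(0L, 3L))
}

#' Look up heptad position and core flag for interface residues
#'
#' @param assignment a [HeptadAssignment-class].
#' @param indices residue indices, all present in the assignment.
#' @return A data.frame with columns `residue`, `letter`, `core`.
#' @examples
#' reg <- heptadRegister(c(110, 114, 117, 121))
#' classifyInterfaceResidues(reg, c(110, 121))
#' @export
classifyInterfaceResidues <- function(assignment, indices) {
  stopifnot(is(assignment, "HeptadAssignment"))
  pos <- match(as.integer(indices), assignment@residue)
  if (anyNA(pos))
    stop("residue index not present in assignment: ",
         paste(indices[is.na(pos)], collapse = ", "))
  data.frame(residue = assignment@residue[pos],
             letter = assignment@letter[pos],
             core = assignment@core[pos])
}
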