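# Direct-space metric tensor of a unit cell (Angstrom^2).
.metricTensor <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
  cg <- cos(cell@gamma * d2r)
  with(list(a = cell@a, b = cell@b, c = cell@c), {
    matrix(c(a * a,      a * b * cg, a * c * cb,
             a * b * cg, b * b,      b * c * ca,
             a * c * cb, b * c * ca, c * c), 3L, 3L)
  })
}

#' Lattice-plane d-spacing for Miller indices (h, k, l)
#'
#' Uses the general triclinic reciprocal-metric formula
#' `d = 1 / sqrt(h' G^-1 h)` with `G` the direct metric tensor, so
#' orthorhombic and monoclinic cells are handled as special cases without a
#' shortcut.
#'
#' @param cell a [UnitCell-class].
#' @param h,k,l integer Miller indices, not all zero.
#' @return d-spacing in Angstrom.
#' @examples
#' dSpacing(unitCell(42.67, 59.68, 156.49), 0, 0, 1)  # 156.49
#' @export
dSpacing <- function(cell, h, k, l) {
  stopifnot(is(cell, "UnitCell"))
  if (h == 0 && k == 0 && l == 0)
    stop("Miller indices must not all be zero")
  hkl <- c(h, k, l)
  1 / sqrt(drop(crossprod(hkl, solve(.metricTensor(cell), hkl))))
}

#' Axial period of the coiled-coil repeat projected by supercoiling
#'
#' The k-m-e-f family's ~5.1 Angstrom meridional reflection arises from the
#' alpha-helical rise per residue (pitch ~5.4 Angstrom) foreshortened by the
#' supercoil tilt: `pitch * cos(tilt)`.
#'
#' @param helixPitch axial rise repeat of the untilted helix in Angstrom.
#' @param tilt supercoil tilt angle in degrees, in \[0, 90).
#' @return Projected meridional spacing in Angstrom.
#' @examples
#' kmefMeridional(5.4, 19.1)  # ~5.1
#' @export
kmefMeridional <- function(helixPitch, tilt) {
  if (helixPitch <= 0) stop("helixPitch must be positive")
  if (tilt < 0 || tilt >= 90) stop("tilt must lie in [0, 90)")
  helixPitch * cos(tilt * pi / 180)
}

#' Longitudinal and lateral repeats implied by a fibrous crystal lattice
#'
#' @param cell a [UnitCell-class].
#' @param longAxis which cell axis runs along the fibre: "a", "b" or "c".
#' @return A list with `longitudinal` (nm) and `lateral` (nm, the two
#'   remaining axes).
#' @examples
#' latticeRepeats(unitCell(42.67, 59.68, 156.49), "c")
#' @export
latticeRepeats <- function(cell, longAxis = c("c", "a", "b")) {
  stopifnot(is(cell, "UnitCell"))
  longAxis <- match.arg(longAxis)
  ax <- c(a = cell@a, b = cell@b, c = cell@c) / 10
  list(longitudinal = unname(ax[longAxis]),
       lateral = unname(ax[setdiff(names(ax), longAxis)]))
}
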