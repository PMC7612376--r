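# Regular grid of bead centres filling extent L at spacing 2*r, centred on 0.
.gridCentres <- function(L, r) {
  m <- max(1L, round(L / (2 * r)))
  if (m == 1L) return(0)
  seq(-(m - 1L) * r, (m - 1L) * r, length.out = m)
}

#' Build a bead model of a single building block
#'
#' Fills a rectangular-cross-section rod (length x width x thickness) with
#' beads on a regular grid of spacing twice the bead radius, with equal
#' scattering weights. The bounding extent along each axis matches the rod
#' dimension to within one grid step.
#'
#' @param spec a [SubunitSpec-class].
#' @param beadRadius bead radius in nm; must not exceed half the rod width
#'   or thickness. Default 0.25 nm.
#' @param useExtended use the extended (19-nm) rather than core (14-nm)
#'   length.
#' @return A [BeadModel-class] with the fibre axis along +z.
#' @examples
#' buildSubunitBeads(subunitSpec("TWO_TWO"), useExtended = TRUE)
#' @export
buildSubunitBeads <- function(spec, beadRadius = 0.25, useExtended = FALSE) {
  stopifnot(is(spec, "SubunitSpec"))
  if (beadRadius <= 0 || beadRadius > min(spec@width, spec@thickness) / 2)
    stop("beadRadius must be positive and at most half the cross-section")
  L <- if (useExtended) spec@extendedLength else spec@coreLength
  g <- expand.grid(x = .gridCentres(spec@width, beadRadius),
                   y = .gridCentres(spec@thickness, beadRadius),
                   z = .gridCentres(L, beadRadius))
  beadModel(as.matrix(g), radius = beadRadius, weight = 1,
            label = sprintf("%s %s rod", spec@kind,
                            if (useExtended) "extended" else "core"))
}

#' Build a bead model of an end-to-end (and laterally associated) fibre
#'
#' Places `nSubunits` copies of a rod of the rule's initial length (20 nm by
#' default) at axial offsets of one increment (15 nm), so the total axial
#' extent equals [predictFibreLength()]. Grid sites duplicated by the 5-nm
#' end-to-end overlap are merged, not double-weighted. `lateralCopies`
#' replicas are offset by the lateral spacing perpendicular to the axis.
#'
#' @param spec a [FibreModelSpec-class].
#' @param beadRadius bead radius in nm (default 0.25).
#' @return A [BeadModel-class].
#' @examples
#' fib <- buildFibreBeads(fibreModelSpec(subunitSpec("FOUR_FOUR"), 2))
#' modelDmax(fib)  # ~35 nm
#' @export
buildFibreBeads <- function(spec, beadRadius = 0.25) {
  stopifnot(is(spec, "FibreModelSpec"))
  su <- spec@subunit
  rule <- spec@rule
  if (beadRadius <= 0 || beadRadius > min(su@width, su@thickness) / 2)
    stop("beadRadius must be positive and at most half the cross-section")
  zs <- .gridCentres(rule@initialLength, beadRadius)
  base <- as.matrix(expand.grid(x = .gridCentres(su@width, beadRadius),
                                y = .gridCentres(su@thickness, beadRadius),
                                z = zs))
  parts <- lapply(seq_len(spec@nSubunits) - 1L, function(k) {
    m <- base
    m[, 3L] <- m[, 3L] + k * rule@increment
    m
  })
  coords <- do.call(rbind, parts)
  # merge grid sites duplicated by the end-to-end overlap
  key <- paste(round(coords[, 1L], 6L), round(coords[, 2L], 6L),
               round(coords[, 3L], 6L))
  coords <- coords[!duplicated(key), , drop = FALSE]
  if (spec@lateralCopies > 1L) {
    lat <- lapply(seq_len(spec@lateralCopies) - 1L, function(j) {
      m <- coords
      m[, 1L] <- m[, 1L] + j * rule@lateralSpacing
      m
    })
    coords <- do.call(rbind, lat)
  }
  beadModel(coords, radius = beadRadius, weight = 1,
            label = sprintf("%s fibre n=%d lat=%d", su@kind, spec@nSubunits,
                            spec@lateralCopies))
}

#' Maximum dimension of a bead model
#'
#' The largest pairwise centre-to-centre distance plus two maximal bead
#' radii; a single bead reports its diameter.
#'
#' @param model a [BeadModel-class].
#' @return Dmax in nm.
#' @examples
#' modelDmax(beadModel(rbind(c(0, 0, 0), c(0, 0, 10)), radius = 0.5))  # 11
#' @export
modelDmax <- function(model) {
  stopifnot(is(model, "BeadModel"))
  if (nrow(model@coords) == 1L) return(2 * model@radius[1L])
  # the extremes of the centre cloud lie on its convex hull corners; use the
  # full pairwise maximum (fast enough at the bead counts used here)
  max(dist(model@coords)) + 2 * max(model@radius)
}

#' Write a bead model as dummy-atom PDB records
#'
#' Coordinates are converted from nm to Angstrom. The bead scattering weight
#' is stored in the occupancy field and the bead radius (in Angstrom) in the
#' B-factor field, so [readBeadsPDB()] round-trips the model to the format's
#' fixed-column precision.
#'
#' @param model a [BeadModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeBeadsPDB(beadModel(rbind(c(0, 0, 0), c(0, 0, 10))), f)
#' @export
writeBeadsPDB <- function(model, path) {
  stopifnot(is(model, "BeadModel"))
  xyz <- as.vector(t(model@coords * 10))
  n <- nrow(model@coords)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(n), resid = rep("BEA", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = model@weight, b = model@radius * 10)
  invisible(path)
}

#' Read a bead model written by [writeBeadsPDB()]
#'
#' @param path PDB file path.
#' @param label label for the returned model.
#' @return A [BeadModel-class] (coordinates in nm).
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeBeadsPDB(beadModel(rbind(c(0, 0, 0), c(0, 0, 10))), f)
#' readBeadsPDB(f)
#' @export
readBeadsPDB <- function(path, label = "beads") {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  beadModel(cbind(at$x, at$y, at$z) / 10, radius = at$b / 10,
            weight = at$o, label = label)
}
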