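# Bilinear interpolation of matrix field at sub-pixel (x, y) positions,
# with coordinates clamped to the image.
.bilinear <- function(field, x, y) {
  nr <- nrow(field); nc <- ncol(field)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  dx <- x - x0; dy <- y - y0
  field[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    field[cbind(y0, x0 + 1L)] * dx * (1 - dy) +
    field[cbind(y0 + 1L, x0)] * (1 - dx) * dy +
    field[cbind(y0 + 1L, x0 + 1L)] * dx * dy
}

# Scale-space derivative fields of a micrograph: Gaussian smoothing at sigma
# followed by central differences. Returns a list of matrices.
.derivativeFields <- function(A, sigma) {
  nr <- nrow(A); nc <- ncol(A)
  maxRadius <- 2 * floor((min(nr, nc) - 1) / 2) + 1
  radius <- min(2 * ceiling(3 * sigma) + 1, maxRadius)
  S <- EBImage::gblur(A, sigma = sigma, radius = radius,
                      boundary = "replicate")
  shift <- function(M, dy, dx) {
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    M[ri, ci, drop = FALSE]
  }
  rx <- (shift(S, 0, 1) - shift(S, 0, -1)) / 2
  ry <- (shift(S, 1, 0) - shift(S, -1, 0)) / 2
  rxx <- shift(S, 0, 1) - 2 * S + shift(S, 0, -1)
  ryy <- shift(S, 1, 0) - 2 * S + shift(S, -1, 0)
  rxy <- (shift(S, 1, 1) + shift(S, -1, -1) -
          shift(S, 1, -1) - shift(S, -1, 1)) / 4
  list(S = S, rx = rx, ry = ry, rxx = rxx, ryy = ryy, rxy = rxy)
}

# Per-point width: distance between the gradient-magnitude maxima on the
# two sides of the centreline along the local normal (NA when either side
# has no interior maximum).
.pointWidth <- function(gmag, px, py, nx, ny, maxU) {
  us <- seq(0.5, maxU, by = 0.25)
  sideEdge <- function(sgn) {
    g <- .bilinear(gmag, px + sgn * us * nx, py + sgn * us * ny)
    i <- which.max(g)
    if (i == length(g)) return(NA_real_)   # no interior maximum on this side
    if (i > 1L) {
      denom <- g[i - 1L] - 2 * g[i] + g[i + 1L]
      off <- if (denom < 0) 0.5 * (g[i - 1L] - g[i + 1L]) / denom else 0
      us[i] + off * 0.25
    } else us[i]
  }
  up <- sideEdge(1); um <- sideEdge(-1)
  if (is.na(up) || is.na(um)) NA_real_ else up + um
}

#' Steger-style ridge detection of curvilinear fibres
#'
#' Detects line points where the principal eigenvalue of the scale-space
#' Hessian (at scale `sigma`) indicates a ridge of the micrograph's
#' polarity, localizes them to sub-pixel accuracy along the principal
#' eigenvector, links them into traces by orientation continuity with
#' hysteresis thresholding (`highThresh` to seed, `lowThresh` to extend),
#' and discards traces shorter than `minLength`. The per-point width is the
#' distance between the two gradient-magnitude maxima found along the local
#' normal.
#'
#' For a fibre of expected width w px the recommended scale is
#' `sigma = w / (2 * sqrt(3))`. Thresholds apply to the ridge strength
#' `-lambda1` (second-derivative units of the input intensity scale); the
#' defaults suit [preprocessMicrograph()] output (unit-variance images).
#'
#' @param image a [Micrograph-class] (typically preprocessed).
#' @param sigma detection scale in px.
#' @param highThresh,lowThresh hysteresis thresholds on ridge strength;
#'   when `NULL` they are set adaptively to
#'   `max(6 * mad(strength), 0.02 * max(strength))` and a third of that,
#'   which suits both noisy and noise-free images.
#' @param minLength minimum trace arc length in px.
#' @param widthSearch half-width of the edge search along the normal in px
#'   (default `2.5 * sigma + 2`).
#' @param widthSigma scale (px) of the gradient field used for the edge
#'   search (default 1). Widths are deliberately measured at a finer scale
#'   than detection: gradient maxima of a profile smoothed at the
#'   detection scale are displaced outwards by a large fraction of that
#'   scale for thin fibres, whereas at unit scale the residual broadening
#'   is a few percent.
#' @return List of [FibreTrace-class] objects, ids in decreasing seed
#'   strength order.
#' @examples
#' sim <- simulateMicrograph(micrographRecipe(sizePx = 256,
#'                                            counts = c("4:4-fibre" = 2)))
#' pre <- preprocessMicrograph(sim$image)
#' length(detectRidges(pre, sigma = 2.3))
#' @export
detectRidges <- function(image, sigma, highThresh = NULL, lowThresh = NULL,
                         minLength = 20, widthSearch = NULL,
                         widthSigma = 1) {
  stopifnot(is(image, "Micrograph"))
  nr <- nrow(image@pixels); nc <- ncol(image@pixels)
  if (sigma <= 0) stop("sigma must be positive")
  if (6 * sigma >= min(nr, nc)) stop("sigma too large for image")
  if (is.null(widthSearch)) widthSearch <- 2.5 * sigma + 2
  A <- image@pixels
  if (image@polarity == "DARK_RIDGES") A <- -A

  der <- .derivativeFields(A, sigma)
  tr <- der$rxx + der$ryy
  disc <- sqrt((der$rxx - der$ryy)^2 + 4 * der$rxy^2)
  lambda1 <- (tr - disc) / 2           # most negative across a bright ridge
  lambda2 <- (tr + disc) / 2
  strength <- -lambda1
  if (is.null(highThresh))
    highThresh <- max(6 * stats::mad(strength), 0.02 * max(strength))
  if (is.null(lowThresh)) lowThresh <- highThresh / 3
  if (highThresh < lowThresh || lowThresh < 0)
    stop("need highThresh >= lowThresh >= 0")
  # eigenvector of lambda1 = the ridge normal
  e1 <- der$rxy
  e2 <- lambda1 - der$rxx
  alt <- abs(der$rxy) < 1e-12
  e1[alt] <- ifelse(der$rxx[alt] <= der$ryy[alt], 1, 0)
  e2[alt] <- ifelse(der$rxx[alt] <= der$ryy[alt], 0, 1)
  nrm <- sqrt(e1^2 + e2^2)
  nxm <- e1 / nrm; nym <- e2 / nrm

  # sub-pixel offset along the normal; a line point has its extremum within
  # the pixel
  num <- der$rx * nxm + der$ry * nym
  den <- der$rxx * nxm^2 + 2 * der$rxy * nxm * nym + der$ryy * nym^2
  t <- ifelse(abs(den) > 1e-12, -num / den, Inf)
  isLine <- strength > lowThresh & abs(t * nxm) <= 0.5 & abs(t * nym) <= 0.5
  border <- ceiling(2 * sigma)
  isLine[c(seq_len(border), nr - seq_len(border) + 1L), ] <- FALSE
  isLine[, c(seq_len(border), nc - seq_len(border) + 1L)] <- FALSE
  if (!any(isLine)) return(list())

  lin <- which(isLine, arr.ind = TRUE)
  idxMap <- matrix(0L, nr, nc)
  idxMap[lin] <- seq_len(nrow(lin))
  nxv <- nxm[lin]; nyv <- nym[lin]
  # blobness: ratio of the two principal curvatures; ~0 along a clean line,
  # rising towards 1 at line ends where the end cap responds in both
  # directions. Used to localize the physical fibre ends, past which the
  # smoothed ridge response alone stays high.
  blob <- (lambda2 / lambda1)[lin]
  py <- lin[, 1L] + t[lin] * nyv
  px <- lin[, 2L] + t[lin] * nxv
  s <- strength[lin]
  # line tangent (perpendicular to the normal), sign-free orientation
  tx <- -nyv; ty <- nxv
  visited <- rep(FALSE, nrow(lin))

  nbOff <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  nbOff <- nbOff[!(nbOff[, 1L] == 0 & nbOff[, 2L] == 0), ]
  nbOff2 <- as.matrix(expand.grid(dy = -3:3, dx = -3:3))
  nbOff2 <- nbOff2[pmax(abs(nbOff2[, 1L]), abs(nbOff2[, 2L])) >= 2L, ]

  walk <- function(start, dirSign) {
    path <- integer()
    cur <- start
    d <- c(tx[cur], ty[cur]) * dirSign
    repeat {
      r0 <- lin[cur, 1L]; c0 <- lin[cur, 2L]
      collect <- function(offsets) {
        cand <- integer(); score <- numeric(); dirs <- list()
        for (k in seq_len(nrow(offsets))) {
          rr <- r0 + offsets[k, 1L]; cc <- c0 + offsets[k, 2L]
          if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
          j <- idxMap[rr, cc]
          if (j == 0L || visited[j]) next
          step <- c(px[j] - px[cur], py[j] - py[cur])
          stepLen <- sqrt(sum(step^2))
          if (stepLen < 1e-9) next
          fwd <- sum(step * d) / stepLen
          if (fwd < 0.3) next
          align <- abs(tx[j] * d[1L] + ty[j] * d[2L])
          if (align < 0.6) next     # orientation break
          cand <- c(cand, j)
          score <- c(score, stepLen + 2 * (1 - align))
          dirs[[length(dirs) + 1L]] <- step / stepLen
        }
        list(cand = cand, score = score, dirs = dirs)
      }
      got <- collect(nbOff)
      # bridge single-pixel dropouts of the line-point criterion
      if (!length(got$cand)) got <- collect(nbOff2)
      cand <- got$cand; score <- got$score; dirs <- got$dirs
      if (!length(cand)) break
      pick <- which.min(score)
      cur <- cand[pick]
      d <- dirs[[pick]]
      visited[cur] <<- TRUE
      path <- c(path, cur)
    }
    path
  }

  seeds <- order(s, decreasing = TRUE)
  seeds <- seeds[s[seeds] >= highThresh]
  paths <- list()
  for (sd0 in seeds) {
    if (visited[sd0]) next
    visited[sd0] <- TRUE
    fwd <- walk(sd0, 1)
    bwd <- walk(sd0, -1)
    ids <- c(rev(bwd), sd0, fwd)
    if (length(ids) >= 2L) paths[[length(paths) + 1L]] <- ids
  }

  # merge fragments across small linking gaps: two trace ends that face
  # each other within mergeGap pixels and continue in a consistent
  # direction belong to one fibre (noise occasionally interrupts the
  # line-point criterion for more than the bridging radius)
  mergeGap <- max(10, 3 * sigma)
  endInfo <- function(ids) {
    n <- length(ids)
    k <- min(8L, n - 1L)
    list(hp = c(px[ids[1L]], py[ids[1L]]),
         ht = { v <- c(px[ids[1L]] - px[ids[1L + k]],
                       py[ids[1L]] - py[ids[1L + k]]); v / sqrt(sum(v^2)) },
         tp = c(px[ids[n]], py[ids[n]]),
         tt = { v <- c(px[ids[n]] - px[ids[n - k]],
                       py[ids[n]] - py[ids[n - k]]); v / sqrt(sum(v^2)) })
  }
  repeat {
    merged <- FALSE
    if (length(paths) < 2L) break
    info <- lapply(paths, endInfo)
    for (a in seq_along(paths)) {
      if (merged) break
      for (b in seq_along(paths)) {
        if (a >= b) next
        ia <- info[[a]]; ib <- info[[b]]
        combos <- list(
          list(end = "tt", oth = "ht", out = function(A, B) c(A, B)),
          list(end = "tt", oth = "tt", out = function(A, B) c(A, rev(B))),
          list(end = "ht", oth = "ht", out = function(A, B) c(rev(A), B)),
          list(end = "ht", oth = "tt", out = function(A, B) c(B, A)))
        for (cm in combos) {
          pA <- if (cm$end == "tt") ia$tp else ia$hp
          tA <- if (cm$end == "tt") ia$tt else ia$ht
          pB <- if (cm$oth == "ht") ib$hp else ib$tp
          tB <- if (cm$oth == "ht") ib$ht else ib$tt
          g <- pB - pA
          gl <- sqrt(sum(g^2))
          if (gl > mergeGap || gl < 1e-9) next
          if (sum(tA * g) / gl < 0.3) next      # A must point towards B
          if (sum(tB * g) / gl > -0.3) next     # B's end must face A
          paths[[a]] <- cm$out(paths[[a]], paths[[b]])
          paths[[b]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  # suppress parallel duplicates: a trace whose points run along a longer
  # trace's centreline is the same ridge picked up from an adjacent pixel
  # band
  if (length(paths) > 1L) {
    ord2 <- order(vapply(paths, length, integer(1L)), decreasing = TRUE)
    keep <- rep(TRUE, length(paths))
    polys <- lapply(paths, function(ids) cbind(px[ids], py[ids]))
    for (iA in seq_along(ord2)) for (iB in seq_along(ord2)) {
      if (iB <= iA) next
      a <- ord2[iA]; b <- ord2[iB]
      if (!keep[a] || !keep[b]) next
      dAB <- .distToPolyline(polys[[b]], polys[[a]])
      if (mean(dAB < 2) > 0.6) keep[b] <- FALSE
    }
    paths <- paths[keep]
  }

  derW <- if (abs(widthSigma - sigma) < 1e-9) der
          else .derivativeFields(A, widthSigma)
  gmag <- sqrt(derW$rx^2 + derW$ry^2)
  traces <- list()
  for (ids in paths) {
    # localize the physical ends: the end cap raises blobness to ~0.5 at
    # the fibre tip, while the linked trace runs on into the smoothed
    # tail. Search the outer 4 sigma of each end for the outermost
    # blobness crossing and cut there; fall back to a half-response trim
    # when no cap signature is found (e.g. at image borders).
    n <- length(ids)
    capWin <- max(2L, ceiling(4 * sigma))
    endCut <- function(idxRange) {
      b <- blob[ids[idxRange]]
      hit <- which(b >= 0.4)
      if (length(hit)) max(hit) else NA_integer_
    }
    headRange <- seq_len(min(capWin, n))
    cutH <- endCut(headRange)
    first <- if (!is.na(cutH)) headRange[cutH] else {
      half <- 0.5 * stats::median(s[ids])
      which(s[ids] >= half)[1L]
    }
    tailRange <- seq(n, max(1L, n - capWin + 1L))
    cutT <- endCut(tailRange)
    last <- if (!is.na(cutT)) tailRange[cutT] else {
      half <- 0.5 * stats::median(s[ids])
      n + 1L - which(rev(s[ids]) >= half)[1L]
    }
    if (is.na(first) || is.na(last) || last - first < 1L) next
    ids <- ids[first:last]
    # saddle filter: a genuine ridge has near-zero curvature along its
    # axis; shoulder artifacts flanking wide-fibre end caps are saddles
    # (strongly positive second derivative along one direction)
    if (stats::median(blob[ids]) < -0.5) next
    pts <- cbind(px[ids], py[ids])
    arc <- .polyLength(pts)
    if (arc < minLength) next
    w <- vapply(ids, function(j)
      .pointWidth(gmag, px[j], py[j], nxv[j], nyv[j], widthSearch),
      numeric(1L))
    mw <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    traces[[length(traces) + 1L]] <-
      new("FibreTrace", id = length(traces) + 1L, centerline = pts,
          width = w, length = arc * image@pixelSize,
          meanWidth = mw * image@pixelSize)
  }
  traces
}
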