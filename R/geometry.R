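# Geometry on the unit episphere (hemisphere z >= 0, apical pole at +z).

#' @keywords internal
.sphPoint <- function(az_deg, pol_deg) {
  az <- az_deg * pi / 180
  pol <- pol_deg * pi / 180
  c(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
}

#' @keywords internal
.projectHemisphere <- function(p, min_z = 0.02) {
  n <- sqrt(sum(p^2))
  if (n < 1e-12) stop("cannot project a zero-length position")
  p <- p / n
  if (p[3] < min_z) {
    p[3] <- min_z
    xy <- sqrt(p[1]^2 + p[2]^2)
    s <- sqrt(1 - min_z^2) / xy
    p[1:2] <- p[1:2] * s
  }
  p
}

#' @keywords internal
.mirrorX <- function(p) {
  if (is.matrix(p)) {
    p[, 1] <- -p[, 1]
  } else {
    p[1] <- -p[1]
  }
  p
}

# Local tangent basis at a point on the sphere: e_phi points along the
# meridian towards the equator (vegetally), e_theta azimuthally
# (counter-clockwise seen from the animal pole).
#' @keywords internal
.tangentBasis <- function(p) {
  n <- p / sqrt(sum(p^2))
  zax <- c(0, 0, 1)
  e_theta <- c(-n[2], n[1], 0)
  nt <- sqrt(sum(e_theta^2))
  if (nt < 1e-9) {           # at the pole: pick a fixed azimuth reference
    e_theta <- c(0, 1, 0)
    e_phi <- c(1, 0, 0)
  } else {
    e_theta <- e_theta / nt
    e_phi <- .cross3(e_theta, n)   # towards the equator
    e_phi <- e_phi / sqrt(sum(e_phi^2))
  }
  list(n = n, e_phi = e_phi, e_theta = e_theta)
}

#' @keywords internal
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
.rotateAbout <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + .cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Place the two daughters of a dividing cell on the episphere
#'
#' Realises the geometric division modes of spiral-cleaving episphere
#' development.  Spiral divisions separate the daughters along the meridian
#' rotated by +/-45 degrees about the surface normal (the sign alternates
#' between successive spiral tiers), plus a constant handedness twist that
#' accumulates the characteristic rotational offset of the spiral pattern.
#' Radial divisions separate daughters along the meridian.  Bilateral
#' divisions separate them along the direction towards the sagittal plane,
#' which is mirror-equivariant: mirror-symmetric mothers produce exactly
#' mirror-symmetric daughter sets.  Budding leaves daughter 1 in place and
#' displaces daughter 2 azimuthally.
#'
#' @param mother position of the mother (3-vector on or near the unit
#'   hemisphere).
#' @param mode one of \code{"spiral_cw"}, \code{"spiral_ccw"},
#'   \code{"bilateral"}, \code{"radial"}, \code{"budding"}.
#' @param separation distance between the daughters (default half of a
#'   nominal inter-cell spacing).
#' @param twist constant spiral handedness bias in degrees added to the
#'   +/-45 degree spiral offset (ignored by other modes).
#' @return a 2 x 3 matrix; row 1 is the more anterior/apical daughter
#'   (index "1"/"a"), row 2 the more posterior one (index "2"/"b").
#' @export
placeDaughters <- function(mother, mode, separation = 0.2, twist = -12) {
  if (sqrt(sum(mother^2)) < 1e-9)
    stop("zero-length mother position")
  b <- .tangentBasis(mother)
  axis <- switch(mode,
    spiral_cw = .rotateAbout(b$e_phi, b$n, (-45 + twist) * pi / 180),
    spiral_ccw = .rotateAbout(b$e_phi, b$n, (45 + twist) * pi / 180),
    radial = b$e_phi,
    bilateral = {
      # towards the sagittal plane x = 0, projected on the tangent plane
      m <- c(-sign(mother[1]), 0, 0)
      m <- m - sum(m * b$n) * b$n
      nm <- sqrt(sum(m^2))
      if (nm < 1e-9) b$e_theta else m / nm
    },
    budding = b$e_theta,
    stop("unknown division mode ", sQuote(mode)))
  if (mode == "budding") {
    d1 <- mother
    d2 <- mother + separation * axis
  } else {
    d1 <- mother - 0.5 * separation * axis
    d2 <- mother + 0.5 * separation * axis
  }
  rbind(.projectHemisphere(d1), .projectHemisphere(d2))
}

#' Rotational symmetry score of a cell arrangement
#'
#' Measures how closely a set of cells approaches n-fold rotational
#' symmetry about the apical (+z) axis: one minus the ratio of the mean
#' nearest-neighbour distance between the point set and its rotation by
#' 2*pi/n to the mean nearest-neighbour spacing of the set, clamped to
#' [0, 1].  A perfectly n-fold symmetric arrangement scores 1.
#'
#' @param tree a [LineageTree-class].
#' @param uids cells to score (must be alive at \code{t}).
#' @param n order of the rotational symmetry (>= 2).
#' @param t developmental time at which positions are taken (hpf).
#' @return a score in [0, 1].
#' @export
rotationalSymmetryScore <- function(tree, uids, n, t) {
  stopifnot(n >= 2)
  if (length(uids) < n)
    stop("need at least n cells to score n-fold symmetry")
  P <- .positionAt(tree, uids, t)
  if (anyNA(P)) stop("cells without recorded positions at t")
  ang <- 2 * pi / n
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  Q <- P %*% t(R)
  d2 <- function(A, B) {
    # pairwise distances, nearest neighbour of each row of A within B
    dd <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(dd, 0))
  }
  drot <- mean(apply(d2(P, Q), 1, min))
  dnn <- d2(P, P)
  diag(dnn) <- Inf
  spacing <- mean(apply(dnn, 1, min))
  max(0, min(1, 1 - drot / spacing))
}
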