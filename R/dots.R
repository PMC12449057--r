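#' Fibonacci-spiral dots on the unit sphere
#'
#' Places \code{n} dots by the golden-angle spiral: heights
#' z_i = 1 - 2(i + 1/2)/n and azimuths phi_i = i * pi(3 - sqrt(5)),
#' i = 0..n-1. The half-offset in z keeps dots off the exact poles. Every
#' dot carries the same area fraction 1/n — the lattice is nearly uniform
#' in spacing and exactly uniform in area, which removes the pole/equator
#' area inhomogeneity of the classical axis-referenced layout. Fully
#' deterministic.
#'
#' @param n number of dots (>= 1).
#' @return a unit-sphere \linkS4class{DotCloud} with method "fibos".
#' @examples
#' fibonacciDots(100)
#' @export
fibonacciDots <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("domain error: n must be a positive integer")
  n <- as.integer(n)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- i * (pi * (3 - sqrt(5)))
  pts <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  new("DotCloud", points = pts, areas = rep(1 / n, n), method = "fibos",
      radius = 1, center = c(0, 0, 0), scaled = FALSE)
}

#' Axis-referenced radial dots on the unit sphere (classical layout)
#'
#' Latitude-band lattice about the z axis: bands are equally spaced in
#' polar angle, each band carries dots equally spaced in azimuth with a
#' count proportional to the band circumference (minimum 1), and each dot's
#' area fraction is the band's exact spherical-zone area divided by the
#' dots in the band. The construction is deterministic and lands within
#' 20% of \code{nTarget} dots, but is anisotropic about the reference
#' axis: dots near the poles carry different areas than equatorial ones
#' and nearest-neighbor spacing is less even than the Fibonacci spiral's.
#'
#' @param nTarget requested dot count (>= 1).
#' @return a unit-sphere \linkS4class{DotCloud} with method "os".
#' @export
radialDots <- function(nTarget) {
  if (!is.numeric(nTarget) || length(nTarget) != 1L || is.na(nTarget) ||
      nTarget < 1)
    stop("domain error: nTarget must be a positive integer")
  nTarget <- as.integer(nTarget)
  # sqrt(n) bands: azimuthal spacing ~ 4/pi x polar spacing, the
  # axis-referenced mismatch characteristic of the classical layout
  nb <- max(1L, as.integer(round(sqrt(nTarget))))
  theta <- (seq_len(nb) - 0.5) * pi / nb              # band centers
  edges <- seq(0, pi, length.out = nb + 1)
  band_area <- (cos(edges[-(nb + 1)]) - cos(edges[-1])) / 2  # fractions
  scale <- nTarget / sum(sin(theta))
  m <- pmax(1L, as.integer(round(scale * sin(theta))))
  pts <- vector("list", nb); areas <- vector("list", nb)
  for (k in seq_len(nb)) {
    phi <- 2 * pi * (seq_len(m[k]) - 1) / m[k]
    st <- sin(theta[k]); ct <- cos(theta[k])
    pts[[k]] <- cbind(x = st * cos(phi), y = st * sin(phi),
                      z = rep(ct, m[k]))
    areas[[k]] <- rep(band_area[k] / m[k], m[k])
  }
  new("DotCloud", points = do.call(rbind, pts),
      areas = unlist(areas), method = "os", radius = 1, center = c(0, 0, 0),
      scaled = FALSE)
}

#' Dots on an atom's van der Waals sphere
#'
#' Generates \code{n = round(density * 4 pi r^2)} dots (at least 1) by the
#' chosen lattice, scales them to radius \code{r} and translates them to
#' the atom center; each dot's area becomes its fraction of the sphere
#' area 4 pi r^2 in Å². The Fibonacci spiral is the default method.
#'
#' @param center atom center, numeric length-3 (Å).
#' @param radius vdW radius (Å); must be set (not NA).
#' @param density surface dot density in dots per Å² (default 5.0, about
#'   180 dots on a carbon atom).
#' @param method "fibos" (default) or "os".
#' @return a scaled \linkS4class{DotCloud}.
#' @export
atomDots <- function(center, radius, density = 5.0,
                     method = c("fibos", "os")) {
  method <- match.arg(method)
  if (is.na(radius))
    stop("state error: atom radius is unset; call assignRadii() first")
  stopifnot(length(center) == 3L, radius > 0, density > 0)
  n <- max(1L, as.integer(round(density * 4 * pi * radius^2)))
  cloud <- if (method == "fibos") fibonacciDots(n) else radialDots(n)
  scaleDots(cloud, center, radius)
}

#' Scale a unit-sphere dot cloud onto an atom sphere
#'
#' @param cloud an unscaled \linkS4class{DotCloud}.
#' @param center target sphere center (Å).
#' @param radius target sphere radius (Å).
#' @return the scaled cloud; areas in Å² summing to 4 pi r^2.
#' @export
scaleDots <- function(cloud, center, radius) {
  stopifnot(is(cloud, "DotCloud"), radius > 0, length(center) == 3L)
  pts <- cloud@points * radius
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  pts[, 3] <- pts[, 3] + center[3]
  new("DotCloud", points = pts,
      areas = cloud@areas * 4 * pi * radius^2 / sum(cloud@areas),
      method = cloud@method, radius = radius, center = as.numeric(center),
      scaled = TRUE)
}
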