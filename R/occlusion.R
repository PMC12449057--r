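#' Build a cell-list neighbor index over a structure
#'
#' Uniform spatial grid with cell edge and guaranteed query radius both
#' equal to \code{2 * max(radius) + dW} — an upper bound on the distance
#' from any atom center to the center of an atom whose vdW surface a
#' surface-dot normal of length <= dW could reach. All radii must be set.
#'
#' @param s a \linkS4class{PDBStructure} with radii assigned.
#' @param dW water-diameter normal cutoff in Å (default 2.8).
#' @return a \linkS4class{NeighborIndex}.
#' @export
buildNeighborIndex <- function(s, dW = 2.8) {
  stopifnot(is(s, "PDBStructure"), dW > 0)
  xyz <- coords(s)
  r <- vdwRadii(s)
  if (nrow(xyz) && anyNA(r))
    stop("state error: structure has unset radii; call assignRadii() first")
  cutoff <- if (nrow(xyz)) 2 * max(r) + dW else dW
  cells <- list()
  if (nrow(xyz)) {
    ic <- floor(xyz / cutoff)
    key <- paste(ic[, 1], ic[, 2], ic[, 3], sep = ",")
    cells <- split(seq_len(nrow(xyz)), key)
  }
  new("NeighborIndex", coords = xyz, radii = as.numeric(r),
      serials = as.integer(atoms(s)$serial), cells = cells,
      cellSize = cutoff, cutoff = cutoff)
}

#' Query atoms within a cutoff of a point
#'
#' Returns the row indices (into the structure's atom table) of all atoms
#' whose center lies within \code{cutoff} of \code{point}, gathered from
#' the grid cells covering the query ball and then distance-filtered, so
#' the result is exactly the all-pairs answer.
#'
#' @param index a \linkS4class{NeighborIndex}.
#' @param point numeric length-3 query position (Å).
#' @param cutoff query radius (Å); defaults to, and must not exceed
#'   usefully, the index's guaranteed cutoff.
#' @param exclude integer atom row indices to drop (e.g. the query atom).
#' @return sorted integer vector of atom row indices.
#' @export
queryNeighbors <- function(index, point, cutoff = index@cutoff,
                           exclude = integer()) {
  stopifnot(is(index, "NeighborIndex"), length(point) == 3L, cutoff > 0)
  if (!nrow(index@coords)) return(integer())
  reach <- as.integer(ceiling(cutoff / index@cellSize))
  ic <- floor(point / index@cellSize)
  span <- -reach:reach
  keys <- as.vector(outer(
    as.vector(outer(ic[1] + span, ic[2] + span, paste, sep = ",")),
    ic[3] + span, paste, sep = ","))
  cand <- unlist(index@cells[keys], use.names = FALSE)
  if (!length(cand)) return(integer())
  d2 <- (index@coords[cand, 1] - point[1])^2 +
        (index@coords[cand, 2] - point[2])^2 +
        (index@coords[cand, 3] - point[3])^2
  hit <- cand[d2 <= cutoff^2]
  sort(setdiff(hit, exclude))
}

#' Remove dots buried inside neighboring atoms
#'
#' Keeps only the dots lying on the exposed part of the atom's vdW
#' surface: a dot is retained iff its distance to every neighbor center is
#' at least that neighbor's radius. Per-dot areas are unchanged. The
#' pre-removal dot indices are returned in the \code{kept} attribute so
#' lattice dots keep a stable identity downstream.
#'
#' @param dots a scaled \linkS4class{DotCloud} on the atom surface.
#' @param neighbors data.frame with columns x, y, z, radius (Å) of the
#'   other atoms (the atom itself excluded).
#' @return the retained-dot \linkS4class{DotCloud}, with attribute
#'   \code{kept} (integer indices into the input cloud).
#' @export
removeBuriedDots <- function(dots, neighbors) {
  stopifnot(is(dots, "DotCloud"))
  keep <- rep(TRUE, nDots(dots))
  P <- dotPoints(dots)
  if (!is.null(neighbors) && nrow(neighbors)) {
    for (j in seq_len(nrow(neighbors))) {
      d2 <- (P[, 1] - neighbors$x[j])^2 + (P[, 2] - neighbors$y[j])^2 +
            (P[, 3] - neighbors$z[j])^2
      keep <- keep & (d2 >= neighbors$radius[j]^2)
      if (!any(keep)) break
    }
  }
  kept <- which(keep)
  out <- new("DotCloud", points = P[kept, , drop = FALSE],
             areas = dotAreas(dots)[kept], method = dots@method,
             radius = dots@radius, center = dots@center, scaled = TRUE)
  attr(out, "kept") <- kept
  out
}

# Vectorized first-intersection ray casting: rays (P, U) against spheres
# (centers, radii). Per sphere, the entry root -b - sqrt(disc) if positive;
# a positive exit root with non-positive entry means the origin is inside
# (length 0). Ties in the minimum go to the first sphere in order.
.castRays <- function(P, U, centers, radii, dW) {
  m <- nrow(P)
  tbest <- rep(Inf, m)
  jbest <- rep(NA_integer_, m)
  for (j in seq_len(nrow(centers))) {
    ocx <- P[, 1] - centers[j, 1]
    ocy <- P[, 2] - centers[j, 2]
    ocz <- P[, 3] - centers[j, 3]
    b <- ocx * U[, 1] + ocy * U[, 2] + ocz * U[, 3]
    cc <- ocx^2 + ocy^2 + ocz^2 - radii[j]^2
    disc <- b^2 - cc
    sq <- sqrt(pmax(disc, 0))
    t1 <- -b - sq
    t2 <- -b + sq
    t <- ifelse(disc < 0, Inf, ifelse(t1 > 0, t1, ifelse(t2 > 0, 0, Inf)))
    upd <- t < tbest
    if (any(upd)) {
      tbest[upd] <- t[upd]
      jbest[upd] <- j
    }
  }
  occ <- tbest <= dW
  list(occluded = occ,
       length = ifelse(occ, tbest, NA_real_),
       which = ifelse(occ, jbest, NA_integer_))
}

#' Trace one outward normal against neighboring spheres
#'
#' Finds the smallest positive ray parameter t with
#' |origin + t * direction - c_j| = r_j over the neighbors. The dot is
#' occluded iff that first intersection lies within the water-diameter
#' cutoff; an origin strictly inside a neighbor sphere is occluded at
#' length 0.
#'
#' @param origin numeric length-3 ray origin (a surface dot, Å).
#' @param direction unit-norm numeric length-3 outward direction.
#' @param neighbors data.frame with columns x, y, z, radius.
#' @param dW water-diameter cutoff (Å).
#' @return list(occluded, length, occluder): length is the normal length
#'   in Å (NA when not occluded); occluder is the row index into
#'   \code{neighbors} of the first surface hit (NA when not occluded).
#' @export
castNormal <- function(origin, direction, neighbors, dW = 2.8) {
  stopifnot(length(origin) == 3L, length(direction) == 3L, dW > 0)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("domain error: direction must be unit-norm")
  if (is.null(neighbors) || !nrow(neighbors))
    return(list(occluded = FALSE, length = NA_real_, occluder = NA_integer_))
  res <- .castRays(matrix(origin, 1), matrix(direction, 1),
                   as.matrix(neighbors[, c("x", "y", "z")]),
                   neighbors$radius, dW)
  list(occluded = res$occluded, length = res$length, occluder = res$which)
}

.emptyRecords <- function() {
  data.frame(atom_serial = integer(), chain = character(),
             resseq = integer(), insert = character(),
             resname = character(), atom_name = character(),
             dot_index = integer(), x = numeric(), y = numeric(),
             z = numeric(), area = numeric(), occluded = logical(),
             length = numeric(), occluder_serial = integer(),
             stringsAsFactors = FALSE)
}

# occlusion records for one atom given its retained surface dots
.occludeOne <- function(arow, irow, dots, index, dW) {
  P <- dotPoints(dots)
  n <- nrow(P)
  kept <- attr(dots, "kept")
  if (is.null(kept)) kept <- seq_len(n)
  base <- data.frame(
    atom_serial = rep(arow$serial, n), chain = rep(arow$chain, n),
    resseq = rep(arow$resseq, n), insert = rep(arow$insert, n),
    resname = rep(arow$resname, n), atom_name = rep(arow$name, n),
    dot_index = kept,
    x = P[, 1], y = P[, 2], z = P[, 3], area = dotAreas(dots),
    occluded = rep(FALSE, n), length = rep(NA_real_, n),
    occluder_serial = rep(NA_integer_, n), stringsAsFactors = FALSE)
  if (!n) return(base)
  ctr <- c(arow$x, arow$y, arow$z)
  U <- cbind(P[, 1] - ctr[1], P[, 2] - ctr[2], P[, 3] - ctr[3]) / dots@radius
  nb <- queryNeighbors(index, ctr, exclude = irow)
  if (length(nb)) {
    res <- .castRays(P, U, index@coords[nb, , drop = FALSE],
                     index@radii[nb], dW)
    base$occluded <- res$occluded
    base$length <- res$length
    base$occluder_serial <- ifelse(res$occluded,
                                   index@serials[nb[res$which]], NA_integer_)
  }
  base
}

#' Occlusion records for one atom's surface dots
#'
#' For each retained dot of \code{atomRow}'s surface, traces the outward
#' radial normal through the neighbor index and reports whether it is
#' occluded, the normal length, and the occluding atom. \code{dots} must
#' already be the exposed-surface cloud (after
#' \code{\link{removeBuriedDots}}); non-occluded dots are reported with
#' \code{occluded = FALSE} and are disregarded downstream.
#'
#' @param s a \linkS4class{PDBStructure} with radii assigned.
#' @param atom integer row index of the atom in \code{atoms(s)}.
#' @param dots the atom's retained \linkS4class{DotCloud}.
#' @param index a \linkS4class{NeighborIndex} over \code{s}.
#' @param dW water-diameter cutoff (Å).
#' @return data.frame of occlusion records (one row per retained dot).
#' @export
occludeAtom <- function(s, atom, dots, index, dW = 2.8) {
  stopifnot(is(s, "PDBStructure"), is(dots, "DotCloud"),
            is(index, "NeighborIndex"))
  .occludeOne(atoms(s)[atom, , drop = FALSE], atom, dots, index, dW)
}

#' Occluded-surface computation for a whole structure
#'
#' The core pipeline: per atom, generate surface dots by the chosen
#' lattice, remove dots buried inside other atoms, then trace each
#' remaining dot's outward normal until it meets a neighboring vdW surface
#' (occluded) or exceeds the water diameter (non-occluded, disregarded).
#' Deterministic: identical inputs give identical records.
#'
#' @param s a \linkS4class{PDBStructure} with radii assigned.
#' @param method dot lattice, "fibos" (default) or "os".
#' @param density surface dot density in dots/Å² (default 5.0).
#' @param dW water-diameter cutoff in Å (default 2.8).
#' @param dotClouds optional list (one scaled \linkS4class{DotCloud} per
#'   atom, pre-removal) overriding internal dot generation — used e.g. to
#'   co-rotate lattices with the structure.
#' @return data.frame with one row per retained dot: atom_serial, chain,
#'   resseq, insert, resname, atom_name, dot_index, x, y, z, area (Å²),
#'   occluded, length (Å, NA when not occluded), occluder_serial.
#' @examples
#' rec <- occludedSurface(makeDimer(1.7, 3.2), density = 2)
#' table(rec$occluded)
#' @export
occludedSurface <- function(s, method = c("fibos", "os"), density = 5.0,
                            dW = 2.8, dotClouds = NULL) {
  method <- match.arg(method)
  stopifnot(is(s, "PDBStructure"), density > 0, dW > 0)
  a <- atoms(s)
  if (!nrow(a)) return(.emptyRecords())
  if (anyNA(a$radius))
    stop("state error: structure has unset radii; call assignRadii() first")
  if (!is.null(dotClouds) && length(dotClouds) != nrow(a))
    stop("dotClouds must supply one cloud per atom")
  index <- buildNeighborIndex(s, dW)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    arow <- a[i, , drop = FALSE]
    cloud <- if (is.null(dotClouds)) {
      atomDots(c(arow$x, arow$y, arow$z), arow$radius, density, method)
    } else dotClouds[[i]]
    nb <- queryNeighbors(index, c(arow$x, arow$y, arow$z), exclude = i)
    nbdf <- data.frame(x = index@coords[nb, 1], y = index@coords[nb, 2],
                       z = index@coords[nb, 3], radius = index@radii[nb])
    retained <- removeBuriedDots(cloud, nbdf)
    out[[i]] <- .occludeOne(arow, i, retained, index, dW)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
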