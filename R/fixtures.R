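# run expr with a local, seeded RNG stream; global .Random.seed untouched
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# one-atom-per-residue sphere cluster as a radii-assigned structure;
# atoms carry legal PDB names (ALA/CA) so the whole stack can run on them
.clusterStructure <- function(xyz, radius, id) {
  n <- nrow(xyz)
  at <- data.frame(
    serial = seq_len(n), name = "CA", elem = "C", resname = "ALA",
    chain = "A", resseq = seq_len(n), insert = "", altloc = "",
    occ = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep(radius, length.out = n), hetero = FALSE,
    stringsAsFactors = FALSE)
  .newStructure(at, id)
}

#' Two-sphere fixture (dimer)
#'
#' Two equal-radius ALA CA pseudo-atoms on the z axis, centers separated
#' by \code{d} Å, radii pre-assigned. At center distance below 2r the
#' spheres overlap and the buried-dot fraction per atom is the
#' spherical-cap fraction (1 - d/(2r))/2; with a surface gap beyond the
#' water diameter no dot is occluded.
#'
#' @param r vdW radius (Å).
#' @param d center separation (Å), > 0.
#' @return a \linkS4class{PDBStructure} of 2 atoms / 2 residues.
#' @export
makeDimer <- function(r = 1.7, d = 3.4) {
  if (!is.numeric(d) || d <= 0) stop("domain error: d must be > 0")
  stopifnot(r > 0)
  .clusterStructure(rbind(c(0, 0, -d / 2), c(0, 0, d / 2)), r,
                    sprintf("dimer_r%.2f_d%.2f", r, d))
}

#' Coordination-shell fixture (buried central atom)
#'
#' One central atom surrounded by \code{nShell} equal atoms whose centers
#' lie along Fibonacci-lattice directions. With \code{contact = TRUE} the
#' shell sits at vdW contact distance 2r, emulating a buried, well-packed
#' core atom; otherwise at \code{spacing} Å (10 Å isolates every atom
#' beyond the water-diameter cutoff).
#'
#' @param r vdW radius (Å).
#' @param nShell number of shell atoms (>= 4).
#' @param contact place the shell at contact distance (default TRUE).
#' @param spacing center distance when \code{contact = FALSE} (Å).
#' @return a \linkS4class{PDBStructure}; residue 1 is the central atom.
#' @export
makeShell <- function(r = 1.7, nShell = 12, contact = TRUE, spacing = 10) {
  stopifnot(r > 0, nShell >= 4)
  d <- if (contact) 2 * r else spacing
  dirs <- dotPoints(fibonacciDots(nShell))
  .clusterStructure(rbind(c(0, 0, 0), dirs * d), r,
                    sprintf("shell_n%d_d%.2f", nShell, d))
}

#' Jittered-lattice cluster fixture (protein-core stand-in)
#'
#' \code{k^3} equal-radius atoms on a cubic lattice with isotropic
#' Gaussian positional jitter, one residue per atom. The defaults
#' (3.1 Å spacing for 1.7 Å radii, 0.25 Å jitter) put most contacts
#' slightly inside vdW overlap, like heavy-atom packing in a protein
#' core, while the jitter breaks the lattice symmetry so per-residue
#' packing varies realistically. Deterministic given the seed.
#'
#' @param k lattice points per edge (k^3 atoms).
#' @param spacing lattice constant (Å).
#' @param jitter coordinate jitter SD (Å).
#' @param r vdW radius (Å).
#' @param seed RNG seed.
#' @return a \linkS4class{PDBStructure}.
#' @export
makeLattice <- function(k = 3, spacing = 3.1, jitter = 0.25, r = 1.7,
                        seed = 99) {
  stopifnot(k >= 1, spacing > 0, jitter >= 0, r > 0)
  g <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1),
                             z = 0:(k - 1))) * spacing
  g <- g + .withSeed(seed, matrix(stats::rnorm(length(g), 0, jitter),
                                  ncol = 3))
  .clusterStructure(g, r, sprintf("lattice_k%d_seed%d", k, seed))
}

#' Random sphere cluster fixture
#'
#' \code{n} equal-radius atoms placed uniformly at random in a cubic box,
#' one residue per atom; deterministic given the seed.
#'
#' @param n number of atoms.
#' @param box cube edge (Å).
#' @param r vdW radius (Å).
#' @param seed RNG seed.
#' @return a \linkS4class{PDBStructure}.
#' @export
makeRandomCluster <- function(n = 20, box = 20, r = 1.7, seed = 1) {
  stopifnot(n >= 1, box > 0, r > 0)
  xyz <- .withSeed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  .clusterStructure(xyz, r, sprintf("cluster_n%d_seed%d", n, seed))
}

#' Perturbed conformer pair (reference vs noisy model)
#'
#' Emulates an experimental structure and a computed model of the same
#' chain: side a is \code{base} unchanged; side b has every coordinate
#' jittered by isotropic Gaussian noise of SD \code{sigma} and, in
#' addition, \code{nOutliers} randomly chosen atoms displaced by
#' \code{outlierShift} Å directed away from the structure centroid — the
#' way a mispacked side chain extends away from its contact cluster.
#' These planted local divergences are what the influence screening
#' should recover. Deterministic given the seed.
#'
#' @param base a \linkS4class{PDBStructure} with radii assigned.
#' @param sigma coordinate noise SD (Å), >= 0.
#' @param nOutliers number of displaced atoms.
#' @param outlierShift displacement magnitude (Å).
#' @param seed RNG seed.
#' @return list(a, b, outliers) where \code{outliers} is a data.frame of
#'   the displaced atoms' residue identities (chain, resseq, insert,
#'   resname).
#' @export
makePerturbedPair <- function(base, sigma = 0.05, nOutliers = 0,
                              outlierShift = 6, seed = 1) {
  stopifnot(is(base, "PDBStructure"), sigma >= 0, nOutliers >= 0)
  a <- atoms(base)
  n <- nrow(a)
  stopifnot(nOutliers <= n)
  res <- .withSeed(seed, {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    xyz <- xyz + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
    idx <- if (nOutliers) sample.int(n, nOutliers) else integer()
    ctr <- colMeans(xyz)
    for (i in idx) {
      u <- xyz[i, ] - ctr
      if (sum(u^2) < 1e-12) u <- stats::rnorm(3)  # atom at the centroid
      xyz[i, ] <- xyz[i, ] + outlierShift * u / sqrt(sum(u^2))
    }
    list(xyz = xyz, idx = idx)
  })
  bat <- a
  bat[, c("x", "y", "z")] <- res$xyz
  list(a = .newStructure(a, paste0(structureId(base), "_ref")),
       b = .newStructure(bat, paste0(structureId(base), "_perturbed")),
       outliers = a[res$idx, c("chain", "resseq", "insert", "resname"),
                    drop = FALSE])
}

#' Brute-force occlusion oracle
#'
#' Reference implementation of the occlusion engine with no spatial index
#' and no per-neighbor vectorization: every dot of every atom is tested,
#' one dot at a time, against all other atoms — first for burial (dot
#' inside a sphere), then for the first positive ray-sphere entry root
#' along the outward normal. Same record contract and tie-breaking (first
#' atom in structure order) as \code{\link{occludedSurface}}; refuses
#' instances above 50 atoms.
#'
#' @inheritParams occludedSurface
#' @return data.frame of occlusion records, identical in layout to
#'   \code{\link{occludedSurface}} output.
#' @export
bruteForceOcclusion <- function(s, method = c("fibos", "os"),
                                density = 5.0, dW = 2.8,
                                dotClouds = NULL) {
  method <- match.arg(method)
  stopifnot(is(s, "PDBStructure"))
  a <- atoms(s)
  if (nrow(a) > 50)
    stop("refusal: brute-force oracle limited to 50 atoms")
  if (!nrow(a)) return(.emptyRecords())
  if (anyNA(a$radius)) stop("state error: unset radii")
  cx <- a$x; cy <- a$y; cz <- a$z; rr <- a$radius
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    cloud <- if (is.null(dotClouds)) {
      atomDots(c(cx[i], cy[i], cz[i]), rr[i], density, method)
    } else dotClouds[[i]]
    P <- dotPoints(cloud); A <- dotAreas(cloud)
    others <- setdiff(seq_len(nrow(a)), i)
    m <- nrow(P)
    retained <- logical(m)
    occl <- logical(m); len <- rep(NA_real_, m)
    who <- rep(NA_integer_, m)
    for (k in seq_len(m)) {
      p <- P[k, ]
      dx <- p[1] - cx[others]; dy <- p[2] - cy[others]
      dz <- p[3] - cz[others]
      d2 <- dx^2 + dy^2 + dz^2
      if (length(others) && any(d2 < rr[others]^2)) next  # buried dot
      retained[k] <- TRUE
      if (!length(others)) next
      u <- (p - c(cx[i], cy[i], cz[i])) / rr[i]
      b <- dx * u[1] + dy * u[2] + dz * u[3]
      cc <- d2 - rr[others]^2
      disc <- b^2 - cc
      sq <- sqrt(pmax(disc, 0))
      t1 <- -b - sq; t2 <- -b + sq
      t <- ifelse(disc < 0, Inf, ifelse(t1 > 0, t1,
                                        ifelse(t2 > 0, 0, Inf)))
      jm <- which.min(t)
      if (t[jm] <= dW) {
        occl[k] <- TRUE; len[k] <- t[jm]
        who[k] <- a$serial[others[jm]]
      }
    }
    keep <- which(retained)
    out[[i]] <- data.frame(
      atom_serial = rep(a$serial[i], length(keep)),
      chain = rep(a$chain[i], length(keep)),
      resseq = rep(a$resseq[i], length(keep)),
      insert = rep(a$insert[i], length(keep)),
      resname = rep(a$resname[i], length(keep)),
      atom_name = rep(a$name[i], length(keep)), dot_index = keep,
      x = P[keep, 1], y = P[keep, 2], z = P[keep, 3], area = A[keep],
      occluded = occl[keep], length = len[keep],
      occluder_serial = who[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(.emptyRecords())
  rownames(res) <- NULL
  res
}
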