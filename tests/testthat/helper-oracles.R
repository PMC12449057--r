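# Independent oracles and small utilities shared across the suite.

# Exhaustive sign-flip Wilcoxon signed-rank oracle: enumerates all 2^n sign
# assignments of the absolute differences and counts rank sums at least /
# at most as extreme as observed. Feasible for n <= 12.
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_le <- mean(Wall <= W + 1e-9)
  p_ge <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# proper rotation matrix from a seeded random QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_structure <- function(s, R, shift = c(0, 0, 0)) {
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  new("PDBStructure", atoms = a, id = paste0(structureId(s), "_rot"))
}

transform_cloud <- function(cloud, R, shift = c(0, 0, 0)) {
  P <- dotPoints(cloud) %*% t(R)
  P[, 1] <- P[, 1] + shift[1]
  P[, 2] <- P[, 2] + shift[2]
  P[, 3] <- P[, 3] + shift[3]
  new("DotCloud", points = P, areas = dotAreas(cloud),
      method = cloud@method, radius = cloud@radius,
      center = as.vector(R %*% cloud@center) + shift, scaled = TRUE)
}

# per-atom scaled dot clouds exactly as the engine generates them
structure_clouds <- function(s, density = 5, method = "fibos") {
  a <- atoms(s)
  lapply(seq_len(nrow(a)), function(i)
    atomDots(c(a$x[i], a$y[i], a$z[i]), a$radius[i], density, method))
}

# nearest-neighbor great-circle spacing CV of a unit-sphere dot cloud
nn_spacing_cv <- function(cloud) {
  P <- dotPoints(cloud)
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  nn <- 2 * asin(pmin(1, apply(D, 1, min) / 2))
  stats::sd(nn) / mean(nn)
}

# minimal fixed-column PDB ATOM/HETATM line
pdb_line <- function(record = "ATOM", serial = 1, name = "CA",
                     altloc = " ", resname = "ALA", chain = "A",
                     resseq = 1, x = 0, y = 0, z = 0, occ = 1,
                     elem = "C") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, formatC(name, width = -4), altloc, resname,
          chain, resseq, x, y, z, occ, 0, elem)
}

write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}
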