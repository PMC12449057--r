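#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "elem", "resname", "chain", "resseq",
                "insert", "altloc", "occ", "x", "y", "z", "radius", "hetero")

#' PDBStructure: an atomic structure read from a PDB file
#'
#' Holds one coordinate set as a data.frame of atom records (one row per
#' atom after alternate-location resolution) together with a source label.
#' Radii are carried per atom and are \code{NA} until assigned with
#' \code{\link{assignRadii}}; no computation that needs radii will accept an
#' unset structure.
#'
#' @slot atoms data.frame with columns serial, name, elem, resname, chain,
#'   resseq, insert, altloc, occ, x, y, z, radius (\code{NA} = unset, Å),
#'   hetero (logical).
#' @slot id character source label (file name or fixture name).
#' @export
setClass("PDBStructure",
         representation(atoms = "data.frame", id = "character"),
         prototype(atoms = data.frame(), id = "unnamed"))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)  # empty structure is valid
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing))
    return(paste("atoms table lacks columns:", paste(missing, collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    return("non-finite atom coordinates")
  r <- a$radius
  if (any(!is.na(r) & r <= 0))
    return("assigned radii must be > 0")
  key <- paste(a$chain, a$resseq, a$insert, a$name)
  if (anyDuplicated(key))
    return("duplicate (chain, resseq, insert, name) after alt-loc resolution")
  TRUE
})

#' RadiiTable: van der Waals radii configuration
#'
#' Maps (residue name, atom name) pairs and fallback element symbols to van
#' der Waals radii in Ångström. Pair entries take precedence over element
#' fallbacks during \code{\link{assignRadii}}.
#'
#' @slot pairs named numeric; names are "RESNAME:ATOMNAME" keys, values Å.
#' @slot elements named numeric; names are element symbols, values Å.
#' @slot source character label for provenance.
#' @export
setClass("RadiiTable",
         representation(pairs = "numeric", elements = "numeric",
                        source = "character"),
         prototype(pairs = numeric(), elements = numeric(), source = "unset"))

setValidity("RadiiTable", function(object) {
  all_r <- c(object@pairs, object@elements)
  if (length(all_r) && (any(all_r <= 0.5) || any(all_r >= 3.0)))
    return("all radii must lie in (0.5, 3.0) Angstrom")
  need <- c("C", "N", "O", "S", "H", "P")
  if (length(object@elements) && !all(need %in% names(object@elements)))
    return(paste("element fallbacks must cover", paste(need, collapse = ", ")))
  TRUE
})

#' DotCloud: area-carrying dots on a sphere
#'
#' A set of surface dots, either on the unit sphere about the origin
#' (unscaled; areas are fractions of the sphere summing to 1) or scaled
#' onto an atom's van der Waals sphere (areas in Å² summing to 4*pi*r^2).
#'
#' @slot points numeric matrix, one row per dot (x, y, z).
#' @slot areas numeric per-dot area weights (fractions before scaling,
#'   Å² after).
#' @slot method "fibos" (golden-angle spiral) or "os" (axis-referenced
#'   latitude bands).
#' @slot radius sphere radius in Å (1 before scaling).
#' @slot center sphere center (origin before scaling).
#' @slot scaled logical; FALSE while on the unit sphere.
#' @export
setClass("DotCloud",
         representation(points = "matrix", areas = "numeric",
                        method = "character", radius = "numeric",
                        center = "numeric", scaled = "logical"),
         prototype(points = matrix(numeric(), ncol = 3), areas = numeric(),
                   method = "fibos", radius = 1, center = c(0, 0, 0),
                   scaled = FALSE))

setValidity("DotCloud", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3L) return("points must be an n x 3 matrix")
  if (length(object@areas) != n) return("areas length must equal dot count")
  if (n && any(object@areas <= 0)) return("all dot areas must be positive")
  if (!object@method %in% c("fibos", "os")) return("method must be fibos or os")
  if (n && !object@scaled) {
    nrm <- sqrt(rowSums(object@points^2))
    if (max(abs(nrm - 1)) > 1e-9) return("unscaled points must be unit-norm")
    if (abs(sum(object@areas) - 1) > 1e-9)
      return("unscaled area fractions must sum to 1")
  }
  TRUE
})

#' NeighborIndex: cell-list spatial index over atom centers
#'
#' Uniform grid with cell edge equal to the query cutoff, so that any
#' fixed-radius query is answered from the 27 cells around the query point.
#' The cutoff is 2*max(radius) + d_w, sufficient for every dot-to-surface
#' occlusion hit.
#'
#' @slot coords numeric matrix of atom centers (Å).
#' @slot radii numeric per-atom vdW radii (Å).
#' @slot serials integer atom serials (row-parallel with coords).
#' @slot cells named list: cell key -> integer atom row indices.
#' @slot cellSize numeric grid edge (Å).
#' @slot cutoff numeric guaranteed query radius (Å).
#' @export
setClass("NeighborIndex",
         representation(coords = "matrix", radii = "numeric",
                        serials = "integer", cells = "list",
                        cellSize = "numeric", cutoff = "numeric"))

#' ComparisonReport: paired packing comparison of two conformers
#'
#' Result of \code{\link{compareStructures}}: residue-paired OSP values,
#' the paired test statistics, and the influence screening.
#'
#' @slot pairs data.frame: chain, resseq, insert, resname, osp_a, osp_b,
#'   diff (osp_b - osp_a), influence, flagged.
#' @slot unmatched data.frame of residues present in only one side.
#' @slot idA,idB character labels of the two structures.
#' @slot meanA,meanB,sdA,sdB numeric residue-OSP summaries per side.
#' @slot sdGap numeric sd_b - sd_a.
#' @slot wilcoxonP numeric two-sided paired Wilcoxon signed-rank p-value.
#' @slot cohensD numeric paired Cohen's d, mean(diff)/sd(diff).
#' @slot side character which dispersion the influence scores attribute
#'   ("gap", "a" or "b").
#' @slot madK numeric MAD multiplier used by the flagging rule.
#' @export
setClass("ComparisonReport",
         representation(pairs = "data.frame", unmatched = "data.frame",
                        idA = "character", idB = "character",
                        meanA = "numeric", meanB = "numeric",
                        sdA = "numeric", sdB = "numeric", sdGap = "numeric",
                        wilcoxonP = "numeric", cohensD = "numeric",
                        side = "character", madK = "numeric"))

setValidity("ComparisonReport", function(object) {
  p <- object@wilcoxonP
  if (length(p) && (p <= 0 || p > 1)) return("wilcoxonP must lie in (0, 1]")
  if (nrow(object@pairs) &&
      !all(c("osp_a", "osp_b", "diff", "influence", "flagged") %in%
           names(object@pairs)))
    return("pairs table lacks required columns")
  TRUE
})
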