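#' Accessors for package classes
#'
#' \code{atoms} returns the atom table of a \linkS4class{PDBStructure};
#' \code{structureId} its source label; \code{nAtoms} the atom count;
#' \code{residues} the derived residue grouping (one row per residue, in
#' file order); \code{coords} the n x 3 coordinate matrix; \code{vdwRadii}
#' the per-atom radii (NA when unset); \code{dotPoints}, \code{dotAreas}
#' and \code{nDots} the components of a \linkS4class{DotCloud};
#' \code{pairedResidues} the paired table of a
#' \linkS4class{ComparisonReport}.
#'
#' @param x the object.
#' @return the accessed component.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("vdwRadii", function(x) standardGeneric("vdwRadii"))

#' @rdname accessors
#' @export
setGeneric("dotPoints", function(x) standardGeneric("dotPoints"))

#' @rdname accessors
#' @export
setGeneric("dotAreas", function(x) standardGeneric("dotAreas"))

#' @rdname accessors
#' @export
setGeneric("nDots", function(x) standardGeneric("nDots"))

#' @rdname accessors
#' @export
setGeneric("pairedResidues", function(x) standardGeneric("pairedResidues"))

#' @rdname accessors
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("structureId", "PDBStructure", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("residues", "PDBStructure", function(x) {
  a <- x@atoms
  if (!nrow(a))
    return(data.frame(chain = character(), resseq = integer(),
                      insert = character(), resname = character(),
                      n_atoms = integer()))
  key <- .residueKey(a)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             insert = a$insert[first], resname = a$resname[first],
             n_atoms = as.integer(table(factor(key, levels = key[first]))),
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("coords", "PDBStructure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z"), drop = FALSE])
  if (!nrow(x@atoms)) m <- matrix(numeric(), ncol = 3,
                                  dimnames = list(NULL, c("x", "y", "z")))
  m
})

#' @rdname accessors
#' @export
setMethod("vdwRadii", "PDBStructure", function(x) x@atoms$radius)

#' @rdname accessors
#' @export
setMethod("dotPoints", "DotCloud", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("dotAreas", "DotCloud", function(x) x@areas)

#' @rdname accessors
#' @export
setMethod("nDots", "DotCloud", function(x) nrow(x@points))

#' @rdname accessors
#' @export
setMethod("pairedResidues", "ComparisonReport", function(x) x@pairs)

# residue identity: insertion code is part of the sequence position
.residueKey <- function(a) paste(a$chain, a$resseq, a$insert, a$resname,
                                 sep = "|")

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  nres <- if (nrow(a)) length(unique(.residueKey(a))) else 0L
  set <- if (nrow(a)) sum(!is.na(a$radius)) else 0L
  cat(sprintf("PDBStructure '%s': %d atoms, %d residues (radii set: %d/%d)\n",
              object@id, nrow(a), nres, set, nrow(a)))
})

setMethod("show", "RadiiTable", function(object) {
  cat(sprintf("RadiiTable '%s': %d (residue, atom) entries, %d element fallbacks\n",
              object@source, length(object@pairs), length(object@elements)))
})

setMethod("show", "DotCloud", function(object) {
  cat(sprintf("DotCloud (%s): %d dots, radius %.3f, total area %.4f\n",
              object@method, nrow(object@points), object@radius,
              sum(object@areas)))
})

setMethod("show", "NeighborIndex", function(object) {
  cat(sprintf("NeighborIndex: %d atoms, %d occupied cells, cutoff %.2f A\n",
              nrow(object@coords), length(object@cells), object@cutoff))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: %s vs %s\n", object@idA, object@idB))
  cat(sprintf("  %d paired residues (%d unmatched)\n", nrow(object@pairs),
              nrow(object@unmatched)))
  cat(sprintf("  mean OSP  a: %.4f  b: %.4f\n", object@meanA, object@meanB))
  cat(sprintf("  sd OSP    a: %.4f  b: %.4f  (gap %+.4f)\n", object@sdA,
              object@sdB, object@sdGap))
  cat(sprintf("  Wilcoxon p = %.4g, Cohen's d = %.3f\n", object@wilcoxonP,
              object@cohensD))
  cat(sprintf("  influential residues (side '%s', k = %.1f): %d\n",
              object@side, object@madK, sum(object@pairs$flagged)))
})
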