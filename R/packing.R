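#' Per-atom packing summary from occlusion records
#'
#' Aggregates one atom's occlusion records into its occluded surface area
#' and occluded surface packing density. With A_d the dot areas and L_d
#' the normal lengths of occluded dots,
#' \deqn{OSP = \frac{\sum_{occ} A_d (1 - L_d / d_W)}{\sum_{all} A_d}}
#' i.e. occluded area weighted by normal shortness, normalized by the
#' atom's total retained (exposed) dot area — 0 for an isolated atom and
#' 1 for a perfectly enclosed atom with zero-length normals.
#' \code{mean_length} is the area-weighted mean normal length over
#' occluded dots (0 when none). An empty record set yields a zero-area
#' summary with OSP 0.
#'
#' @param records occlusion records of a single atom (rows of the
#'   \code{\link{occludedSurface}} output).
#' @param dW water-diameter cutoff used for the records (Å).
#' @return one-row data.frame: exposed_area, occluded_area, mean_length,
#'   osp.
#' @export
atomPacking <- function(records, dW = 2.8) {
  stopifnot(dW > 0)
  if (is.null(records) || !nrow(records))
    return(data.frame(exposed_area = 0, occluded_area = 0,
                      mean_length = 0, osp = 0))
  if (length(unique(records$atom_serial)) > 1L)
    stop("atomPacking expects records from a single atom")
  a <- records$area
  occ <- records$occluded
  exposed <- sum(a)
  occluded <- sum(a[occ])
  if (!any(occ))
    return(data.frame(exposed_area = exposed, occluded_area = 0,
                      mean_length = 0, osp = 0))
  L <- records$length[occ]
  w <- a[occ]
  osp <- sum(w * (1 - L / dW)) / exposed
  data.frame(exposed_area = exposed, occluded_area = occluded,
             mean_length = sum(w * L) / sum(w), osp = osp)
}

#' Per-atom packing table for a structure
#'
#' Applies \code{\link{atomPacking}} to every atom of the structure, in
#' structure order; atoms whose dots were all removed (fully buried
#' surface) get a zero-area row.
#'
#' @param s the \linkS4class{PDBStructure} the records came from.
#' @param records \code{\link{occludedSurface}} output for \code{s}.
#' @param dW water-diameter cutoff (Å).
#' @return data.frame: serial, chain, resseq, insert, resname, atom_name
#'   plus the \code{atomPacking} columns, one row per atom.
#' @export
atomPackingTable <- function(s, records, dW = 2.8) {
  stopifnot(is(s, "PDBStructure"))
  a <- atoms(s)
  grp <- split(records, factor(records$atom_serial, levels = a$serial))
  packs <- do.call(rbind, lapply(grp, atomPacking, dW = dW))
  cbind(data.frame(serial = a$serial, chain = a$chain, resseq = a$resseq,
                   insert = a$insert, resname = a$resname,
                   atom_name = a$name, stringsAsFactors = FALSE),
        packs, row.names = NULL)
}

#' Per-residue packing table
#'
#' Aggregates atom packing into residues, in structure order: occluded
#' area sums over member atoms; the residue OSP is by default the
#' unweighted mean of its atoms' OSP values (every atom counts equally in
#' the residue average), or the exposed-area-weighted mean when
#' \code{areaWeighted}; mean normal length is weighted by the atoms'
#' occluded areas.
#'
#' @param s the \linkS4class{PDBStructure}.
#' @param atomTable output of \code{\link{atomPackingTable}}; must cover
#'   every atom of \code{s}.
#' @param areaWeighted weight atom OSPs by exposed area (default FALSE).
#' @return data.frame: chain, resseq, insert, resname, n_atoms,
#'   occluded_area, mean_length, osp — one row per residue.
#' @export
residueTable <- function(s, atomTable, areaWeighted = FALSE) {
  stopifnot(is(s, "PDBStructure"))
  a <- atoms(s)
  if (!all(a$serial %in% atomTable$serial))
    stop("consistency error: atoms without a packing row")
  atomTable <- atomTable[match(a$serial, atomTable$serial), , drop = FALSE]
  key <- .residueKey(a)
  lev <- unique(key)
  grp <- split(atomTable, factor(key, levels = lev))
  first <- !duplicated(key)
  osp <- vapply(grp, function(g) {
    w <- if (areaWeighted) g$exposed_area else rep(1, nrow(g))
    if (sum(w) == 0) 0 else sum(w * g$osp) / sum(w)
  }, numeric(1))
  mlen <- vapply(grp, function(g) {
    w <- g$occluded_area
    if (sum(w) == 0) 0 else sum(w * g$mean_length) / sum(w)
  }, numeric(1))
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             insert = a$insert[first], resname = a$resname[first],
             n_atoms = vapply(grp, nrow, integer(1)),
             occluded_area = vapply(grp, function(g) sum(g$occluded_area),
                                    numeric(1)),
             mean_length = mlen, osp = unname(osp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Structure-level OSP summary
#'
#' Mean and sample (n-1) standard deviation of the residue OSP values.
#' A single-residue table has no sample SD; it is reported as 0 and the
#' result carries attribute \code{sd_degenerate = TRUE}.
#'
#' @param resTable output of \code{\link{residueTable}}.
#' @param id structure label for the summary row.
#' @return one-row data.frame: id, n_res, mean_osp, sd_osp.
#' @export
structureSummary <- function(resTable, id = "structure") {
  if (is.null(resTable) || !nrow(resTable))
    stop("domain error: empty residue table")
  out <- data.frame(id = id, n_res = nrow(resTable),
                    mean_osp = mean(resTable$osp),
                    sd_osp = if (nrow(resTable) > 1) stats::sd(resTable$osp)
                             else 0,
                    stringsAsFactors = FALSE)
  if (nrow(resTable) == 1L) attr(out, "sd_degenerate") <- TRUE
  out
}

#' One-shot packing analysis of a structure
#'
#' Runs the full pipeline — occlusion, atom packing, residue aggregation,
#' structure summary — and returns all four tables.
#'
#' @inheritParams occludedSurface
#' @param areaWeighted passed to \code{\link{residueTable}}.
#' @return list with elements \code{records}, \code{atoms},
#'   \code{residues}, \code{summary}.
#' @examples
#' pd <- packingDensity(makeShell(1.7, 8), density = 2)
#' pd$summary
#' @export
packingDensity <- function(s, method = c("fibos", "os"), density = 5.0,
                           dW = 2.8, areaWeighted = FALSE,
                           dotClouds = NULL) {
  method <- match.arg(method)
  rec <- occludedSurface(s, method = method, density = density, dW = dW,
                         dotClouds = dotClouds)
  at <- atomPackingTable(s, rec, dW = dW)
  res <- residueTable(s, at, areaWeighted = areaWeighted)
  list(records = rec, atoms = at, residues = res,
       summary = structureSummary(res, id = structureId(s)))
}
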