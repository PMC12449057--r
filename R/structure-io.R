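#' Read a PDB file into a PDBStructure
#'
#' Parses fixed-column ATOM/HETATM records (via \pkg{bio3d}) into a
#' \linkS4class{PDBStructure}. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order). Waters and
#' hetero atoms are dropped unless \code{includeHetero}; hydrogens (and
#' deuteriums) are dropped unless \code{keepHydrogens} — computed models
#' and experimental structures differ in hydrogen content, so packing
#' comparisons default to the common heavy-atom set. Radii are left unset
#' (\code{NA}); call \code{\link{assignRadii}} before any occlusion
#' computation.
#'
#' @param path path to a PDB file.
#' @param includeHetero keep HETATM records and waters (default FALSE).
#' @param keepHydrogens keep H/D atoms (default FALSE).
#' @return a \linkS4class{PDBStructure}.
#' @examples
#' pdb <- writePDB(makeDimer(1.7, 3.4), tempfile(fileext = ".pdb"))
#' readPDB(pdb)
#' @export
readPDB <- function(path, includeHetero = FALSE, keepHydrogens = FALSE) {
  if (!file.exists(path))
    stop("input error: cannot read '", path, "'")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  .checkCoordColumns(lines, which(is_atom))
  if (!any(is_atom))
    return(.newStructure(.emptyAtoms(), basename(path)))

  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) {
    guess <- suppressWarnings(bio3d::atom2ele(a$elety[bad], rescue = TRUE))
    elem[bad] <- guess
  }
  elem <- toupper(trimws(elem))

  at <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    elem = elem,
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resseq = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    occ = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    radius = NA_real_,
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)

  water <- at$resname %in% c("HOH", "WAT", "DOD", "H2O", "SOL")
  if (!includeHetero) at <- at[!at$hetero & !water, , drop = FALSE]
  if (!keepHydrogens) at <- at[!(at$elem %in% c("H", "D")), , drop = FALSE]
  at <- .resolveAltLoc(at)
  rownames(at) <- NULL
  .newStructure(at, basename(path))
}

# coordinate columns 31-54 of every ATOM/HETATM record must be numeric
.checkCoordColumns <- function(lines, idx) {
  for (i in idx) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(flds))
    if (any(is.na(vals)) || nchar(lines[i]) < 54)
      stop("parse error: malformed coordinate columns at line ", i)
  }
  invisible(TRUE)
}

# keep, per (chain, resseq, insert, resname, name), the alt-loc with the
# highest occupancy; ties -> first occurrence in the file
.resolveAltLoc <- function(at) {
  if (!nrow(at)) return(at)
  key <- paste(at$chain, at$resseq, at$insert, at$resname, at$name, sep = "|")
  ord <- order(-at$occ, seq_len(nrow(at)))
  sel <- sort(ord[!duplicated(key[ord])])
  at[sel, , drop = FALSE]
}

.emptyAtoms <- function() {
  data.frame(serial = integer(), name = character(), elem = character(),
             resname = character(), chain = character(), resseq = integer(),
             insert = character(), altloc = character(), occ = numeric(),
             x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), hetero = logical(),
             stringsAsFactors = FALSE)
}

.newStructure <- function(atoms, id) {
  new("PDBStructure", atoms = atoms, id = as.character(id))
}

#' Write a PDBStructure to a PDB file
#'
#' Emits fixed-column ATOM (or HETATM) records; coordinates are written to
#' 3 decimal places, so \code{readPDB(writePDB(s))} reproduces coordinates
#' to PDB precision and atom identities exactly. An empty structure yields
#' a valid file containing only END.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(s, path) {
  stopifnot(is(s, "PDBStructure"))
  a <- atoms(s)
  ok <- tryCatch({
    if (!nrow(a)) {
      writeLines("END", path)
    } else {
      bio3d::write.pdb(
        file = path,
        type = ifelse(a$hetero, "HETATM", "ATOM"),
        xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
        resno = a$resseq, resid = a$resname, eleno = a$serial,
        elety = a$name, chain = ifelse(a$chain == " ", "", a$chain),
        insert = a$insert, o = a$occ, b = rep(0, nrow(a)),
        elesy = a$elem)
    }
    TRUE
  }, error = function(e) {
    stop("I/O error writing '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' van der Waals radii tables
#'
#' \code{readRadiiTable} reads a plain-text two-column configuration
#' (key, radius in Å); keys of the form \code{RES:ATOM} map a residue/atom
#' pair, bare keys are element fallbacks. Lines starting with \code{#} are
#' comments. \code{defaultRadiiTable} loads the bundled Bondi-style table
#' (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å plus halogens and
#' selenium).
#'
#' @param path path to a radii configuration file.
#' @return a \linkS4class{RadiiTable}.
#' @export
readRadiiTable <- function(path) {
  if (!file.exists(path))
    stop("input error: cannot read radii table '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pairs <- numeric(); elements <- numeric()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 2L)
      stop("parse error in radii table: '", ln, "'")
    r <- suppressWarnings(as.numeric(f[2]))
    if (is.na(r)) stop("parse error in radii table: '", ln, "'")
    if (grepl(":", f[1], fixed = TRUE)) pairs[toupper(f[1])] <- r
    else elements[toupper(f[1])] <- r
  }
  new("RadiiTable", pairs = pairs, elements = elements,
      source = basename(path))
}

#' @rdname readRadiiTable
#' @export
defaultRadiiTable <- function() {
  readRadiiTable(system.file("extdata", "vdw_radii.txt", package = "fibos",
                             mustWork = TRUE))
}

#' Assign van der Waals radii to every atom
#'
#' Looks each atom up by (residue name, atom name) in the table's pair
#' entries, falling back to the element entry. Atoms matching neither
#' cause an error naming the offenders; a structure is only usable by the
#' occlusion engine once every atom has a radius.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param table a \linkS4class{RadiiTable}
#'   (default \code{defaultRadiiTable()}).
#' @return the structure with all radii set.
#' @export
assignRadii <- function(s, table = defaultRadiiTable()) {
  stopifnot(is(s, "PDBStructure"), is(table, "RadiiTable"))
  a <- atoms(s)
  if (!nrow(a)) return(s)
  key <- toupper(paste(a$resname, a$name, sep = ":"))
  r <- unname(table@pairs[key])
  miss <- is.na(r)
  r[miss] <- unname(table@elements[toupper(a$elem[miss])])
  if (any(is.na(r))) {
    bad <- which(is.na(r))
    stop("radius assignment error: no entry for atom(s) ",
         paste(sprintf("%s %s/%s%s (element '%s')", a$resname[bad],
                       a$chain[bad], a$resseq[bad], a$name[bad],
                       a$elem[bad]), collapse = "; "))
  }
  a$radius <- r
  .newStructure(a, structureId(s))
}
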