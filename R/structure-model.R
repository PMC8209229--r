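#' Read a protein structure from a PDB file
#'
#' Parses a PDB file into a [RINStructure-class]: standard amino-acid
#' residues of the selected chains only, first model of multi-model files,
#' highest-occupancy conformer for alternate locations (ties broken by
#' altloc letter order). Waters, glycans and other hetero groups are
#' removed and counted. Author residue numbering is kept untouched; for
#' factor VIII structures it equals the legacy mature-protein numbering.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain ids to keep (default all
#'   protein chains).
#' @param domains either \code{"none"} (default) or \code{"fviii"} to label
#'   residues with the canonical FVIII domain architecture via
#'   [fviiiDomain()].
#' @param structureId identifier stored in the object (default: file base
#'   name without extension).
#' @return a [RINStructure-class].
#' @examples
#' spec <- generatorSpec(seed = 1, nResidues = 8)
#' pdb <- tempfile(fileext = ".pdb")
#' generateStructure(spec, path = pdb)
#' s <- readStructure(pdb)
#' nrow(residueTable(s))
#' @export
readStructure <- function(path, chains = NULL, domains = c("none", "fviii"),
                          structureId = NULL) {
  domains <- match.arg(domains)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  nIn <- nrow(a)

  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]

  isWater <- a$resid %in% c("HOH", "WAT", "DOD", "H2O")
  isStd <- a$resid %in% .STANDARD_AA3 & a$type == "ATOM"
  nWater <- length(unique(makeResidueKey(a$chain, a$resno, a$insert)[isWater]))
  dropped <- a[!isStd & !isWater, , drop = FALSE]
  nHet <- length(unique(makeResidueKey(dropped$chain, dropped$resno, dropped$insert)))
  a <- a[isStd, , drop = FALSE]
  if (nrow(a) == 0L) stop("no protein residues in '", path, "'")

  # altloc: highest occupancy wins per (residue, atom name); ties by letter
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  atomId <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  nAltConflicts <- 0L
  if (anyDuplicated(atomId)) {
    ord <- order(atomId, -a$o, a$alt)
    a <- a[ord, , drop = FALSE]
    atomId <- atomId[ord]
    dup <- duplicated(atomId)
    nAltConflicts <- sum(dup)
    a <- a[!dup, , drop = FALSE]
  }

  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("^[0-9]+", "", a$elety[bad]), 1, 1)
  elem <- toupper(trimws(elem))
  isH <- elem %in% c("H", "D")

  base <- toupper(gsub("[0-9]", "", a$elety))
  chainPart <- ifelse(
    a$elety %in% .MAIN_CHAIN_ATOMS |
      (isH & base %in% c("H", "HN", "HA", "HXT")),
    "main_chain", "side_chain"
  )

  atoms <- data.frame(
    chain = a$chain, resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety, element = elem,
    x = a$x, y = a$y, z = a$z,
    altloc = a$alt, occupancy = a$o,
    chainPart = chainPart, isHydrogen = isH,
    stringsAsFactors = FALSE
  )
  atoms$key <- makeResidueKey(atoms$chain, atoms$resno, atoms$icode)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL

  dm <- character(0)
  if (domains == "fviii") {
    keys <- unique(atoms$key)
    resno <- atoms$resno[match(keys, atoms$key)]
    dm <- fviiiDomain(resno)
    names(dm) <- keys
    dm <- dm[!is.na(dm)]
  }

  .logInfo("readStructure: kept %d residues; dropped %d water and %d hetero/non-standard residues (%d altloc conflicts resolved)",
           length(unique(atoms$key)), nWater, nHet, nAltConflicts)

  if (is.null(structureId)) structureId <- sub("\\.[^.]*$", "", basename(path))
  new("RINStructure",
      structureId = structureId, atoms = atoms, domainMap = dm,
      parseLog = list(atomsRead = nIn, watersDropped = nWater,
                      heteroDropped = nHet, altlocConflicts = nAltConflicts))
}

#' Residue-level summary of a structure
#'
#' @param x a [RINStructure-class].
#' @param ... unused.
#' @return data.frame with one row per residue: \code{key}, \code{chain},
#'   \code{resno}, \code{icode}, \code{resid}, \code{domain}.
#' @export
setMethod("residueTable", "RINStructure", function(x, ...) {
  a <- x@atoms
  keys <- unique(a$key)
  i <- match(keys, a$key)
  out <- data.frame(
    key = keys, chain = a$chain[i], resno = a$resno[i], icode = a$icode[i],
    resid = a$resid[i], stringsAsFactors = FALSE
  )
  out$domain <- unname(x@domainMap[out$key])
  out
})

setMethod("show", "RINStructure", function(object) {
  rt <- residueTable(object)
  cat("RINStructure '", object@structureId, "': ",
      nrow(rt), " residues, ", nrow(object@atoms), " atoms, chains ",
      paste(unique(rt$chain), collapse = ","), "\n", sep = "")
  if (length(object@domainMap)) {
    cat("  domains:", paste(names(table(object@domainMap)), collapse = " "), "\n")
  }
})

#' Reference Gly-X-Gly surface areas
#'
#' Loads the table of reference solvent-accessible surface areas of the 20
#' standard amino acids in an extended Gly-X-Gly tripeptide (theoretical
#' maximum-exposure scale), used to normalize per-residue areas into
#' relative exposures. The shipped file can be swapped for an alternative
#' scale (e.g. empirical maxima) with the same two-column CSV layout.
#'
#' @param file CSV with columns \code{resid}, \code{area}; default is the
#'   table shipped with the package.
#' @return named numeric vector (3-letter code to area in square angstrom).
#' @export
referenceAreas <- function(file = system.file("extdata", "gly_x_gly_reference_areas.csv",
                                              package = "fviiiRIN")) {
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  ref <- stats::setNames(tab$area, tab$resid)
  stopifnot(length(ref) == 20L, all(ref > 0), all(names(ref) %in% .STANDARD_AA3))
  ref
}

#' Relative surface exposure
#'
#' Divides each residue's surface area by the reference area of the same
#' residue type, giving a dimensionless burial measure (~0 fully buried,
#' ~1 fully exposed; not clamped, so extended conformations may exceed 1).
#'
#' @param structure a [RINStructure-class] (provides residue types).
#' @param areas named per-residue areas as returned by
#'   [computeSurfaceArea()]; computed on the fly when \code{NULL}.
#' @param ref named reference-area vector from [referenceAreas()].
#' @param ... passed to [computeSurfaceArea()] when \code{areas} is NULL.
#' @return named numeric vector of exposure ratios (one per residue).
#' @export
relativeExposure <- function(structure, areas = NULL, ref = referenceAreas(), ...) {
  stopifnot(is(structure, "RINStructure"))
  if (is.null(areas)) areas <- computeSurfaceArea(structure, ...)
  rt <- residueTable(structure)
  types <- rt$resid[match(names(areas), rt$key)]
  missing <- setdiff(unique(types), names(ref))
  if (length(missing)) {
    stop("no reference area for residue type(s): ", paste(missing, collapse = ", "))
  }
  areas / unname(ref[types])
}

#' Write a per-residue area/exposure CSV
#'
#' @param structure a [RINStructure-class].
#' @param areas named per-residue areas.
#' @param exposure named per-residue relative exposures.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeResidueAreas <- function(structure, areas, exposure, file) {
  rt <- residueTable(structure)
  i <- match(rt$key, names(areas))
  out <- data.frame(
    chain = rt$chain, seq_number = rt$resno, icode = rt$icode,
    restype = rt$resid, area = unname(areas[i]),
    relative_exposure = unname(exposure[match(rt$key, names(exposure))]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
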