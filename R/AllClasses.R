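#' @import methods
NULL

setOldClass("igraph")

#' Protein structure as typed residues and atoms
#'
#' An S4 container for a parsed protein structure: standard amino-acid
#' residues only, with per-atom coordinates (angstrom), main-chain/side-chain
#' classification, and an optional residue-to-domain map. Residues are
#' identified by a key of the form \code{"<chain>:<seq_number>"} (with the
#' insertion code appended when present, e.g. \code{"A:100A"}), where the
#' sequence number is the author numbering of the source file; for factor
#' VIII structures this is the legacy mature-protein numbering.
#'
#' @slot structureId single string identifying the structure (e.g. a PDB id).
#' @slot atoms data.frame with one row per atom: \code{chain}, \code{resno},
#'   \code{icode}, \code{resid} (3-letter type), \code{elety} (atom name),
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{altloc},
#'   \code{occupancy}, \code{chainPart} (\code{"main_chain"} or
#'   \code{"side_chain"}), \code{isHydrogen}, \code{key}.
#' @slot domainMap named character vector mapping residue keys to domain
#'   labels (may be empty).
#' @slot parseLog list of bookkeeping counts recorded while parsing
#'   (dropped waters/hetero/nonstandard residues, altloc conflicts).
#'
#' @seealso [readStructure()], [residueTable()], [computeSurfaceArea()]
#' @export
setClass("RINStructure",
  representation(
    structureId = "character",
    atoms = "data.frame",
    domainMap = "character",
    parseLog = "list"
  ),
  prototype(
    structureId = NA_character_,
    atoms = data.frame(),
    domainMap = character(0),
    parseLog = list()
  )
)

.MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

.CENTRALITY_MEASURES <- c("degree", "betweenness", "closeness",
                          "burt_constraint", "pagerank", "kcore", "authority")

.STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

setValidity("RINStructure", function(object) {
  a <- object@atoms
  need <- c(
    "chain", "resno", "icode", "resid", "elety", "element",
    "x", "y", "z", "altloc", "occupancy", "chainPart", "isHydrogen", "key"
  )
  if (!all(need %in% names(a))) {
    return(paste("atoms missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    return("non-finite atom coordinates")
  }
  if (!all(a$resid %in% .STANDARD_AA3)) {
    return("non-standard residue types present after filtering")
  }
  if (!all(a$chainPart %in% c("main_chain", "side_chain"))) {
    return("chainPart must be main_chain or side_chain")
  }
  # every residue needs at least one main-chain atom
  mc <- tapply(a$chainPart == "main_chain", a$key, any)
  if (!all(mc)) {
    return(paste("residues without main-chain atoms:", paste(names(mc)[!mc][1:min(3, sum(!mc))], collapse = ", ")))
  }
  TRUE
})

#' Residue interaction network
#'
#' An undirected simple graph over residues: one node per residue key, one
#' edge per residue pair in atomic contact. Edges carry the interaction
#' classes observed among qualifying atom pairs (subset of \code{mc_mc},
#' \code{mc_sc}, \code{sc_sc}, joined by \code{"+"}) and the smallest
#' qualifying heavy-atom distance. Edges are unweighted for all centrality
#' computations.
#'
#' @slot graph an [igraph::igraph] with vertex attribute \code{name} (residue
#'   key) and edge attributes \code{interactionClasses}, \code{minDistance}.
#' @slot provenance list recording construction parameters (cutoff,
#'   covalent-exclusion flag, hydrogen policy) and isolated-node bookkeeping.
#'
#' @seealso [detectContacts()], [buildNetwork()], [computeCentralities()]
#' @export
setClass("ResidueNetwork",
  representation(graph = "igraph", provenance = "list"),
  prototype(provenance = list())
)

setValidity("ResidueNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("graph must have no self-loops")
  if (any(igraph::which_multiple(g))) return("graph must be simple (no parallel edges)")
  if (is.null(igraph::V(g)$name)) return("vertices must be named by residue key")
  TRUE
})
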