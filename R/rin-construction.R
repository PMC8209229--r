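#' Detect residue-residue atomic contacts
#'
#' Emits one contact per unordered residue pair having at least one
#' heavy-atom pair closer than \code{cutoff}. Each contact records every
#' interaction class observed among qualifying atom pairs —
#' main-chain/main-chain (\code{mc_mc}), main-chain/side-chain
#' (\code{mc_sc}), side-chain/side-chain (\code{sc_sc}) — and the smallest
#' qualifying distance. Hydrogens never participate (heavy-atom
#' convention). With \code{excludeCovalent} (default), the inter-residue
#' peptide bond C(i)-N(i+1) and disulfide SG-SG pairs closer than 2.5
#' angstrom are not counted as contacts; all other inter-residue atom pairs
#' count.
#'
#' @param x a [RINStructure-class].
#' @param cutoff contact distance cutoff in angstrom (default 5.0).
#' @param excludeCovalent drop peptide-bond and disulfide atom pairs
#'   (default TRUE).
#' @param ... unused.
#' @return data.frame with columns \code{keyA}, \code{keyB} (residue keys,
#'   \code{keyA < keyB}), \code{classes} (interaction classes joined by
#'   \code{"+"}), \code{minDistance}.
#' @export
setMethod("detectContacts", "RINStructure",
  function(x, cutoff = 5.0, excludeCovalent = TRUE, ...) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
      stop("cutoff must be a single positive number")
    }
    a <- x@atoms[!x@atoms$isHydrogen, , drop = FALSE]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    pairs <- .atomPairsWithin(xyz, cutoff)
    if (nrow(pairs) == 0L) {
      return(data.frame(keyA = character(0), keyB = character(0),
                        classes = character(0), minDistance = numeric(0)))
    }
    keyI <- a$key[pairs$i]; keyJ <- a$key[pairs$j]
    keep <- keyI != keyJ
    pairs <- pairs[keep, , drop = FALSE]
    keyI <- keyI[keep]; keyJ <- keyJ[keep]

    if (excludeCovalent && nrow(pairs)) {
      eI <- a$elety[pairs$i]; eJ <- a$elety[pairs$j]
      sameChain <- a$chain[pairs$i] == a$chain[pairs$j]
      dres <- abs(a$resno[pairs$i] - a$resno[pairs$j])
      peptide <- sameChain &
        ((eI == "C" & eJ == "N") | (eI == "N" & eJ == "C")) &
        (dres == 1L | pairs$d < 1.8)
      disulfide <- eI == "SG" & eJ == "SG" & pairs$d < 2.5
      drop <- peptide | disulfide
      pairs <- pairs[!drop, , drop = FALSE]
      keyI <- keyI[!drop]; keyJ <- keyJ[!drop]
    }
    if (nrow(pairs) == 0L) {
      return(data.frame(keyA = character(0), keyB = character(0),
                        classes = character(0), minDistance = numeric(0)))
    }

    partI <- a$chainPart[pairs$i]; partJ <- a$chainPart[pairs$j]
    cls <- ifelse(partI == "main_chain" & partJ == "main_chain", "mc_mc",
           ifelse(partI == "side_chain" & partJ == "side_chain", "sc_sc", "mc_sc"))

    keyA <- pmin(keyI, keyJ); keyB <- pmax(keyI, keyJ)
    pairId <- paste(keyA, keyB, sep = "~")
    classes <- vapply(split(cls, pairId),
                      function(v) paste(sort(unique(v)), collapse = "+"), "")
    minD <- vapply(split(pairs$d, pairId), min, 0)
    ids <- names(classes)
    ab <- do.call(rbind, strsplit(ids, "~", fixed = TRUE))
    out <- data.frame(keyA = ab[, 1], keyB = ab[, 2],
                      classes = unname(classes), minDistance = unname(minD),
                      stringsAsFactors = FALSE)
    out[order(out$keyA, out$keyB), , drop = FALSE]
  })

#' Assemble a residue interaction network from contacts
#'
#' Merges duplicate contacts for the same unordered pair (union of
#' interaction classes, minimum of distances), drops self-pairs with a
#' warning, and keeps contact-free residues as isolated nodes (logged and
#' recorded in provenance) so the node set equals the residue universe.
#'
#' @param contacts data.frame as returned by [detectContacts()] (extra
#'   duplicate rows allowed).
#' @param residues character vector of residue keys forming the node
#'   universe (typically \code{residueTable(s)$key}).
#' @param provenance named list of construction parameters stored in the
#'   object.
#' @return a [ResidueNetwork-class].
#' @export
buildNetwork <- function(contacts, residues, provenance = list()) {
  stopifnot(is.character(residues), length(residues) > 0,
            !anyDuplicated(residues))
  bad <- setdiff(c(contacts$keyA, contacts$keyB), residues)
  if (length(bad)) {
    stop("contacts reference residues outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  self <- contacts$keyA == contacts$keyB
  if (any(self)) {
    warning(sum(self), " self-contact(s) dropped")
    contacts <- contacts[!self, , drop = FALSE]
  }
  if (nrow(contacts)) {
    a <- pmin(contacts$keyA, contacts$keyB)
    b <- pmax(contacts$keyA, contacts$keyB)
    pairId <- paste(a, b, sep = "~")
    cls <- vapply(split(contacts$classes, pairId), function(v) {
      paste(sort(unique(unlist(strsplit(v, "+", fixed = TRUE)))), collapse = "+")
    }, "")
    minD <- vapply(split(contacts$minDistance, pairId), min, 0)
    ab <- do.call(rbind, strsplit(names(cls), "~", fixed = TRUE))
    edges <- data.frame(a = ab[, 1], b = ab[, 2], classes = unname(cls),
                        minDistance = unname(minD), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        classes = character(0), minDistance = numeric(0))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(residues), name = residues)
  if (nrow(edges)) {
    g <- igraph::add_edges(
      g, rbind(match(edges$a, residues), match(edges$b, residues)),
      interactionClasses = edges$classes, minDistance = edges$minDistance
    )
  }
  iso <- residues[igraph::degree(g) == 0]
  if (length(iso)) {
    .logInfo("buildNetwork: %d isolated node(s) retained", length(iso))
  }
  provenance$isolatedNodes <- iso
  new("ResidueNetwork", graph = g, provenance = provenance)
}

#' One-call residue interaction network construction
#'
#' Convenience wrapper: [detectContacts()] followed by [buildNetwork()]
#' over all residues of the structure, with parameters recorded in
#' provenance.
#'
#' @inheritParams detectContacts,RINStructure-method
#' @param structure a [RINStructure-class].
#' @return a [ResidueNetwork-class].
#' @export
buildRIN <- function(structure, cutoff = 5.0, excludeCovalent = TRUE) {
  contacts <- detectContacts(structure, cutoff = cutoff,
                             excludeCovalent = excludeCovalent)
  buildNetwork(contacts, residueTable(structure)$key,
               provenance = list(cutoff = cutoff,
                                 excludeCovalent = excludeCovalent,
                                 includeHydrogens = FALSE,
                                 structureId = structure@structureId))
}

#' @describeIn ResidueNetwork-class the underlying igraph object.
#' @param x a [ResidueNetwork-class].
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "ResidueNetwork"))
  x@graph
}

#' @describeIn ResidueNetwork-class edge list with interaction classes and
#'   minimum distances.
#' @export
edgeTable <- function(x) {
  stopifnot(is(x, "ResidueNetwork"))
  g <- x@graph
  el <- igraph::as_edgelist(g)
  data.frame(
    keyA = el[, 1], keyB = el[, 2],
    classes = if (igraph::ecount(g)) igraph::E(g)$interactionClasses else character(0),
    minDistance = if (igraph::ecount(g)) igraph::E(g)$minDistance else numeric(0),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "ResidueNetwork", function(object) {
  g <- object@graph
  cat("ResidueNetwork: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
      " edges (", sum(igraph::degree(g) == 0), " isolated)\n", sep = "")
  prov <- object@provenance
  if (!is.null(prov$cutoff)) cat("  contact cutoff:", prov$cutoff, "A\n")
})
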