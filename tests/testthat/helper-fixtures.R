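# In-code fixtures: hand-built structures and networks for unit tests.

# minimal RINStructure from a list of residues; each residue is
# list(chain=, resno=, resid=, atoms=list(name = c(x, y, z)))
makeTestStructure <- function(residues, structureId = "test") {
  rows <- list()
  for (r in residues) {
    for (ai in seq_along(r$atoms)) {
      nm <- names(r$atoms)[ai]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = r$chain, resno = r$resno, icode = "",
        resid = r$resid, elety = nm, element = substr(nm, 1, 1),
        x = r$atoms[[ai]][1], y = r$atoms[[ai]][2], z = r$atoms[[ai]][3],
        altloc = "", occupancy = 1,
        chainPart = if (nm %in% c("N", "CA", "C", "O", "OXT")) "main_chain" else "side_chain",
        isHydrogen = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$key <- makeResidueKey(atoms$chain, atoms$resno, atoms$icode)
  new("RINStructure", structureId = structureId, atoms = atoms,
      domainMap = character(0), parseLog = list())
}

# a glycine (backbone only) at an offset
glycineAt <- function(chain, resno, offset = c(0, 0, 0)) {
  list(chain = chain, resno = resno, resid = "GLY",
       atoms = list(N = c(-1.46, 0, 0) + offset, CA = c(0, 0, 0) + offset,
                    C = c(0.55, 1.42, 0) + offset, O = c(1.23, 1.8, 0.95) + offset))
}

# wrap an igraph graph (vertices get names if missing) as a ResidueNetwork
netFromGraph <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name", value = paste0("V", seq_len(igraph::vcount(g))))
  }
  new("ResidueNetwork", graph = g, provenance = list())
}

# seeded Erdos-Renyi network plus its adjacency matrix
seededER <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  list(net = netFromGraph(g),
       A = as.matrix(igraph::as_adjacency_matrix(g)))
}

# rigid-body rotation of all structure coordinates
rotateStructure <- function(s, angles = c(0.3, 1.1, -0.7), shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  R <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE) %*%
       matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
       matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R)
  s@atoms$x <- xyz[, 1] + shift[1]
  s@atoms$y <- xyz[, 2] + shift[2]
  s@atoms$z <- xyz[, 3] + shift[3]
  s
}

# canonical string form of a contact table for set comparisons
contactIds <- function(contacts) {
  sort(paste(contacts$keyA, contacts$keyB, sep = "~"))
}
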