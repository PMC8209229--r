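test_that("synthetic PDB fixtures round-trip through the parser", {
  spec <- generatorSpec(seed = 5, nResidues = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  suppressMessages(generateStructure(spec, path = pdb))
  s <- suppressMessages(readStructure(pdb))
  rt <- residueTable(s)
  expect_equal(nrow(rt), 5)
  # every residue has a CA
  hasCA <- tapply(s@atoms$elety == "CA", s@atoms$key, any)
  expect_true(all(hasCA))
  expect_true(validObject(s))
})

test_that("waters and hetero groups are filtered and counted", {
  spec <- generatorSpec(seed = 5, nResidues = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  suppressMessages(generateStructure(spec, path = pdb))
  lines <- readLines(pdb)
  extra <- c(
    "HETATM 9991  O   HOH A 900      30.000  30.000  30.000  1.00  0.00           O",
    "HETATM 9992  C1  NAG A 901      35.000  35.000  35.000  1.00  0.00           C"
  )
  writeLines(c(lines[-length(lines)], extra, "END"), pdb)
  s <- suppressMessages(readStructure(pdb))
  expect_equal(nrow(residueTable(s)), 5)
  expect_equal(s@parseLog$watersDropped, 1)
  expect_equal(s@parseLog$heteroDropped, 1)
})

test_that("altloc conformers resolve to highest occupancy, ties by letter", {
  hdr <- "ATOM  %5d  %-3s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s"
  lines <- c(
    sprintf(hdr, 1, "N", " ", "ALA", 1, 0, 0, 0, 1.0, 0, "N"),
    sprintf(hdr, 2, "CA", "A", "ALA", 1, 1.46, 0, 0, 0.4, 0, "C"),
    sprintf(hdr, 3, "CA", "B", "ALA", 1, 9.99, 0, 0, 0.6, 0, "C"),
    sprintf(hdr, 4, "C", "A", "ALA", 1, 2.0, 1.4, 0, 0.5, 0, "C"),
    sprintf(hdr, 5, "C", "B", "ALA", 1, 8.88, 1.4, 0, 0.5, 0, "C"),
    sprintf(hdr, 6, "O", " ", "ALA", 1, 2.6, 1.8, 1, 1.0, 0, "O"),
    "END"
  )
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, pdb)
  s <- suppressMessages(readStructure(pdb))
  a <- s@atoms
  expect_equal(nrow(a), 4)
  expect_equal(a$x[a$elety == "CA"], 9.99)  # higher occupancy wins
  expect_equal(a$x[a$elety == "C"], 2.0)    # tie broken by altloc letter
  expect_equal(s@parseLog$altlocConflicts, 2)
})

test_that("unreadable and empty selections produce clear errors", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(suppressMessages(readStructure(bad)))
  spec <- generatorSpec(seed = 5, nResidues = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  suppressMessages(generateStructure(spec, path = pdb))
  expect_error(suppressMessages(readStructure(pdb, chains = "Z")), "no protein residues")
})

test_that("surface areas agree with an independent Shrake-Rupley implementation", {
  spec <- generatorSpec(seed = 1, nResidues = 3, fold = "extended",
                        sequence = c("GLY", "ALA", "GLY"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  s <- suppressMessages(generateStructure(spec, path = pdb))
  areas <- computeSurfaceArea(s)

  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "from Bio.PDB import PDBParser",
    "from Bio.PDB.SASA import ShrakeRupley",
    "import sys",
    "s = PDBParser(QUIET=True).get_structure('x', sys.argv[1])",
    "sr = ShrakeRupley(probe_radius=1.4, n_points=960,",
    "  radii_dict={'C':1.70,'N':1.55,'O':1.52,'S':1.80,'P':1.80,'SE':1.90,'H':1.20})",
    "sr.compute(s, level='R')",
    "for r in s.get_residues():",
    "    print(r.get_id()[1], r.sasa)"
  ), script)
  out <- system2(py, c(script, pdb), stdout = TRUE)
  ref <- read.table(text = out, col.names = c("resno", "area"))
  ours <- areas[makeResidueKey("A", ref$resno)]
  expect_lt(max(abs(ours - ref$area) / ref$area), 0.01)
})

test_that("a residue enclosed by a shell of atoms is buried", {
  shellPts <- fviiiRIN:::.spherePoints(220) * 4.0
  shell <- list(chain = "A", resno = 2, resid = "GLY",
                atoms = c(list(CA = shellPts[1, ]),
                          setNames(lapply(2:220, function(i) shellPts[i, ]),
                                   rep("CB", 219))))
  s <- makeTestStructure(list(glycineAt("A", 1), shell))
  areas <- computeSurfaceArea(s)
  expect_lt(areas[["A:1"]], 1)
})

test_that("identical residues far apart get equal areas; rotation changes nothing", {
  s <- makeTestStructure(list(glycineAt("A", 1), glycineAt("B", 2, offset = c(60, 0, 0))))
  areas <- computeSurfaceArea(s)
  expect_equal(areas[["A:1"]], areas[["B:2"]], tolerance = 1e-12)

  spec <- generatorSpec(seed = 9, nResidues = 12)
  s2 <- suppressMessages(generateStructure(spec))
  # fine quadrature so rotation error reflects the method, not point noise
  a1 <- computeSurfaceArea(s2, spherePoints = 3840L)
  a2 <- computeSurfaceArea(rotateStructure(s2), spherePoints = 3840L)
  expect_lt(max(abs(a2 - a1) / pmax(a1, 1)), 0.01)
  # additivity: residue areas sum to the whole-structure total by construction
  aAtoms <- fviiiRIN:::.shrakeRupley(
    as.matrix(s2@atoms[, c("x", "y", "z")]),
    fviiiRIN:::.vdwRadius(s2@atoms$element), 1.4, 3840L)
  expect_equal(sum(a1), sum(aAtoms), tolerance = 1e-9)
})

test_that("relative exposure is the area over the reference area", {
  s <- makeTestStructure(list(glycineAt("A", 1)))
  ref <- referenceAreas()
  expect_equal(unname(relativeExposure(s, areas = c("A:1" = 0))), 0)
  expect_equal(unname(relativeExposure(s, areas = c("A:1" = ref[["GLY"]]))), 1)
  # scale equivariance
  a <- c("A:1" = 57.3)
  expect_equal(relativeExposure(s, areas = 2 * a),
               2 * relativeExposure(s, areas = a))
  # extended Gly-X-Gly: middle residue near full exposure
  spec <- generatorSpec(seed = 1, nResidues = 3, fold = "extended",
                        sequence = c("GLY", "ALA", "GLY"))
  sg <- suppressMessages(generateStructure(spec))
  rel <- relativeExposure(sg)
  expect_gt(rel[["A:2"]], 0.8)
  expect_lt(rel[["A:2"]], 1.2)
})

test_that("missing reference entries are reported by residue type", {
  s <- makeTestStructure(list(glycineAt("A", 1)))
  ref <- referenceAreas()
  expect_error(relativeExposure(s, areas = c("A:1" = 10), ref = ref[names(ref) != "GLY"]),
               "GLY")
})
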