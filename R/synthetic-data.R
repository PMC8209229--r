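# Deterministic synthetic inputs with known ground truth: toy structures
# (ideal helices, extended chains, two-domain constructs), alanine-mutant
# activity tables with a planted monotone dependence on a centrality, and
# messy clinical tables with planted positional enrichment.

#' Specification for the synthetic generators
#'
#' All generator randomness flows from \code{seed}; the same spec always
#' reproduces identical outputs byte for byte.
#'
#' @param seed integer RNG seed.
#' @param nResidues number of residues (>= 3).
#' @param fold backbone fold: ideal alpha-helix (\code{"helix"}), extended
#'   beta-strand-like chain (\code{"extended"}), or two helices on separate
#'   chains separated by a spatial gap (\code{"two_domain"}).
#' @param activityBeta planted effect size: log-odds of Low activity per
#'   standard deviation of the chosen centrality.
#' @param activityFeature centrality column the activity depends on.
#' @param clinicalEnrichment odds multiplier for reported mutations at
#'   designated harmful positions.
#' @param nClinical number of clinical records to generate (>= 10).
#' @param interdomainGap spatial gap (angstrom) between the two domains of
#'   the \code{two_domain} fold; the default leaves zero inter-domain
#'   contacts at a 5 angstrom cutoff.
#' @param sequence optional vector of 3-letter residue types recycled along
#'   the chain; default draws types deterministically from the seed.
#' @return a validated \code{GeneratorSpec} list.
#' @export
generatorSpec <- function(seed = 1L, nResidues = 30L,
                          fold = c("helix", "extended", "two_domain"),
                          activityBeta = 4, activityFeature = "closeness",
                          clinicalEnrichment = 3, nClinical = 500L,
                          interdomainGap = 40, sequence = NULL) {
  fold <- match.arg(fold)
  if (nResidues < 3) stop("nResidues must be >= 3")
  spec <- list(seed = as.integer(seed), nResidues = as.integer(nResidues),
               fold = fold, activityBeta = activityBeta,
               activityFeature = activityFeature,
               clinicalEnrichment = clinicalEnrichment,
               nClinical = as.integer(nClinical),
               interdomainGap = interdomainGap, sequence = sequence)
  class(spec) <- "GeneratorSpec"
  spec
}

# ideal backbone geometry (angstrom / degrees)
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.8)
.TORSIONS <- list(helix = c(phi = -57, psi = -47),
                  extended = c(phi = -139, psi = 135))

# natural-extension-reference-frame placement of atom D from A-B-C,
# bond length r (C-D), bond angle theta (B-C-D), dihedral chi (A-B-C-D)
.nerf <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * cos(ch) * m + sin(th) * sin(ch) * n)
}

# backbone N/CA/C/O coordinates for an n-residue chain at fixed phi/psi
.buildBackbone <- function(n, phi, psi) {
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND[["N_CA"]], 0, 0)
  ang <- .ANGLE[["N_CA_C"]] * pi / 180
  C[1, ] <- CA[1, ] + .BOND[["CA_C"]] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                      .BOND[["C_N"]], .ANGLE[["CA_C_N"]], psi)
      CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ],
                       .BOND[["N_CA"]], .ANGLE[["C_N_CA"]], 180)
      C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ],
                      .BOND[["CA_C"]], .ANGLE[["N_CA_C"]], phi)
    }
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ],
                    .BOND[["C_O"]], .ANGLE[["CA_C_O"]], psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# pseudo side-chain positions: 2.4 A from CA, outward from the fitted
# chain axis (helix) or away from the backbone within the N-CA-C frame
.sideChainPositions <- function(bb, outwardFromAxis) {
  n <- nrow(bb$CA)
  CB <- matrix(NA_real_, n, 3)
  if (outwardFromAxis && n >= 3) {
    ctr <- colMeans(bb$CA)
    axis <- svd(sweep(bb$CA, 2, ctr))$v[, 1]
    for (i in seq_len(n)) {
      v <- bb$CA[i, ] - ctr
      out <- v - sum(v * axis) * axis
      nrm <- sqrt(sum(out^2))
      if (nrm < 1e-8) out <- c(axis[2], -axis[1], 0) else out <- out / nrm
      CB[i, ] <- bb$CA[i, ] + 2.4 * out
    }
  } else {
    for (i in seq_len(n)) {
      u1 <- bb$N[i, ] - bb$CA[i, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- bb$C[i, ] - bb$CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
      out <- -(u1 + u2); out <- out / sqrt(sum(out^2))
      CB[i, ] <- bb$CA[i, ] + 2.4 * out
    }
  }
  CB
}

.formatPdbAtom <- function(serial, name, resid, chain, resno, xyz, element) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Generate a synthetic protein structure
#'
#' Builds an ideal backbone (alpha-helix or extended chain, standard bond
#' geometry) with one pseudo side-chain atom per non-glycine residue (2.4
#' angstrom from the C-alpha, pointing outward), or two such helices on
#' chains A and B separated by a spatial gap. The structure is returned as
#' a [RINStructure-class] and optionally written as a valid PDB file that
#' [readStructure()] round-trips.
#'
#' @param spec a [generatorSpec()].
#' @param path optional output PDB path.
#' @return a [RINStructure-class] (invisibly carries no ground truth; the
#'   geometry itself is the ground truth).
#' @export
generateStructure <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  n <- spec$nResidues
  set.seed(spec$seed)
  seqTypes <- if (is.null(spec$sequence)) {
    sample(.STANDARD_AA3, n, replace = TRUE)
  } else rep_len(spec$sequence, n)

  if (spec$fold == "two_domain") {
    n1 <- ceiling(n / 2); n2 <- n - n1
    if (n2 < 1) stop("two_domain fold needs at least 4 residues")
    t1 <- .TORSIONS$helix
    bb1 <- .buildBackbone(n1, t1[["phi"]], t1[["psi"]])
    bb2 <- .buildBackbone(n2, t1[["phi"]], t1[["psi"]])
    span <- max(bb1$CA[, 1]) - min(bb1$CA[, 1])
    shift <- c(span + spec$interdomainGap, 0, 0)
    for (nm in names(bb2)) bb2[[nm]] <- sweep(bb2[[nm]], 2, shift, "+")
    parts <- list(list(bb = bb1, chain = "A", resno = seq_len(n1)),
                  list(bb = bb2, chain = "B", resno = n1 + seq_len(n2)))
    outward <- TRUE
  } else {
    tor <- .TORSIONS[[spec$fold]]
    parts <- list(list(bb = .buildBackbone(n, tor[["phi"]], tor[["psi"]]),
                       chain = "A", resno = seq_len(n)))
    outward <- spec$fold == "helix"
  }

  rows <- list(); serial <- 0L
  for (p in parts) {
    CB <- .sideChainPositions(p$bb, outward)
    for (i in seq_along(p$resno)) {
      resno <- p$resno[i]
      resid <- seqTypes[resno]
      atoms <- list(N = p$bb$N[i, ], CA = p$bb$CA[i, ],
                    C = p$bb$C[i, ], O = p$bb$O[i, ])
      if (resid != "GLY") atoms$CB <- CB[i, ]
      for (nm in names(atoms)) {
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          chain = p$chain, resno = resno, icode = "", resid = resid,
          elety = nm, element = substr(nm, 1, 1),
          x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
          altloc = "", occupancy = 1,
          chainPart = if (nm %in% .MAIN_CHAIN_ATOMS) "main_chain" else "side_chain",
          isHydrogen = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$key <- makeResidueKey(atoms$chain, atoms$resno, atoms$icode)
  atoms[, c("x", "y", "z")] <- round(atoms[, c("x", "y", "z")], 3)

  if (!is.null(path)) {
    lines <- character(nrow(atoms))
    for (i in seq_len(nrow(atoms))) {
      lines[i] <- .formatPdbAtom(i, atoms$elety[i], atoms$resid[i],
                                 atoms$chain[i], atoms$resno[i],
                                 c(atoms$x[i], atoms$y[i], atoms$z[i]),
                                 atoms$element[i])
    }
    writeLines(c(sprintf("REMARK   6 SYNTHETIC %s FOLD SEED %d", toupper(spec$fold), spec$seed),
                 lines, "TER", "END"), path)
  }

  new("RINStructure",
      structureId = sprintf("synthetic_%s_%d", spec$fold, spec$seed),
      atoms = atoms, domainMap = character(0),
      parseLog = list(synthetic = TRUE, fold = spec$fold))
}

# inverse-CDF triangular sampler on [a, b] with mode m
.rtriangular <- function(n, a, m, b) {
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Generate alanine-mutant activity labels with planted centrality effect
#'
#' Draws one alanine mutant per network residue whose probability of Low
#' activity is \code{plogis(activityBeta * z)}, with \code{z} the z-scored
#' value of the chosen centrality. Chromogenic and secretion percentages
#' are then drawn from triangular distributions (mode 10 on [0, 50] for
#' Low, mode 90 on [50, 100] for High), so the 50 percent rule is
#' exercised with realistic spread. Per-instance Bayes-optimal
#' probabilities and labels are recorded as ground truth.
#'
#' @param tab centrality table from [computeCentralities()].
#' @param spec a [generatorSpec()].
#' @return data.frame of mutant records: \code{key}, \code{chain},
#'   \code{position}, \code{wt_aa}, \code{mut_aa}, \code{chromogenic_pct},
#'   \code{secretion_pct}, \code{label}, plus ground-truth columns
#'   \code{bayes_p_low}, \code{bayes_label}; attribute
#'   \code{bayes_accuracy} is the Bayes-optimal accuracy of the draw.
#' @export
generateActivityLabels <- function(tab, spec) {
  stopifnot(inherits(spec, "GeneratorSpec"),
            spec$activityFeature %in% names(tab))
  f <- tab[[spec$activityFeature]]
  sdf <- stats::sd(f, na.rm = TRUE)
  if (is.na(sdf) || sdf == 0) {
    stop("zero-variance feature: ", spec$activityFeature)
  }
  z <- (f - mean(f, na.rm = TRUE)) / stats::sd(f, na.rm = TRUE)
  pLow <- stats::plogis(spec$activityBeta * z)
  set.seed(spec$seed + 1L)
  low <- stats::rbinom(length(pLow), 1, pLow) == 1
  chrom <- ifelse(low, .rtriangular(length(low), 0, 10, 50),
                  .rtriangular(length(low), 50, 90, 100))
  lowSec <- stats::rbinom(length(pLow), 1, pLow) == 1
  secr <- ifelse(lowSec, .rtriangular(length(low), 0, 10, 50),
                 .rtriangular(length(low), 50, 90, 100))
  parts <- strsplit(tab$key, ":", fixed = TRUE)
  out <- data.frame(
    key = tab$key,
    chain = vapply(parts, `[`, "", 1L),
    position = as.integer(gsub("[A-Za-z]+$", "", vapply(parts, `[`, "", 2L))),
    wt_aa = NA_character_, mut_aa = "ALA",
    chromogenic_pct = chrom, secretion_pct = secr,
    label = ifelse(chrom > 50, "High", "Low"),
    bayes_p_low = pLow,
    bayes_label = ifelse(pLow > 0.5, "Low", "High"),
    stringsAsFactors = FALSE
  )
  attr(out, "bayes_accuracy") <- mean(pmax(pLow, 1 - pLow))
  out
}

#' Generate a raw clinical mutation table with planted enrichment
#'
#' Positions acquire at least one reported mutation with odds multiplied
#' by \code{clinicalEnrichment} inside the designated harmful set; records
#' are then distributed over the reported positions. A fixed set of messy
#' rows exercising every sanitation rule (range, bound marker, ambiguous
#' severity, stop codon, above-100 value, boundary-spanning range,
#' non-numeric) is planted in known positions and recorded as ground
#' truth.
#'
#' @param positions integer vector of candidate legacy positions.
#' @param spec a [generatorSpec()].
#' @param harmfulPositions subset of \code{positions} where enrichment is
#'   planted.
#' @param baseProb baseline probability that a non-harmful position has a
#'   reported mutation (default 0.35).
#' @return raw clinical data.frame (schema of [sanitizeRecords()]);
#'   attributes \code{reported_positions}, \code{planted_messy} (row ids of
#'   the messy records) carry the ground truth.
#' @export
generateClinicalTable <- function(positions, spec, harmfulPositions,
                                  baseProb = 0.35) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  if (length(positions) == 0) stop("empty position set")
  if (spec$nClinical < 10) stop("nClinical must be >= 10")
  positions <- unique(as.integer(positions))
  harmfulPositions <- intersect(unique(as.integer(harmfulPositions)), positions)

  set.seed(spec$seed + 2L)
  o0 <- baseProb / (1 - baseProb)
  o1 <- o0 * spec$clinicalEnrichment
  pPos <- ifelse(positions %in% harmfulPositions, o1 / (1 + o1), baseProb)
  present <- stats::runif(length(positions)) < pPos
  reported <- positions[present]
  if (length(reported) == 0) reported <- sample(positions, 1)

  n <- spec$nClinical
  recPos <- sample(reported, n, replace = TRUE)
  sev <- sample(c("severe", "moderate", "severe", "mild"), n, replace = TRUE)
  val <- ifelse(sev == "severe", round(stats::runif(n, 0, 0.9), 1),
         ifelse(sev == "moderate", round(stats::runif(n, 1, 5), 1),
                round(stats::runif(n, 5.5, 40), 1)))
  raw <- data.frame(
    mutation_type = "Point", variant_effect = "Missense",
    position_legacy = recPos,
    fviii_c_raw = as.character(val),
    fviii_c_1st = as.character(val), fviii_c_2st = as.character(val),
    severity_reported = sev, protein_change = NA_character_,
    stringsAsFactors = FALSE
  )

  messy <- data.frame(
    mutation_type = "Point", variant_effect = "Missense",
    position_legacy = rep(reported[1], 7),
    fviii_c_raw = c("10 to 24", "< 1", "25", "30", "150", "0 to 2", "NR"),
    fviii_c_1st = NA_character_, fviii_c_2st = NA_character_,
    severity_reported = c("mild", "severe", "mild/moderate", "severe",
                          "mild", "moderate", "mild"),
    protein_change = c(NA, NA, NA, "Arg15*", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  idx <- sort(sample(n + 7L, 7L))
  ord <- integer(n + 7L)
  ord[idx] <- n + seq_len(7L)
  ord[setdiff(seq_len(n + 7L), idx)] <- seq_len(n)
  out <- rbind(raw, messy)[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reported_positions") <- reported
  attr(out, "planted_messy") <- idx
  attr(out, "harmful_positions") <- harmfulPositions
  out
}
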