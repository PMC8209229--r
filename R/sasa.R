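# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic golden-spiral sphere points; per-atom area = fraction of
# test points on the probe-expanded sphere not occluded by any neighbor,
# times the sphere area. Per-residue areas are sums over the residue's
# heavy atoms, so they are additive by construction.

# van der Waals radii (angstrom) by element; .default covers exotic elements
.VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  H = 1.20, D = 1.20, .default = 1.70
)

.vdwRadius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- .VDW_RADII[[".default"]]
  unname(r)
}

# n deterministic, near-uniform points on the unit sphere (golden spiral)
.spherePoints <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# all atom pairs with distance < cutoff, as data.frame(i, j, d), i < j.
# Blocked all-pairs scan: exact, vectorized, adequate for the structure
# sizes this package targets (up to a few thousand heavy atoms).
.atomPairsWithin <- function(xyz, cutoff, block = 512L) {
  n <- nrow(xyz)
  out <- vector("list", 0L)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  c2 <- cutoff^2
  starts <- seq.int(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    if (s + 1L > n) break
    rows <- s:e
    rest <- (s + 1L):n
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz[rest, , drop = FALSE]^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz[rest, , drop = FALSE])
    hit <- which(d2 < c2, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- rows[hit[, 1L]]
      j <- rest[hit[, 2L]]
      keep <- i < j
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          i = i[keep], j = j[keep],
          d = sqrt(pmax(0, d2[hit][keep]))
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(i = integer(0), j = integer(0), d = numeric(0))
}

# core Shrake-Rupley: per-atom accessible area for heavy atoms
.shrakeRupley <- function(xyz, radii, probeRadius, spherePoints) {
  n <- nrow(xyz)
  pts <- .spherePoints(spherePoints)
  expanded <- radii + probeRadius
  maxReach <- 2 * max(expanded)
  pairs <- .atomPairsWithin(xyz, maxReach)
  nbr <- vector("list", n)
  if (nrow(pairs)) {
    touch <- pairs$d < expanded[pairs$i] + radii[pairs$j] + probeRadius |
      pairs$d < expanded[pairs$j] + radii[pairs$i] + probeRadius
    pairs <- pairs[touch, , drop = FALSE]
    nbr <- split(c(pairs$j, pairs$i), factor(c(pairs$i, pairs$j), levels = seq_len(n)))
  }
  areas <- numeric(n)
  for (i in seq_len(n)) {
    R <- expanded[i]
    p <- pts * R
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, spherePoints)
    for (j in nbr[[i]]) {
      rj2 <- (radii[j] + probeRadius)^2
      dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
      free <- free & (dx * dx + dy * dy + dz * dz > rj2)
      if (!any(free)) break
    }
    areas[i] <- 4 * pi * R^2 * sum(free) / spherePoints
  }
  areas
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley numerical quadrature over heavy atoms: each atom's sphere
#' (van der Waals radius plus probe) is sampled with a deterministic
#' golden-spiral point set, and the accessible fraction becomes the atom's
#' area. Residue areas are sums over the residue's heavy atoms, so they add
#' up exactly to the whole-structure area. Hydrogens present in the input
#' are ignored (heavy-atom convention).
#'
#' @param x a [RINStructure-class].
#' @param probeRadius solvent probe radius in angstrom (default 1.4).
#' @param spherePoints quadrature points per atom (default 960).
#' @param ... unused.
#' @return named numeric vector: residue key to area in square angstrom.
#' @export
setMethod("computeSurfaceArea", "RINStructure",
  function(x, probeRadius = 1.4, spherePoints = 960L, ...) {
    stopifnot(probeRadius > 0, spherePoints >= 12)
    a <- x@atoms[!x@atoms$isHydrogen, , drop = FALSE]
    allKeys <- unique(x@atoms$key)
    noHeavy <- setdiff(allKeys, unique(a$key))
    if (length(noHeavy)) {
      stop("residue(s) with no heavy atoms: ", paste(noHeavy, collapse = ", "))
    }
    xyz <- as.matrix(a[, c("x", "y", "z")])
    radii <- .vdwRadius(a$element)
    atomAreas <- .shrakeRupley(xyz, radii, probeRadius, as.integer(spherePoints))
    res <- tapply(atomAreas, factor(a$key, levels = allKeys), sum)
    out <- as.numeric(res)
    names(out) <- allKeys
    out
  })
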