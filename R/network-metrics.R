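# Seven per-residue centrality measures and their correlation structure.
#
# Conventions for degenerate graphs: closeness is computed within each
# connected component with (n_comp - 1) normalization and is 0 for isolated
# nodes; Burt's constraint is undefined (NA) for isolated nodes; HITS
# authority is a deterministic power iteration from the uniform vector,
# max-normalized, and all-zero on edgeless graphs.

# component-wise closeness: (n_comp - 1) / sum of within-component distances
.closenessByComponent <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1L) { out[idx] <- 0; next }
    d <- igraph::distances(g, v = idx, to = idx)
    out[idx] <- (length(idx) - 1) / rowSums(d)
  }
  out
}

# HITS authority on an undirected graph: power iteration x <- A (A x),
# started from the uniform vector, max-normalized each step
.hitsAuthority <- function(g, tol = 1e-12, maxIter = 10000L) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(numeric(n))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1, n)
  for (k in seq_len(maxIter)) {
    xn <- as.numeric(A %*% as.numeric(A %*% x))
    m <- max(xn)
    if (m == 0) return(numeric(n))
    xn <- xn / m
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  x
}

#' Per-residue centrality table
#'
#' Computes the seven node-centrality measures of the residue interaction
#' network on the unweighted, undirected graph: degree (neighbor count),
#' betweenness (unnormalized Brandes pair counts, each unordered pair once),
#' closeness (within-component, \code{(n_comp - 1) / sum d}; 0 for isolated
#' nodes), Burt's constraint (NA for isolated nodes), PageRank (uniform
#' teleport), k-core number, and HITS authority (max-normalized). Optionally
#' joins relative exposure and domain labels.
#'
#' @param x a [ResidueNetwork-class].
#' @param damping PageRank damping factor in (0,1), default 0.85.
#' @param exposure optional named per-residue relative exposure from
#'   [relativeExposure()].
#' @param domains optional named character vector of domain labels (e.g. a
#'   structure's \code{domainMap}).
#' @param ... unused.
#' @return data.frame with one row per network node: \code{key}, the seven
#'   measures, and optional \code{relative_exposure} / \code{domain}.
#' @export
setMethod("computeCentralities", "ResidueNetwork",
  function(x, damping = 0.85, exposure = NULL, domains = NULL, ...) {
    g <- x@graph
    if (igraph::vcount(g) == 0L) stop("empty graph")
    if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
      stop("damping must be in (0,1)")
    }
    keys <- igraph::V(g)$name
    tab <- data.frame(
      key = keys,
      degree = unname(igraph::degree(g)),
      betweenness = unname(igraph::betweenness(g, directed = FALSE)),
      closeness = .closenessByComponent(g),
      burt_constraint = unname(igraph::constraint(g)),
      pagerank = unname(igraph::page_rank(g, damping = damping)$vector),
      kcore = unname(igraph::coreness(g)),
      authority = .hitsAuthority(g),
      stringsAsFactors = FALSE
    )
    tab$burt_constraint[tab$degree == 0] <- NA_real_
    if (!is.null(exposure)) tab$relative_exposure <- unname(exposure[tab$key])
    if (!is.null(domains)) tab$domain <- unname(domains[tab$key])
    tab
  })

#' Pearson correlations among centrality measures
#'
#' @param tab centrality table from [computeCentralities()].
#' @param measures measure columns to correlate (default: the seven
#'   centralities present in the table).
#' @return symmetric correlation matrix with unit diagonal; rows/columns of
#'   zero-variance measures are NA (with a warning).
#' @export
measureCorrelations <- function(tab, measures = intersect(.CENTRALITY_MEASURES, names(tab))) {
  stopifnot(nrow(tab) >= 3, all(measures %in% names(tab)))
  m <- as.matrix(tab[, measures, drop = FALSE])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  v <- apply(m, 2, stats::var)
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  zero <- v == 0
  if (any(zero)) {
    warning("zero-variance measure(s): ", paste(measures[zero], collapse = ", "))
    r[zero, ] <- NA_real_
    r[, zero] <- NA_real_
  }
  diag(r) <- ifelse(zero, NA_real_, 1)
  r
}
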