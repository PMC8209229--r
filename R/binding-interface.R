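# Binding-site neighborhoods: first-shell network neighbors of curated
# binding-site residues, and centrality comparisons between groups.

#' Read a binding-site residue file
#'
#' Tab-separated file with columns \code{partner}, \code{chain},
#' \code{position} (legacy mature numbering) and optional \code{source};
#' lines starting with \code{#} are comments. The file shipped in
#' \code{inst/extdata} is a deliberately incomplete starter list.
#'
#' @param file TSV path.
#' @return data.frame with an added \code{key} column of residue keys.
#' @export
readBindingSites <- function(file = system.file("extdata", "fviii_binding_sites_starter.tsv",
                                                package = "fviiiRIN")) {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("partner", "chain", "position") %in% names(tab)))
  tab$key <- makeResidueKey(tab$chain, tab$position)
  tab
}

#' First-shell neighbors of binding-site residues
#'
#' Returns the residues adjacent in the network to at least one site
#' residue, minus the site residues themselves (deduplicated across
#' partners). Site residues absent from the network are dropped with a
#' warning; an empty intersection is an error.
#'
#' @param network a [ResidueNetwork-class].
#' @param siteKeys character vector of binding-site residue keys (union
#'   over partners).
#' @param shell neighborhood radius in graph steps (default 1, the paper's
#'   immediate neighbors; larger values take all nodes within that
#'   distance).
#' @return character vector of neighbor residue keys.
#' @export
siteNeighborhood <- function(network, siteKeys, shell = 1L) {
  stopifnot(is(network, "ResidueNetwork"), shell >= 1L)
  g <- network@graph
  nodes <- igraph::V(g)$name
  missing <- setdiff(siteKeys, nodes)
  if (length(missing) == length(unique(siteKeys))) {
    stop("no binding-site residue matches a network node; unmatched: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  if (length(missing)) {
    warning(length(missing), " site residue(s) not in the network, dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  sites <- intersect(siteKeys, nodes)
  nb <- igraph::ego(g, order = shell, nodes = sites, mode = "all")
  neigh <- unique(unlist(lapply(nb, function(v) v$name)))
  setdiff(neigh, sites)
}

#' Compare a centrality measure between two residue groups
#'
#' Unpaired two-sided Wilcoxon rank-sum test on the measure's values, with
#' exact p-values for small tie-free samples (both groups at most 25) and
#' the tie-corrected normal approximation otherwise. Groups must be
#' disjoint.
#'
#' @param tab centrality table.
#' @param groupA,groupB character vectors of residue keys.
#' @param measure measure column name (e.g. \code{"degree"}).
#' @return data.frame row: measure, group sizes, group medians, rank-sum
#'   statistic W, two-sided p-value.
#' @export
compareCentrality <- function(tab, groupA, groupB, measure) {
  stopifnot(measure %in% names(tab))
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  va <- tab[[measure]][tab$key %in% groupA]
  vb <- tab[[measure]][tab$key %in% groupB]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2 || length(vb) < 2) {
    stop("both groups need >= 2 residues with '", measure, "' defined")
  }
  ties <- anyDuplicated(c(va, vb)) > 0
  if (length(unique(c(va, vb))) == 1L) {
    w <- length(va) * length(vb) / 2
    p <- 1
  } else {
    exact <- !ties && length(va) <= 25 && length(vb) <= 25
    ht <- suppressWarnings(
      stats::wilcox.test(va, vb, alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    w <- unname(ht$statistic)
    p <- min(1, ht$p.value)
  }
  data.frame(measure = measure, nA = length(va), nB = length(vb),
             medianA = stats::median(va), medianB = stats::median(vb),
             statistic = w, p_value = p, stringsAsFactors = FALSE)
}
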