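# Residue criticality: degree/betweenness group assignment, Pareto-front
# super-critical residues, and per-domain closeness summaries.

#' Assign HDHB / LDHB / LDLB criticality groups
#'
#' Partitions residues by quantile thresholds on degree and betweenness:
#' HDHB (high-degree, high-betweenness: both at or above their high
#' quantile), LDHB (degree at or below its low quantile, betweenness at or
#' above the high quantile), LDLB (both at or below their low quantiles);
#' everything else is unassigned. Thresholds use the linear-interpolation
#' quantile convention, so labels are invariant under rank-preserving
#' rescaling of the measures.
#'
#' @param tab centrality table from [computeCentralities()].
#' @param degreeHigh,betweennessHigh high quantiles (default 0.90).
#' @param degreeLow,betweennessLow low quantiles (default 0.50).
#' @return data.frame: \code{key}, \code{group} (factor with levels HDHB,
#'   LDHB, LDLB, unassigned).
#' @export
assignCriticalityGroups <- function(tab, degreeHigh = 0.90, betweennessHigh = 0.90,
                                    degreeLow = 0.50, betweennessLow = 0.50) {
  if (!(degreeLow < degreeHigh) || !(betweennessLow < betweennessHigh) ||
      degreeLow < 0 || betweennessLow < 0 || degreeHigh > 1 || betweennessHigh > 1) {
    stop("quantiles must satisfy 0 <= low < high <= 1")
  }
  qd <- stats::quantile(tab$degree, c(degreeLow, degreeHigh), names = FALSE, type = 7)
  qb <- stats::quantile(tab$betweenness, c(betweennessLow, betweennessHigh), names = FALSE, type = 7)
  group <- rep("unassigned", nrow(tab))
  group[tab$degree <= qd[1] & tab$betweenness <= qb[1]] <- "LDLB"
  group[tab$degree <= qd[1] & tab$betweenness >= qb[2]] <- "LDHB"
  group[tab$degree >= qd[2] & tab$betweenness >= qb[2]] <- "HDHB"
  data.frame(key = tab$key,
             group = factor(group, levels = c("HDHB", "LDHB", "LDLB", "unassigned")),
             stringsAsFactors = FALSE)
}

#' Pareto front of centrality measures
#'
#' Returns the non-dominated residues: a residue is on the front iff no
#' other residue is at least as large on all chosen measures and strictly
#' larger on at least one (weak dominance with at-least-one-strict; exact
#' ties on all measures keep both). These are the "super-critical" residues
#' when applied to degree, betweenness and closeness together.
#'
#' @param tab centrality table.
#' @param measures columns to maximize jointly (default degree,
#'   betweenness, closeness).
#' @return character vector of residue keys on the front.
#' @export
paretoFront <- function(tab, measures = c("degree", "betweenness", "closeness")) {
  stopifnot(all(measures %in% names(tab)), nrow(tab) > 0)
  m <- as.matrix(tab[, measures, drop = FALSE])
  ok <- stats::complete.cases(m)
  if (!all(ok)) {
    warning(sum(!ok), " residue(s) with missing measures excluded from the front")
  }
  keys <- tab$key[ok]
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L) return(character(0))
  dominated <- logical(n)
  for (i in seq_len(n)) {
    geq <- rowSums(m >= matrix(m[i, ], n, ncol(m), byrow = TRUE)) == ncol(m)
    gt <- rowSums(m > matrix(m[i, ], n, ncol(m), byrow = TRUE)) > 0
    dominated[i] <- any(geq & gt)
  }
  keys[!dominated]
}

#' Per-domain closeness summary
#'
#' Median and quartiles of closeness for each domain label (linear
#' interpolation quantile convention; unlabeled residues are grouped under
#' \code{"unassigned"}).
#'
#' @param tab centrality table with a \code{domain} column.
#' @param measure column to summarize (default \code{"closeness"}).
#' @return data.frame: \code{domain}, \code{n}, \code{q1}, \code{median},
#'   \code{q3}; attribute \code{quantile_type} records the convention.
#' @export
domainClosenessSummary <- function(tab, measure = "closeness") {
  stopifnot(measure %in% names(tab))
  if (is.null(tab$domain)) stop("centrality table has no domain column")
  dom <- ifelse(is.na(tab$domain), "unassigned", tab$domain)
  sp <- split(tab[[measure]], dom)
  out <- do.call(rbind, lapply(names(sp), function(d) {
    q <- stats::quantile(sp[[d]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(domain = d, n = length(sp[[d]]),
               q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "quantile_type") <- "linear interpolation (R type 7)"
  out
}

#' Write criticality results for visualization tools
#'
#' Emits the criticality CSV (residue, group, Pareto flag) and a
#' Cytoscape/Chimera-ready attribute file mapping residues to group color
#' names.
#'
#' @param groups data.frame from [assignCriticalityGroups()].
#' @param front character vector from [paretoFront()].
#' @param file output CSV path.
#' @param attributeFile optional path for the color attribute file.
#' @return \code{file}, invisibly.
#' @export
writeCriticality <- function(groups, front, file, attributeFile = NULL) {
  out <- data.frame(residue = groups$key, group = as.character(groups$group),
                    pareto_front = groups$key %in% front,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file, row.names = FALSE)
  if (!is.null(attributeFile)) {
    colors <- c(HDHB = "red", LDHB = "orange", LDLB = "blue",
                unassigned = "gray")
    att <- data.frame(residue = out$residue,
                      color = ifelse(out$pareto_front, "magenta",
                                     colors[out$group]))
    utils::write.table(att, attributeFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
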