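# End-to-end orchestration: structure -> RIN -> centralities -> criticality
# (-> binding interface -> classifier -> clinical association), with
# deterministic outputs and a machine-readable run report.

#' Run the full residue-network analysis pipeline
#'
#' Executes the stages in order: load or generate a structure, build the
#' residue interaction network, compute centralities (joined with relative
#' exposure and domain labels), assign criticality groups and the Pareto
#' front, then optionally the binding-interface comparison, the activity
#' classifier (on a supplied or generated mutant table) and the clinical
#' association. All stage outputs are written under \code{outDir} as CSV /
#' GraphML / JSON, plus a run report with the configuration, seed, stage
#' row counts and a config hash; identical configuration and seed
#' reproduce identical outputs. A stage failure aborts with the stage name
#' and leaves a \code{FAILED} marker file next to the partial outputs.
#'
#' @param config named list. Recognized keys (all defaults documented):
#'   \code{structurePath} (PDB file) or \code{generator} (a
#'   [generatorSpec()]; default helix of 60 residues, seed from
#'   \code{seed}); \code{chains}; \code{domains} (\code{"none"} or
#'   \code{"fviii"}); \code{cutoff} (5.0); \code{excludeCovalent} (TRUE);
#'   \code{probeRadius} (1.4); \code{spherePoints} (960);
#'   \code{damping} (0.85); \code{quantiles} (list degreeHigh 0.90,
#'   betweennessHigh 0.90, degreeLow 0.50, betweennessLow 0.50);
#'   \code{bindingSiteFile} (optional TSV); \code{mutants} (optional
#'   data.frame or \code{TRUE} to generate synthetically);
#'   \code{classifier} (list: folds 10, flagBand c(0.4, 0.6), features,
#'   fullGrid FALSE); \code{clinical} (optional raw table or \code{TRUE}
#'   to generate).
#' @param outDir output directory (created if missing).
#' @param seed integer seed driving every stochastic stage.
#' @return the run report, invisibly (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("rinrun"), seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(
    structurePath = NULL, chains = NULL, domains = "none",
    generator = NULL, cutoff = 5.0, excludeCovalent = TRUE,
    probeRadius = 1.4, spherePoints = 960L, damping = 0.85,
    quantiles = list(degreeHigh = 0.90, betweennessHigh = 0.90,
                     degreeLow = 0.50, betweennessLow = 0.50),
    bindingSiteFile = NULL, mutants = NULL,
    classifier = list(folds = 10L, flagBand = c(0.4, 0.6),
                      features = .DEFAULT_FEATURES, fullGrid = FALSE),
    clinical = NULL
  ), config)
  cfgHash <- sum(utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = "")) *
                   (seq_along(utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = ""))) %% 97 + 1)) %% 1e9

  report <- list(package = "fviiiRIN",
                 version = as.character(utils::packageVersion("fviiiRIN")),
                 seed = seed, configHash = cfgHash, stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(outDir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # structure
  s <- stage("structure", function() {
    if (!is.null(cfg$structurePath)) {
      readStructure(cfg$structurePath, chains = cfg$chains, domains = cfg$domains)
    } else {
      spec <- cfg$generator
      if (is.null(spec)) spec <- generatorSpec(seed = seed, nResidues = 60L)
      generateStructure(spec, path = file.path(outDir, "structure.pdb"))
    }
  })
  report$stages$structure <- list(residues = nrow(residueTable(s)))

  # surface + exposure
  expo <- stage("exposure", function() {
    areas <- computeSurfaceArea(s, probeRadius = cfg$probeRadius,
                                spherePoints = cfg$spherePoints)
    rel <- relativeExposure(s, areas = areas)
    writeResidueAreas(s, areas, rel, file.path(outDir, "residue_areas.csv"))
    rel
  })
  report$stages$exposure <- list(residues = length(expo))

  # network
  net <- stage("network", function() {
    buildRIN(s, cutoff = cfg$cutoff, excludeCovalent = cfg$excludeCovalent)
  })
  report$stages$network <- list(nodes = igraph::vcount(net@graph),
                                edges = igraph::ecount(net@graph))

  # centralities
  doms <- if (length(s@domainMap)) s@domainMap else NULL
  tab <- stage("centralities", function() {
    t <- computeCentralities(net, damping = cfg$damping,
                             exposure = expo, domains = doms)
    utils::write.csv(t, file.path(outDir, "centralities.csv"), row.names = FALSE)
    utils::write.csv(measureCorrelations(t),
                     file.path(outDir, "measure_correlations.csv"))
    t
  })
  report$stages$centralities <- list(rows = nrow(tab))

  # criticality
  crit <- stage("criticality", function() {
    q <- cfg$quantiles
    groups <- assignCriticalityGroups(tab, q$degreeHigh, q$betweennessHigh,
                                      q$degreeLow, q$betweennessLow)
    front <- paretoFront(tab)
    writeCriticality(groups, front, file.path(outDir, "criticality.csv"),
                     attributeFile = file.path(outDir, "criticality_colors.tsv"))
    if (!is.null(tab$domain)) {
      utils::write.csv(domainClosenessSummary(tab),
                       file.path(outDir, "domain_closeness.csv"), row.names = FALSE)
    }
    list(groups = groups, front = front)
  })
  report$stages$criticality <- list(paretoFrontSize = length(crit$front),
                                    groupCounts = as.list(table(crit$groups$group)))

  # export
  stage("export", function() {
    exportNetwork(net, tab = tab, groups = crit$groups, front = crit$front,
                  format = "graphml", file = file.path(outDir, "network.graphml"))
    exportNetwork(net, format = "edge_tsv", file = file.path(outDir, "network_edges.tsv"))
    exportNetwork(net, tab = tab, groups = crit$groups, front = crit$front,
                  format = "node_csv", file = file.path(outDir, "network_nodes.csv"))
  })
  report$stages$export <- list(formats = c("graphml", "edge_tsv", "node_csv"))

  # optional: binding interface
  if (!is.null(cfg$bindingSiteFile)) {
    bi <- stage("binding_interface", function() {
      sites <- readBindingSites(cfg$bindingSiteFile)
      nb <- siteNeighborhood(net, sites$key)
      cmp <- do.call(rbind, lapply(c("degree", "betweenness", "closeness"),
        function(m) compareCentrality(tab, intersect(sites$key, tab$key), nb, m)))
      utils::write.csv(cmp, file.path(outDir, "binding_interface.csv"), row.names = FALSE)
      list(sites = length(intersect(sites$key, tab$key)), neighbors = length(nb))
    })
    report$stages$binding_interface <- bi
  }

  # optional: activity classifier
  if (!is.null(cfg$mutants)) {
    cl <- stage("classifier", function() {
      mut <- cfg$mutants
      if (isTRUE(mut)) {
        spec <- cfg$generator
        if (is.null(spec)) spec <- generatorSpec(seed = seed, nResidues = 60L)
        mut <- generateActivityLabels(tab, spec)
      }
      ft <- buildFeatureTable(tab, mut, features = cfg$classifier$features)
      model <- trainMembers(ft, folds = cfg$classifier$folds, seed = seed,
                            grids = classifierGrids(isTRUE(cfg$classifier$fullGrid)),
                            flagBand = cfg$classifier$flagBand)
      preds <- ensemblePredict(model, as.data.frame(ft$x))
      preds$residue <- ft$keys
      utils::write.csv(preds, file.path(outDir, "predictions.csv"), row.names = FALSE)
      metrics <- c(model$ensembleCV,
                   list(bestParams = model$bestParams, seed = seed))
      jsonlite::write_json(metrics, file.path(outDir, "classifier_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      model$ensembleCV
    })
    report$stages$classifier <- cl
  }

  # optional: clinical association
  if (!is.null(cfg$clinical)) {
    ca <- stage("clinical", function() {
      raw <- cfg$clinical
      harmful <- NULL
      if (isTRUE(raw)) {
        spec <- cfg$generator
        if (is.null(spec)) spec <- generatorSpec(seed = seed, nResidues = 60L)
        rt <- residueTable(s)
        harmful <- rt$resno[order(-tab$degree)][seq_len(max(3, nrow(rt) %/% 4))]
        raw <- generateClinicalTable(rt$resno, spec, harmful)
      }
      san <- sanitizeRecords(raw)
      utils::write.csv(san$records, file.path(outDir, "clinical_sanitized.csv"),
                       row.names = FALSE)
      utils::write.csv(san$exclusions, file.path(outDir, "clinical_exclusions.csv"),
                       row.names = FALSE)
      res <- NULL
      if (!is.null(harmful)) {
        rt <- residueTable(s)
        res <- fisherAssociation(harmful, setdiff(rt$resno, harmful),
                                 unique(san$records$position_legacy))
        utils::write.csv(res, file.path(outDir, "clinical_association.csv"),
                         row.names = FALSE)
      }
      list(kept = nrow(san$records), excluded = nrow(san$exclusions),
           association = if (!is.null(res)) list(odds_ratio = res$odds_ratio,
                                                 p_value = res$p_value))
    })
    report$stages$clinical <- ca
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Export a residue network for external tools
#'
#' GraphML (schema-valid, with all node attributes: the seven centralities,
#' relative exposure, domain, criticality group, Pareto flag), a Cytoscape
#' edge list TSV (node_a, node_b, interaction_classes), or a node
#' attribute CSV.
#'
#' @param x a [ResidueNetwork-class].
#' @param format one of \code{"graphml"}, \code{"edge_tsv"},
#'   \code{"node_csv"}.
#' @param file output path.
#' @param tab optional centrality table to attach as node attributes.
#' @param groups optional criticality assignment from
#'   [assignCriticalityGroups()].
#' @param front optional Pareto front keys from [paretoFront()].
#' @param ... unused.
#' @return \code{file}, invisibly.
#' @export
setMethod("exportNetwork", "ResidueNetwork",
  function(x, format = c("graphml", "edge_tsv", "node_csv"), file,
           tab = NULL, groups = NULL, front = NULL, ...) {
    if (!is.character(format) || !format[1] %in% c("graphml", "edge_tsv", "node_csv")) {
      stop("unknown format '", format[1],
           "'; supported: graphml, edge_tsv, node_csv")
    }
    format <- format[1]
    g <- x@graph
    keys <- igraph::V(g)$name
    nodeAttrs <- data.frame(key = keys, stringsAsFactors = FALSE)
    if (!is.null(tab)) {
      nodeAttrs <- merge(nodeAttrs, tab, by = "key", all.x = TRUE, sort = FALSE)
    }
    if (!is.null(groups)) {
      nodeAttrs$group <- as.character(groups$group[match(keys, groups$key)])
    }
    if (!is.null(front)) nodeAttrs$pareto_front <- keys %in% front
    nodeAttrs <- nodeAttrs[match(keys, nodeAttrs$key), , drop = FALSE]

    if (format == "graphml") {
      for (col in setdiff(names(nodeAttrs), "key")) {
        v <- nodeAttrs[[col]]
        if (is.factor(v)) v <- as.character(v)
        if (is.logical(v)) v <- as.character(v)
        g <- igraph::set_vertex_attr(g, col, value = v)
      }
      igraph::write_graph(g, file, format = "graphml")
    } else if (format == "edge_tsv") {
      et <- edgeTable(x)
      utils::write.table(
        data.frame(node_a = et$keyA, node_b = et$keyB,
                   interaction_classes = et$classes),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.csv(nodeAttrs, file, row.names = FALSE)
    }
    invisible(file)
  })
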