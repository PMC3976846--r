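#' @include synthdata.R cbpso.R bayesnet.R
NULL

#' Run the full selection pipeline on synthetic or supplied data
#'
#' Chains the pipeline stages — simulate (optional), aggregate, rank,
#' select, network — writing every artifact into `outDir`:
#' `symptom_table.csv`, `grouping.json` (with learned code maps),
#' `syndromes.csv`, `ranking.csv`, `selection.json` (bitstring, named
#' subset, final fitness, config echo), `trace.json`, `network.dot`,
#' `network.json` and `discretization.json`. Every JSON artifact embeds
#' the seed, so reruns with an identical configuration are identical.
#'
#' @param outDir output directory (created if absent).
#' @param seed integer seed driving simulation, fold shuffling and the
#'   swarm search.
#' @param table,grouping optional [SymptomTable-class] /
#'   [SyndromeGrouping-class]; when omitted a synthetic dataset from
#'   `spec` is generated.
#' @param spec a [syntheticSpec()] used when no table is supplied.
#' @param swarm a [swarmConfig()]; defaults to the standard settings with
#'   `D` set from the grouping.
#' @param lssvr an [lssvrConfig()].
#' @return invisibly, a list with `hierarchy`, `ranking`, `selection`
#'   and `network`.
#' @export
runPipeline <- function(outDir, seed = 1L, table = NULL, grouping = NULL,
                        spec = standardPanelSpec(seed), swarm = NULL,
                        lssvr = lssvrConfig(seed = seed)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(table)) {
    sim <- generateSymptomData(spec)
    table <- sim$table
    grouping <- sim$grouping
    jsonlite::write_json(sim$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  writeSymptomTable(table, file.path(outDir, "symptom_table.csv"))

  hierarchy <- buildHierarchy(table, grouping)
  writeGrouping(hierarchyGrouping(hierarchy),
                file.path(outDir, "grouping.json"))
  syn <- syndromeValues(hierarchy)
  utils::write.csv(as.data.frame(syn, check.names = FALSE),
                   file.path(outDir, "syndromes.csv"), row.names = FALSE)

  if (is.null(swarm)) swarm <- swarmConfig(D = ncol(syn), seed = seed)
  swarm$seed <- as.integer(seed)
  lssvr$seed <- as.integer(seed)
  sel <- selectSyndromes(hierarchy, swarm, lssvr)
  utils::write.csv(sel$ranking, file.path(outDir, "ranking.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         bitstring = bitKey(bestPosition(sel$fit)),
         selected = sel$selected,
         fitness = bestFitness(sel$fit),
         lssvr = list(sigma2 = sel$lssvr$sigma2, gamma = sel$lssvr$gamma),
         config = sel$fit@config),
    file.path(outDir, "selection.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  jsonlite::write_json(
    list(seed = seed, gbest_fitness = fitnessTrace(sel$fit)),
    file.path(outDir, "trace.json"), auto_unbox = TRUE, digits = NA)

  # discrete Bayesian network over the selected syndromes
  selCols <- syn[, sel$selected, drop = FALSE]
  disc <- discretizeTable(selCols)
  writeDiscretizationSpec(disc$specs,
                          file.path(outDir, "discretization.json"))
  dag <- greedyStructureSearch(disc$data)
  bn <- fitCPTs(dag, disc$data)
  writeNetworkDOT(bn, file.path(outDir, "network.dot"))
  writeNetworkJSON(bn, file.path(outDir, "network.json"))

  invisible(list(hierarchy = hierarchy, ranking = sel$ranking,
                 selection = sel, network = bn))
}
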