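#' Insert a previously unseen drug into the graph
#'
#' Adds a new drug node with the given embedding as its features, computes
#' drug-similarity edges against all existing drugs at the configured
#' threshold, and adds no binding edges. The virtual-hub connection is made
#' automatically at encoding time, so an embedding dissimilar to every
#' existing drug is still reachable through the hub. Inserted drugs are
#' recorded in the metadata and excluded from the node-ordering hash, and do
#' not gain similarity edges to other inserted drugs.
#'
#' @param graph a [HeteroGraph-class].
#' @param drugId new drug id (must not already be present).
#' @param embedding numeric vector matching the drug feature dimension.
#' @param cfg a [graphConfig()] supplying `drugSimThreshold`.
#' @return the extended [HeteroGraph-class].
#' @export
insertDrug <- function(graph, drugId, embedding,
                       cfg = graph@metadata$config %||% graphConfig()) {
  if (drugId %in% graph@drugIds || drugId %in% graph@targetIds)
    stop("node id '", drugId, "' already present")
  embedding <- as.numeric(embedding)
  if (length(embedding) != ncol(graph@drugFeatures))
    stop("embedding dimension mismatch with drug features")
  if (sum(embedding^2) == 0) stop("zero-norm drug embedding")
  inserted <- graph@metadata$insertedDrugs %||% character(0)
  base <- setdiff(graph@drugIds, inserted)
  sims <- as.vector(.normalizeRows(graph@drugFeatures[base, , drop = FALSE]) %*%
                      (embedding / sqrt(sum(embedding^2))))
  hits <- base[sims > cfg$drugSimThreshold]
  newEdges <- if (length(hits)) {
    .canonPairs(rep(drugId, length(hits)), hits)
  } else .emptyEdgeFrame()
  ds <- sort(c(graph@drugIds, drugId))
  feat <- rbind(graph@drugFeatures, matrix(embedding, 1))
  rownames(feat) <- c(graph@drugIds, drugId)
  feat <- feat[ds, , drop = FALSE]
  dsim <- rbind(graph@drugSim, newEdges)
  dsim <- dsim[order(dsim$a, dsim$b), , drop = FALSE]
  rownames(dsim) <- NULL
  md <- graph@metadata
  md$insertedDrugs <- c(inserted, drugId)
  new("HeteroGraph",
      targetIds = graph@targetIds, drugIds = ds,
      targetFeatures = graph@targetFeatures, drugFeatures = feat,
      ppi = graph@ppi, targetSim = graph@targetSim, drugSim = dsim,
      bind = graph@bind, bindMP = graph@bindMP, metadata = md)
}

#' Score a drug against every target in the largest connected component
#'
#' One encoding pass with frozen weights, then the link head against every
#' target node of the largest connected component of the base graph. The
#' percentile of a target is the fraction of scored targets with a strictly
#' higher score (equal scores share a percentile; the top score has
#' percentile 0). Scores at or above `hitThreshold` are flagged as
#' high-confidence hits.
#'
#' @param fit a [DTIFit-class] (or [DTIModel-class]) trained on the base
#'   graph.
#' @param graph the [HeteroGraph-class], typically after [insertDrug()].
#' @param drugId drug to score.
#' @param useAuxMp include auxiliary binding edges in message passing
#'   (default `TRUE`: deployment uses the full graph).
#' @param hitThreshold report parameter for the high-confidence flag
#'   (default 0.9).
#' @param checkHash refuse a graph whose base node ordering differs from the
#'   one the model was trained on (default `TRUE`).
#' @return data.frame (`target_id`, `score`, `percentile`, `hit`) sorted by
#'   decreasing score.
#' @export
scoreProteome <- function(fit, graph, drugId, useAuxMp = TRUE,
                          hitThreshold = 0.9, checkHash = TRUE) {
  model <- if (is(fit, "DTIFit")) fit@model else fit
  if (!is(model, "DTIModel")) stop("'fit' must be a DTIFit or DTIModel")
  if (!drugId %in% graph@drugIds) stop("drug '", drugId, "' not in graph")
  if (checkHash && !identical(model@graphHash, graphHash(graph)))
    stop("graph node ordering differs from the model's training graph; ",
         "set checkHash = FALSE to override")
  lcc <- largestComponent(graph)
  targets <- targetIds(lcc)
  H <- encodeGraph(graph, model, mp = list(bind_mp = isTRUE(useAuxMp)))
  scores <- linkScore(
    matrix(H[drugId, ], length(targets), model@config$embedDim, byrow = TRUE),
    H[targets, , drop = FALSE], model)
  perc <- (length(scores) - rank(scores, ties.method = "max")) / length(scores)
  out <- data.frame(target_id = targets, score = scores, percentile = perc,
                    hit = scores >= hitThreshold, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
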