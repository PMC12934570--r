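#' Assemble the heterogeneous proteome-wide interaction graph
#'
#' Builds a [HeteroGraph-class] from the four input tables: target nodes are
#' all targets with at least one pocket in the residue table; drug nodes are
#' all drugs appearing in either binding source. Pocket-similarity edges join
#' target pairs whose maximal residue-pair cosine similarity strictly exceeds
#' `cfg$targetSimThreshold`; drug-similarity edges join drug pairs whose
#' embedding cosine similarity strictly exceeds `cfg$drugSimThreshold`; PPI
#' records pass [filterPPI()]. Binding records referencing targets without
#' pockets are dropped (and counted in the metadata). A pair present in both
#' binding sources is kept as a supervision edge and removed from the
#' message-passing set, so no pair is simultaneously supervision and message
#' path.
#'
#' Drug node features are the drug embeddings; target node features are the
#' mean of all residue embeddings across the target's pockets (pooled pocket
#' representation).
#'
#' @param residues residue embedding table (see [targetSimilarity()]).
#' @param drugs data.frame with columns `drug_id`, `smiles` and a numeric
#'   matrix column `embedding`.
#' @param ppi data.frame of PPI records (see [filterPPI()]).
#' @param bind labeled binding records: data.frame (`drug`, `target`,
#'   `label` in 0/1).
#' @param bindMP positive-only auxiliary binding records: data.frame
#'   (`drug`, `target`).
#' @param cfg a [graphConfig()].
#' @return a [HeteroGraph-class].
#' @examples
#' b <- generateBundle(simConfig(seed = 1))
#' g <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
#' g
#' @export
assembleGraph <- function(residues, drugs, ppi, bind, bindMP = NULL,
                          cfg = graphConfig()) {
  .checkResidueTable(residues)
  if (!all(c("drug_id", "embedding") %in% names(drugs)))
    stop("drug table needs columns drug_id, embedding")
  if (anyDuplicated(drugs$drug_id)) stop("duplicated drug_id in drug table")
  if (is.null(bindMP)) bindMP <- .emptyBindFrame(label = FALSE)
  bind <- as.data.frame(bind); bindMP <- as.data.frame(bindMP)
  if (!all(c("drug", "target", "label") %in% names(bind)))
    stop("labeled binding table needs columns drug, target, label")
  if (nrow(bind) && !all(bind$label %in% c(0, 1)))
    stop("labels must be 0/1 in the labeled binding table")
  if ("label" %in% names(bindMP) && nrow(bindMP) && !all(bindMP$label == 1))
    stop("auxiliary (message-passing) binding records must be positive-only")

  vTarget <- sort(unique(as.character(residues$target_id)))
  allBindDrugs <- unique(c(as.character(bind$drug), as.character(bindMP$drug)))
  missing <- setdiff(allBindDrugs, drugs$drug_id)
  if (length(missing))
    stop("binding records reference drugs absent from the drug table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  vDrug <- sort(allBindDrugs)

  ## drop binding records whose target has no pocket representation
  keepB <- bind$target %in% vTarget
  keepM <- bindMP$target %in% vTarget
  droppedBind <- sum(!keepB); droppedMP <- sum(!keepM)
  bind <- bind[keepB, , drop = FALSE]
  bindMP <- bindMP[keepM, , drop = FALSE]

  ## duplicate handling inside the labeled source
  bk <- .pairKey(bind$drug, bind$target)
  if (anyDuplicated(bk)) {
    lab <- tapply(bind$label, bk, function(l) length(unique(l)))
    if (any(lab > 1)) {
      conf <- names(lab)[lab > 1][1L]
      stop("conflicting duplicate labels in labeled binding table for pair: ",
           gsub("\r", " / ", conf))
    }
    bind <- bind[!duplicated(bk), , drop = FALSE]
  }
  mk <- .pairKey(bindMP$drug, bindMP$target)
  bindMP <- bindMP[!duplicated(mk), , drop = FALSE]
  ## prediction source wins: remove supervised pairs from the MP set
  inBoth <- .pairKey(bindMP$drug, bindMP$target) %in% .pairKey(bind$drug, bind$target)
  dedupMP <- sum(inBoth)
  bindMP <- bindMP[!inBoth, , drop = FALSE]

  dIdx <- match(vDrug, drugs$drug_id)
  drugFeat <- drugs$embedding[dIdx, , drop = FALSE]
  rownames(drugFeat) <- vDrug
  if (any(rowSums(drugFeat^2) == 0)) stop("zero-norm drug embedding")

  ## pooled pocket representation as target features
  emb <- residues$embedding
  grp <- factor(residues$target_id, levels = vTarget)
  targetFeat <- rowsum(emb, grp) / as.vector(table(grp))
  rownames(targetFeat) <- vTarget

  eTsim <- buildSimilarityEdges(vTarget, residues, cfg$targetSimThreshold,
                                mode = "target", chunkSize = cfg$chunkSize)
  eDsim <- buildSimilarityEdges(vDrug, drugFeat, cfg$drugSimThreshold,
                                mode = "drug", chunkSize = cfg$chunkSize)
  ePPI <- filterPPI(ppi, cfg, targets = vTarget)

  bindOut <- data.frame(drug = as.character(bind$drug),
                        target = as.character(bind$target),
                        label = as.integer(bind$label),
                        stringsAsFactors = FALSE)
  bindOut <- bindOut[order(bindOut$drug, bindOut$target), , drop = FALSE]
  mpOut <- data.frame(drug = as.character(bindMP$drug),
                      target = as.character(bindMP$target),
                      stringsAsFactors = FALSE)
  mpOut <- mpOut[order(mpOut$drug, mpOut$target), , drop = FALSE]
  rownames(bindOut) <- rownames(mpOut) <- NULL

  new("HeteroGraph",
      targetIds = vTarget, drugIds = vDrug,
      targetFeatures = targetFeat, drugFeatures = drugFeat,
      ppi = ePPI, targetSim = eTsim, drugSim = eDsim,
      bind = bindOut, bindMP = mpOut,
      metadata = list(config = cfg,
                      droppedBindPocketless = droppedBind,
                      droppedMPPocketless = droppedMP,
                      dedupMP = dedupMP,
                      insertedDrugs = character(0)))
}

#' @rdname HeteroGraph-accessors
#' @export
setMethod("targetIds", "HeteroGraph", function(x) x@targetIds)

#' @rdname HeteroGraph-accessors
#' @export
setMethod("drugIds", "HeteroGraph", function(x) x@drugIds)

#' @rdname HeteroGraph-accessors
#' @export
setMethod("nodeFeatures", "HeteroGraph", function(x, type = c("target", "drug")) {
  type <- match.arg(type)
  if (type == "target") x@targetFeatures else x@drugFeatures
})

.edgeTypes <- c("ppi", "target_sim", "drug_sim", "bind", "bind_mp")

#' @rdname HeteroGraph-accessors
#' @export
setMethod("edgeTable", "HeteroGraph", function(x, type = .edgeTypes) {
  type <- match.arg(type, .edgeTypes)
  switch(type, ppi = x@ppi, target_sim = x@targetSim, drug_sim = x@drugSim,
         bind = x@bind, bind_mp = x@bindMP)
})

## igraph view over all edge types; node names are prefixed so a drug and a
## target can never collide on a raw id.
.asIgraph <- function(g) {
  pre <- function(p, x) paste0(p, x, recycle0 = TRUE)
  tn <- pre("t:", g@targetIds); dn <- pre("d:", g@drugIds)
  e <- rbind(
    cbind(pre("t:", g@ppi$a), pre("t:", g@ppi$b)),
    cbind(pre("t:", g@targetSim$a), pre("t:", g@targetSim$b)),
    cbind(pre("d:", g@drugSim$a), pre("d:", g@drugSim$b)),
    cbind(pre("d:", g@bind$drug), pre("t:", g@bind$target)),
    cbind(pre("d:", g@bindMP$drug), pre("t:", g@bindMP$target))
  )
  igraph::graph_from_data_frame(
    as.data.frame(e, stringsAsFactors = FALSE),
    directed = FALSE, vertices = c(tn, dn))
}

#' Largest connected component of a heterogeneous graph
#'
#' Connectivity counts all five edge types. Ties between equally sized
#' components are broken in favor of the component containing the
#' lexicographically smallest node id.
#'
#' @param x a [HeteroGraph-class] with at least one node.
#' @return the induced [HeteroGraph-class] on the largest component.
#' @export
setMethod("largestComponent", "HeteroGraph", function(x) {
  if (length(x@targetIds) + length(x@drugIds) == 0L) stop("empty graph")
  ig <- .asIgraph(x)
  comp <- igraph::components(ig)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## smallest raw node id per tied component
    nm <- substring(names(comp$membership), 3L)
    mins <- vapply(best, function(ci) min(nm[comp$membership == ci]), character(1))
    best <- best[order(mins)][1L]
  }
  keep <- names(comp$membership)[comp$membership == best]
  keepT <- substring(keep[startsWith(keep, "t:")], 3L)
  keepD <- substring(keep[startsWith(keep, "d:")], 3L)
  .induceSubgraph(x, keepT, keepD)
})

.induceSubgraph <- function(g, keepT, keepD) {
  keepT <- sort(keepT); keepD <- sort(keepD)
  fe <- function(e) {
    e[e$a %in% keepT & e$b %in% keepT, , drop = FALSE]
  }
  fd <- function(e) e[e$a %in% keepD & e$b %in% keepD, , drop = FALSE]
  fb <- function(e) e[e$drug %in% keepD & e$target %in% keepT, , drop = FALSE]
  md <- g@metadata
  md$parentNodes <- c(targets = length(g@targetIds), drugs = length(g@drugIds))
  md$insertedDrugs <- intersect(md$insertedDrugs %||% character(0), keepD)
  out <- new("HeteroGraph",
      targetIds = keepT, drugIds = keepD,
      targetFeatures = g@targetFeatures[keepT, , drop = FALSE],
      drugFeatures = g@drugFeatures[keepD, , drop = FALSE],
      ppi = fe(g@ppi), targetSim = fe(g@targetSim), drugSim = fd(g@drugSim),
      bind = fb(g@bind), bindMP = fb(g@bindMP),
      metadata = md)
  out
}

#' Summary statistics of a heterogeneous graph
#'
#' Node and edge counts per type, average degrees, and the number of
#' connected components.
#'
#' @param x a [HeteroGraph-class].
#' @return data.frame with columns `property`, `value`.
#' @export
setMethod("graphStats", "HeteroGraph", function(x) {
  nT <- length(x@targetIds); nD <- length(x@drugIds)
  counts <- c(ppi = nrow(x@ppi), target_sim = nrow(x@targetSim),
              drug_sim = nrow(x@drugSim), bind = nrow(x@bind),
              bind_mp = nrow(x@bindMP))
  nE <- sum(counts)
  degT <- if (nT) (2 * (counts["ppi"] + counts["target_sim"]) +
                   counts["bind"] + counts["bind_mp"]) / nT else 0
  degD <- if (nD) (2 * counts["drug_sim"] + counts["bind"] + counts["bind_mp"]) / nD else 0
  ncomp <- if (nT + nD) igraph::count_components(.asIgraph(x)) else 0L
  data.frame(
    property = c("n_nodes", "n_target_nodes", "n_drug_nodes", "n_edges",
                 "n_bind_edges", "n_bind_mp_edges", "n_ppi_edges",
                 "n_target_sim_edges", "n_drug_sim_edges",
                 "avg_degree", "avg_target_degree", "avg_drug_degree",
                 "n_components"),
    value = as.numeric(c(nT + nD, nT, nD, nE,
                         counts["bind"], counts["bind_mp"], counts["ppi"],
                         counts["target_sim"], counts["drug_sim"],
                         if (nT + nD) 2 * nE / (nT + nD) else 0, degT, degD,
                         ncomp)),
    stringsAsFactors = FALSE)
})

#' Node-ordering hash of a graph
#'
#' Hash over the sorted target and drug id vectors, excluding drugs inserted
#' after assembly with [insertDrug()]. Model checkpoints carry this hash and
#' scoring refuses graphs whose base node ordering differs.
#'
#' @param x a [HeteroGraph-class].
#' @return character hash.
#' @export
setMethod("graphHash", "HeteroGraph", function(x) {
  base <- setdiff(x@drugIds, x@metadata$insertedDrugs %||% character(0))
  rlang::hash(list(x@targetIds, sort(base)))
})

setMethod("show", "HeteroGraph", function(object) {
  st <- graphStats(object)
  v <- stats::setNames(st$value, st$property)
  cat("HeteroGraph with", v["n_target_nodes"], "targets,",
      v["n_drug_nodes"], "drugs\n")
  cat("  edges: ppi=", v["n_ppi_edges"], " target_sim=", v["n_target_sim_edges"],
      " drug_sim=", v["n_drug_sim_edges"], " bind=", v["n_bind_edges"],
      " bind_mp=", v["n_bind_mp_edges"], "\n", sep = "")
  cat("  components:", v["n_components"], "\n")
  invisible(object)
})
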