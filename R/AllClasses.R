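#' @import methods
NULL

#' Heterogeneous proteome-wide interaction graph
#'
#' Container for the undirected heterogeneous graph on which message passing
#' and link prediction operate. Nodes are protein targets and drugs; the five
#' typed edge sets are protein-protein interactions (`ppi`), binding-pocket
#' similarity between targets (`target_sim`), drug-drug similarity
#' (`drug_sim`), labeled binding interactions used for supervision (`bind`),
#' and positive-only auxiliary binding interactions used exclusively for
#' message passing (`bind_mp`).
#'
#' Node ordering is lexicographic by id, targets before drugs; the feature
#' matrices follow this order. Same-type edges are stored once per unordered
#' pair with `a < b`; binding edges are stored as (drug, target).
#'
#' @slot targetIds,drugIds character vectors of node ids (sorted).
#' @slot targetFeatures,drugFeatures numeric feature matrices, one row per
#'   node in id order.
#' @slot ppi,targetSim,drugSim data.frames with columns `a`, `b`.
#' @slot bind data.frame with columns `drug`, `target`, `label` (0/1).
#' @slot bindMP data.frame with columns `drug`, `target`.
#' @slot metadata list of assembly provenance (config echo, dedup counts,
#'   inserted drug ids).
#'
#' @seealso [assembleGraph()], [largestComponent()], [graphStats()]
#' @export
setClass("HeteroGraph",
  representation(
    targetIds = "character",
    drugIds = "character",
    targetFeatures = "matrix",
    drugFeatures = "matrix",
    ppi = "data.frame",
    targetSim = "data.frame",
    drugSim = "data.frame",
    bind = "data.frame",
    bindMP = "data.frame",
    metadata = "list"
  )
)

setValidity("HeteroGraph", function(object) {
  msg <- character(0)
  ts <- object@targetIds; ds <- object@drugIds
  if (anyDuplicated(ts)) msg <- c(msg, "duplicated target ids")
  if (anyDuplicated(ds)) msg <- c(msg, "duplicated drug ids")
  if (length(intersect(ts, ds))) msg <- c(msg, "a node id is both target and drug")
  if (is.unsorted(ts)) msg <- c(msg, "target ids not sorted")
  if (is.unsorted(ds)) msg <- c(msg, "drug ids not sorted")
  if (nrow(object@targetFeatures) != length(ts))
    msg <- c(msg, "target feature rows != number of targets")
  if (nrow(object@drugFeatures) != length(ds))
    msg <- c(msg, "drug feature rows != number of drugs")
  chkSame <- function(e, ids, nm) {
    out <- character(0)
    if (nrow(e)) {
      if (any(e$a == e$b)) out <- c(out, paste0(nm, ": self-loop present"))
      if (!all(c(e$a, e$b) %in% ids)) out <- c(out, paste0(nm, ": endpoint outside node set"))
      if (anyDuplicated(.pairKey(pmin(e$a, e$b), pmax(e$a, e$b))))
        out <- c(out, paste0(nm, ": duplicated unordered pair"))
    }
    out
  }
  msg <- c(msg, chkSame(object@ppi, ts, "ppi"),
           chkSame(object@targetSim, ts, "target_sim"),
           chkSame(object@drugSim, ds, "drug_sim"))
  chkBip <- function(e, nm) {
    out <- character(0)
    if (nrow(e)) {
      if (!all(e$drug %in% ds)) out <- c(out, paste0(nm, ": unknown drug"))
      if (!all(e$target %in% ts)) out <- c(out, paste0(nm, ": unknown target"))
      if (anyDuplicated(.pairKey(e$drug, e$target)))
        out <- c(out, paste0(nm, ": duplicated pair"))
    }
    out
  }
  msg <- c(msg, chkBip(object@bind, "bind"), chkBip(object@bindMP, "bind_mp"))
  if (nrow(object@bind) && !all(object@bind$label %in% c(0L, 1L)))
    msg <- c(msg, "bind labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Split plan for training, validation and test partitions
#'
#' Holds either a random interaction-level split or a drug-similarity split:
#' fingerprint clusters, cluster medoids, the cluster-to-partition map,
#' per-interaction partition labels, and per-fold message-passing allowlists
#' of auxiliary binding records (leakage control).
#'
#' @slot mode `"random"` or `"drug"`.
#' @slot seed integer seed the plan was built from.
#' @slot nFolds number of cross-validation folds (0 for random mode).
#' @slot testFraction configured held-out fraction of interactions.
#' @slot clusters data.frame (`drug_id`, `cluster_id`) for labeled drugs.
#' @slot medoids data.frame (`cluster_id`, `drug_id`).
#' @slot medoidFps list with `bits` (named list of on-bit integer vectors per
#'   cluster id) and `size`.
#' @slot partition data.frame (`cluster_id`, `partition`).
#' @slot interactions data.frame (`drug`, `target`, `label`, `partition`).
#' @slot mpAllowlist named list, fold label -> data.frame (`drug`, `target`)
#'   of auxiliary records allowed to message-pass for that fold.
#' @slot auxAssignment data.frame (`drug_id`, `cluster_id`, `partition`) of
#'   auxiliary drugs placed by medoid similarity.
#' @slot auxFps list like `medoidFps` for auxiliary drugs (kept so leakage
#'   audits can recompute the assignment independently).
#' @slot allowAllAux logical; random mode admits all auxiliary records.
#' @slot config list echo of split parameters.
#' @export
setClass("SplitPlan",
  representation(
    mode = "character", seed = "integer", nFolds = "integer",
    testFraction = "numeric",
    clusters = "data.frame", medoids = "data.frame", medoidFps = "list",
    partition = "data.frame", interactions = "data.frame",
    mpAllowlist = "list", auxAssignment = "data.frame", auxFps = "list",
    allowAllAux = "logical", config = "list"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("random", "drug")) msg <- c(msg, "mode must be random/drug")
  it <- object@interactions
  need <- c("drug", "target", "label", "partition")
  if (!all(need %in% names(it))) msg <- c(msg, "interactions missing columns")
  if (object@mode == "drug" && nrow(it)) {
    byDrug <- tapply(it$partition, it$drug, function(p) length(unique(p)))
    if (any(byDrug > 1)) msg <- c(msg, "a drug's interactions span partitions")
  }
  if (length(msg)) msg else TRUE
})

#' Graph-transformer link prediction model
#'
#' Parameters of the model: per-node-type input projections to the shared
#' embedding dimension, a learned virtual-node feature vector, per-layer
#' per-edge-type transformer-convolution weights, and the two-layer
#' feedforward link head. Created by [initModel()]; trained by
#' [trainModel()].
#'
#' @slot config model configuration list (see [modelConfig()]).
#' @slot params nested parameter list (projections, virtual node, trunk
#'   layers, head).
#' @slot graphHash hash of the node ordering of the graph the model was
#'   initialized/trained on; scoring refuses mismatched graphs unless
#'   overridden.
#' @slot seed integer run seed used for initialization.
#' @export
setClass("DTIModel",
  representation(config = "list", params = "list",
                 graphHash = "character", seed = "integer")
)

#' Training result
#'
#' @slot model the [DTIModel-class] at the epoch with the best validation
#'   AUROC (earliest epoch on ties).
#' @slot epochLog data.frame with one row per epoch: training loss,
#'   validation AUROC, wall time, the hash of the message-passing adjacency
#'   actually used, and the per-epoch supervision/message-passing separation
#'   check.
#' @slot fold fold label the model was validated on (`"random"` for random
#'   plans).
#' @slot bestEpoch integer index of the selected epoch.
#' @slot finalParams parameter list at the last epoch (the selected-epoch
#'   parameters live in `model`).
#' @slot trainConfig list echo of the training configuration.
#' @slot mpSignature expected message-passing adjacency hash.
#' @export
setClass("DTIFit",
  representation(model = "DTIModel", epochLog = "data.frame",
                 fold = "character", bestEpoch = "integer",
                 finalParams = "list",
                 trainConfig = "list", mpSignature = "character")
)
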