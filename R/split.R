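#' Hierarchically cluster drugs by fingerprint Tanimoto similarity
#'
#' Agglomerative clustering on the distance `1 - tanimoto`, with the
#' dendrogram cut to exactly `nClusters` clusters. The medoid of a cluster is
#' the member minimizing the summed distance to all cluster members (ties
#' broken by lexicographically smallest drug id).
#'
#' @param fps a [fingerprintSet()].
#' @param nClusters number of clusters (at most the number of drugs).
#' @param linkage agglomeration criterion: `"average"` (default), `"single"`
#'   or `"complete"`.
#' @return list of class `ClusterAssignment` with elements `clusters` (named
#'   integer vector drug id -> cluster id), `medoids` (named character vector
#'   cluster id -> drug id), `medoidFps`, `nClusters`, `linkage`.
#' @export
clusterDrugs <- function(fps, nClusters,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  nClusters <- .assertCount(nClusters, "nClusters")
  ids <- names(fps$bits)
  n <- length(ids)
  if (nClusters > n) stop("nClusters exceeds number of drugs")
  S <- .tanimotoMatrix(fps)
  D <- 1 - S
  if (n == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    cl <- stats::cutree(hc, k = nClusters)
  }
  medoids <- vapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    tot <- rowSums(D[members, members, drop = FALSE])
    cand <- members[tot == min(tot)]
    sort(cand)[1L]
  }, character(1))
  names(medoids) <- as.character(sort(unique(cl)))
  structure(list(
    clusters = cl,
    medoids = medoids,
    medoidFps = fingerprintSet(stats::setNames(fps$bits[medoids], names(medoids)),
                               fps$size),
    nClusters = nClusters, linkage = linkage
  ), class = "ClusterAssignment")
}

#' Assign an external drug to the nearest cluster medoid
#'
#' Returns the cluster whose medoid fingerprint has maximal Tanimoto
#' similarity to `fp`; ties go to the smallest cluster id.
#'
#' @param fp integer vector of on-bit positions.
#' @param assignment a [clusterDrugs()] result (or any list with a
#'   `medoidFps` [fingerprintSet()]).
#' @return cluster id (integer).
#' @export
assignExternalDrug <- function(fp, assignment) {
  mfps <- assignment$medoidFps
  if (is.null(mfps) || !length(mfps$bits)) stop("no medoids available")
  sims <- vapply(mfps$bits, function(m) {
    u <- length(union(fp, m))
    if (u == 0L) 0 else length(intersect(fp, m)) / u
  }, numeric(1))
  cids <- suppressWarnings(as.integer(names(mfps$bits)))
  if (anyNA(cids)) stop("medoid fingerprints must be named by integer cluster ids")
  best <- cids[sims == max(sims)]
  min(best)
}

#' Partition fingerprint clusters into cross-validation folds and a test set
#'
#' Clusters are assigned whole, so all binding interactions of a drug lie in
#' that drug's partition. Assignment is seeded greedy: clusters in order of
#' decreasing interaction count (ties shuffled under `seed`) each go to the
#' partition with the largest relative deficit below its interaction quota
#' (folds share `1 - testFraction` evenly; test gets `testFraction`).
#'
#' @param assignment a [clusterDrugs()] result covering every drug in
#'   `interactions`.
#' @param interactions data.frame (`drug`, `target`, `label`).
#' @param nFolds number of cross-validation folds.
#' @param testFraction fraction of interactions for the held-out test set.
#' @param seed integer seed.
#' @param tolerance allowed deviation of the realized test fraction from
#'   `testFraction` (absolute, default 0.02).
#' @return a [SplitPlan-class] (without auxiliary allowlists; see
#'   [selectMpEdges()] and [drugSplit()]).
#' @export
partitionClusters <- function(assignment, interactions, nFolds = 5L,
                              testFraction = 0.1, seed = 1L,
                              tolerance = 0.02) {
  nFolds <- .assertCount(nFolds, "nFolds")
  testFraction <- .assertProb(testFraction, "testFraction")
  seed <- .assertCount(seed, "seed", min = 0L)
  cl <- assignment$clusters
  miss <- setdiff(unique(interactions$drug), names(cl))
  if (length(miss))
    stop("interactions reference drugs without a cluster: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  icl <- cl[interactions$drug]
  cnt <- table(factor(icl, levels = sort(unique(cl))))
  cids <- as.integer(names(cnt))
  n <- sum(cnt)
  parts <- c(paste0("fold_", seq_len(nFolds) - 1L), "test")
  quota <- c(rep((1 - testFraction) * n / nFolds, nFolds), testFraction * n)
  names(quota) <- parts
  set.seed(seed)
  ord <- order(-as.vector(cnt), sample.int(length(cnt)))
  assigned <- stats::setNames(numeric(length(parts)), parts)
  partOf <- stats::setNames(character(length(cids)), as.character(cids))
  for (i in ord) {
    deficit <- (quota - assigned) / pmax(quota, 1e-9)
    p <- parts[which.max(deficit)]
    partOf[as.character(cids[i])] <- p
    assigned[p] <- assigned[p] + cnt[i]
  }
  realized <- assigned["test"] / n
  clusterCounts <- paste0("cluster ", cids, ": ", as.vector(cnt), collapse = "; ")
  if (abs(realized - testFraction) > tolerance) {
    stop("cannot satisfy test fraction ", testFraction, " within tolerance ",
         tolerance, " (realized ", round(realized, 4), "); ",
         "cluster interaction counts: ", clusterCounts)
  }
  foldCnt <- assigned[parts[seq_len(nFolds)]]
  if (any(foldCnt == 0)) {
    stop("empty cross-validation fold; cluster interaction counts: ",
         clusterCounts)
  }
  it <- data.frame(drug = as.character(interactions$drug),
                   target = as.character(interactions$target),
                   label = as.integer(interactions$label),
                   partition = unname(partOf[as.character(icl)]),
                   stringsAsFactors = FALSE)
  new("SplitPlan",
      mode = "drug", seed = seed, nFolds = nFolds,
      testFraction = testFraction,
      clusters = data.frame(drug_id = names(cl), cluster_id = as.integer(cl),
                            stringsAsFactors = FALSE, row.names = NULL),
      medoids = data.frame(cluster_id = as.integer(names(assignment$medoids)),
                           drug_id = unname(assignment$medoids),
                           stringsAsFactors = FALSE),
      medoidFps = unclass(assignment$medoidFps),
      partition = data.frame(cluster_id = cids, partition = unname(partOf),
                             stringsAsFactors = FALSE),
      interactions = it,
      mpAllowlist = list(), auxAssignment = data.frame(), auxFps = list(),
      allowAllAux = FALSE,
      config = list(nFolds = nFolds, testFraction = testFraction,
                    tolerance = tolerance, seed = seed,
                    linkage = assignment$linkage,
                    nClusters = assignment$nClusters))
}

.foldLabels <- function(plan) paste0("fold_", seq_len(plan@nFolds) - 1L)

#' Auxiliary message-passing allowlist for one fold
#'
#' An auxiliary (positive-only) binding record may message-pass in a fold's
#' training graph only if its drug is most similar (by Tanimoto to the
#' cluster medoids) to a cluster assigned to that fold's *training* set --
#' not to the fold's own validation clusters and not to test clusters.
#'
#' @param plan a [SplitPlan-class] from [partitionClusters()].
#' @param fold a fold label (e.g. `"fold_0"`) that serves as validation.
#' @param auxRecords data.frame (`drug`, `target`) of auxiliary records.
#' @param auxFps [fingerprintSet()] covering the auxiliary drugs; drugs
#'   without a fingerprint are excluded with a warning.
#' @return the allowed subset of `auxRecords`.
#' @export
selectMpEdges <- function(plan, fold, auxRecords, auxFps) {
  if (!fold %in% .foldLabels(plan))
    stop("'fold' must be one of: ", paste(.foldLabels(plan), collapse = ", "))
  if (!nrow(auxRecords)) return(auxRecords[0, , drop = FALSE])
  assignment <- list(medoidFps = do.call(fingerprintSet, plan@medoidFps))
  partOf <- stats::setNames(plan@partition$partition,
                            as.character(plan@partition$cluster_id))
  trainParts <- setdiff(.foldLabels(plan), fold)
  drugs <- unique(as.character(auxRecords$drug))
  noFp <- setdiff(drugs, names(auxFps$bits))
  if (length(noFp)) {
    warning("auxiliary drugs without fingerprints excluded: ",
            paste(utils::head(noFp, 5L), collapse = ", "))
  }
  ok <- vapply(drugs, function(d) {
    if (d %in% noFp) return(FALSE)
    cid <- assignExternalDrug(auxFps$bits[[d]], assignment)
    partOf[as.character(cid)] %in% trainParts
  }, logical(1))
  out <- auxRecords[as.character(auxRecords$drug) %in% drugs[ok], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-similarity split with message-passing leakage control
#'
#' Convenience wrapper running [clusterDrugs()], [partitionClusters()] and
#' [selectMpEdges()] for every fold, and recording the medoid assignment of
#' the auxiliary drugs in the plan.
#'
#' @param interactions labeled binding records (`drug`, `target`, `label`).
#' @param fps [fingerprintSet()] for the labeled drugs.
#' @param auxRecords,auxFps auxiliary binding records and their fingerprints
#'   (may be `NULL`).
#' @param nClusters,nFolds,testFraction,seed,tolerance,linkage see
#'   [clusterDrugs()] and [partitionClusters()].
#' @return a complete [SplitPlan-class].
#' @examples
#' b <- generateBundle(simConfig(seed = 1))
#' plan <- drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
#'                   nClusters = 20, seed = 1)
#' plan
#' @export
drugSplit <- function(interactions, fps, auxRecords = NULL, auxFps = NULL,
                      nClusters = 100L, nFolds = 5L, testFraction = 0.1,
                      seed = 1L, tolerance = 0.02,
                      linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  labeledDrugs <- sort(unique(as.character(interactions$drug)))
  sub <- fingerprintSet(fps$bits[intersect(names(fps$bits), labeledDrugs)],
                        fps$size)
  miss <- setdiff(labeledDrugs, names(sub$bits))
  if (length(miss))
    stop("labeled drugs without fingerprints: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  assignment <- clusterDrugs(sub, nClusters, linkage = linkage)
  plan <- partitionClusters(assignment, interactions, nFolds = nFolds,
                            testFraction = testFraction, seed = seed,
                            tolerance = tolerance)
  if (!is.null(auxRecords) && nrow(auxRecords)) {
    if (is.null(auxFps)) stop("auxiliary records given without fingerprints")
    allow <- lapply(.foldLabels(plan), function(f)
      selectMpEdges(plan, f, auxRecords[, c("drug", "target")], auxFps))
    names(allow) <- .foldLabels(plan)
    plan@mpAllowlist <- allow
    drugs <- sort(intersect(unique(as.character(auxRecords$drug)),
                            names(auxFps$bits)))
    asg <- list(medoidFps = do.call(fingerprintSet, plan@medoidFps))
    partOf <- stats::setNames(plan@partition$partition,
                              as.character(plan@partition$cluster_id))
    cid <- vapply(drugs, function(d)
      assignExternalDrug(auxFps$bits[[d]], asg), integer(1))
    plan@auxAssignment <- data.frame(
      drug_id = drugs, cluster_id = unname(cid),
      partition = unname(partOf[as.character(cid)]),
      stringsAsFactors = FALSE)
    plan@auxFps <- unclass(fingerprintSet(auxFps$bits[drugs], auxFps$size))
  }
  methods::validObject(plan)
  plan
}

#' Random interaction-level split
#'
#' Uniform shuffle of the labeled interactions into train / validation /
#' test partitions at the given ratios, deterministic for a fixed seed. The
#' random split places no restriction on auxiliary message-passing edges.
#'
#' @param interactions labeled binding records (`drug`, `target`, `label`).
#' @param ratios numeric triple (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return a [SplitPlan-class] with mode `"random"`.
#' @export
randomSplit <- function(interactions, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be a (train, val, test) triple summing to 1")
  seed <- .assertCount(seed, "seed", min = 0L)
  n <- nrow(interactions)
  set.seed(seed)
  perm <- sample.int(n)
  nTest <- round(n * ratios[3L])
  nVal <- round(n * ratios[2L])
  part <- rep("train", n)
  part[perm[seq_len(nTest)]] <- "test"
  if (nVal) part[perm[nTest + seq_len(nVal)]] <- "validation"
  it <- data.frame(drug = as.character(interactions$drug),
                   target = as.character(interactions$target),
                   label = as.integer(interactions$label),
                   partition = part, stringsAsFactors = FALSE)
  new("SplitPlan",
      mode = "random", seed = seed, nFolds = 0L, testFraction = ratios[3L],
      clusters = data.frame(), medoids = data.frame(), medoidFps = list(),
      partition = data.frame(), interactions = it,
      mpAllowlist = list(), auxAssignment = data.frame(), auxFps = list(),
      allowAllAux = TRUE,
      config = list(ratios = ratios, seed = seed))
}

#' Audit a split plan for message-passing leakage
#'
#' Verifies that (a) no drug's interactions span two partitions (drug mode),
#' (b) no labeled validation/test binding pair occurs in any message-passing
#' edge set (the graph's auxiliary set or any fold allowlist), and (c) every
#' allowlisted auxiliary record satisfies the medoid-cluster rule, recomputed
#' from the stored fingerprints. An empty report is a pass.
#'
#' @param plan a [SplitPlan-class].
#' @param graph the [HeteroGraph-class] the plan will train on.
#' @return data.frame of violations with columns `type`, `detail` (0 rows if
#'   the plan is clean).
#' @export
auditLeakage <- function(plan, graph) {
  viol <- list()
  add <- function(type, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(type = type, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  it <- plan@interactions
  if (plan@mode == "drug" && nrow(it)) {
    nPart <- tapply(it$partition, it$drug, function(p) length(unique(p)))
    for (d in names(nPart)[nPart > 1]) add("drug_in_two_partitions", d)
  }
  heldOut <- if (plan@mode == "drug") {
    it[it$partition == "test", , drop = FALSE]
  } else {
    it[it$partition %in% c("validation", "test"), , drop = FALSE]
  }
  valKeysByFold <- if (plan@mode == "drug") {
    lapply(stats::setNames(nm = .foldLabels(plan)), function(f)
      .pairKey(it$drug[it$partition == f], it$target[it$partition == f]))
  } else list()
  hoKeys <- .pairKey(heldOut$drug, heldOut$target)
  mpSets <- c(list(graph_bind_mp = .pairKey(graph@bindMP$drug, graph@bindMP$target)),
              lapply(plan@mpAllowlist, function(a) .pairKey(a$drug, a$target)))
  for (nm in names(mpSets)) {
    bad <- intersect(hoKeys, mpSets[[nm]])
    for (k in bad)
      add("held_out_pair_in_mp", paste0(nm, ": ", gsub("\r", "/", k)))
  }
  ## a fold's own validation pairs must not message-pass for that fold
  for (f in names(plan@mpAllowlist)) {
    bad <- intersect(valKeysByFold[[f]], mpSets[[f]])
    for (k in bad)
      add("validation_pair_in_fold_mp", paste0(f, ": ", gsub("\r", "/", k)))
  }
  if (plan@mode == "drug" && length(plan@mpAllowlist) &&
      length(plan@auxFps) && length(plan@auxFps$bits)) {
    asg <- list(medoidFps = do.call(fingerprintSet, plan@medoidFps))
    partOf <- stats::setNames(plan@partition$partition,
                              as.character(plan@partition$cluster_id))
    for (f in names(plan@mpAllowlist)) {
      trainParts <- setdiff(.foldLabels(plan), f)
      allow <- plan@mpAllowlist[[f]]
      for (d in unique(as.character(allow$drug))) {
        fp <- plan@auxFps$bits[[d]]
        okRule <- !is.null(fp) &&
          partOf[as.character(assignExternalDrug(fp, asg))] %in% trainParts
        if (!okRule) add("allowlist_cluster_rule", paste0(f, ": ", d))
      }
    }
  }
  if (!length(viol))
    return(data.frame(type = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

setMethod("show", "SplitPlan", function(object) {
  it <- object@interactions
  cat("SplitPlan (", object@mode, " mode, seed ", object@seed, ")\n", sep = "")
  if (nrow(it)) {
    tab <- table(it$partition)
    pos <- tapply(it$label, it$partition, sum)
    for (p in names(tab)) {
      nc <- if (object@mode == "drug")
        sum(object@partition$partition == p) else NA
      cat(sprintf("  %-12s %5d interactions (%d positive%s)\n", p, tab[[p]],
                  pos[[p]],
                  if (!is.na(nc)) paste0(", ", nc, " clusters") else ""))
    }
  }
  invisible(object)
})

#' Serialize / read a split plan as JSON
#'
#' Serialization is canonical: the same plan always produces byte-identical
#' JSON.
#'
#' @param plan a [SplitPlan-class].
#' @param path file path.
#' @return `writeSplitPlan` returns `path` invisibly; `readSplitPlan` a
#'   [SplitPlan-class].
#' @export
writeSplitPlan <- function(plan, path) {
  rep <- list(
    mode = plan@mode, seed = plan@seed, nFolds = plan@nFolds,
    testFraction = plan@testFraction,
    clusters = plan@clusters, medoids = plan@medoids,
    medoidFps = plan@medoidFps,
    partition = plan@partition, interactions = plan@interactions,
    mpAllowlist = plan@mpAllowlist, auxAssignment = plan@auxAssignment,
    auxFps = plan@auxFps, allowAllAux = plan@allowAllAux,
    config = plan@config)
  json <- jsonlite::toJSON(rep, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  rep <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = TRUE)
  asDf <- function(x, cols) {
    if (!length(x)) return(data.frame())
    as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
  }
  fps <- function(x) {
    if (!length(x) || !length(x$bits)) return(list())
    list(bits = lapply(x$bits, as.integer), size = as.integer(x$size))
  }
  new("SplitPlan",
      mode = rep$mode, seed = as.integer(rep$seed),
      nFolds = as.integer(rep$nFolds), testFraction = rep$testFraction,
      clusters = asDf(rep$clusters), medoids = asDf(rep$medoids),
      medoidFps = fps(rep$medoidFps),
      partition = asDf(rep$partition), interactions = asDf(rep$interactions),
      mpAllowlist = lapply(rep$mpAllowlist %||% list(), asDf),
      auxAssignment = asDf(rep$auxAssignment), auxFps = fps(rep$auxFps),
      allowAllAux = rep$allowAllAux, config = rep$config)
}
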