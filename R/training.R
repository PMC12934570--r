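#' Training configuration
#'
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize supervision edges per gradient step (default 512; the
#'   full graph is encoded once per step, batching applies to supervision
#'   edges only).
#' @param maxEpochs fixed epoch budget (default 100); the best epoch is
#'   selected post hoc by validation AUROC.
#' @param seed single run seed governing initialization and shuffling.
#' @param useAuxMp include the auxiliary (positive-only) binding edges in
#'   message passing (default `TRUE`); the ablation toggle.
#' @param featureDropout probability of zeroing a drug node's raw input
#'   features at each training step (node-level dropout; default 0.9). After
#'   training, the `1 - featureDropout` test-time scale is folded into the
#'   drug input projection, so downstream consumers use the checkpoint as-is.
#'   A high rate forces the trunk to explain binding through graph
#'   neighborhoods rather than memorizing the drug feature vectors, which is
#'   what lets the model generalize to drugs whose chemistry was never
#'   labeled in training.
#' @param edgeDropout probability of dropping each undirected message-passing
#'   edge (both directions jointly) at each training epoch (default 0.3).
#'   Edge dropout prevents the trunk from memorizing node identities through
#'   their exact neighborhood constellations and pushes it toward
#'   neighborhood-content rules that transfer to held-out chemistry.
#'   Attention renormalizes per destination, so evaluation on the full edge
#'   set needs no rescaling.
#' @param featureNoise standard deviation of Gaussian noise added to all raw
#'   node features at each training step (default 0.1). Denoising
#'   augmentation: individual nodes stop being identifiable from minor
#'   feature idiosyncrasies, so the trunk cannot memorize pair labels and has
#'   to model the shared structure. Evaluation is noise-free.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-3, batchSize = 512L,
                        maxEpochs = 100L, seed = 1L, useAuxMp = TRUE,
                        featureDropout = 0.9, edgeDropout = 0.3,
                        featureNoise = 0.1,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(learningRate = learningRate,
                 batchSize = .assertCount(batchSize, "batchSize"),
                 maxEpochs = .assertCount(maxEpochs, "maxEpochs"),
                 seed = .assertCount(seed, "seed", min = 0L),
                 useAuxMp = isTRUE(useAuxMp),
                 featureDropout = .assertProb(featureDropout, "featureDropout"),
                 edgeDropout = .assertProb(edgeDropout, "edgeDropout"),
                 featureNoise = as.numeric(featureNoise),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "TrainConfig")
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))`. Scores of exactly 0 or 1 are
#' clamped at 1e-12 with a warning.
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @return nonnegative scalar loss.
#' @export
bceLoss <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(scores <= 0) || any(scores >= 1)) {
    warning("scores at 0/1 clamped to [1e-12, 1 - 1e-12]")
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  }
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties counting one half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC requires at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## Adam on the flattened parameter vector.
.adamInit <- function(theta) list(m = numeric(length(theta)),
                                  v = numeric(length(theta)), t = 0L)

.adamStep <- function(theta, grad, state, tc) {
  state$t <- state$t + 1L
  state$m <- tc$beta1 * state$m + (1 - tc$beta1) * grad
  state$v <- tc$beta2 * state$v + (1 - tc$beta2) * grad^2
  mhat <- state$m / (1 - tc$beta1^state$t)
  vhat <- state$v / (1 - tc$beta2^state$t)
  list(theta = theta - tc$learningRate * mhat / (sqrt(vhat) + tc$eps),
       state = state)
}

## Partition labels of the supervision sets for a run.
.runPartitions <- function(plan, fold) {
  if (plan@mode == "drug") {
    folds <- .foldLabels(plan)
    if (is.null(fold) || !fold %in% folds)
      stop("drug-mode training needs 'fold' in: ", paste(folds, collapse = ", "))
    list(train = setdiff(folds, fold), validation = fold, test = "test")
  } else {
    list(train = "train", validation = "validation", test = "test")
  }
}

## Message-passing selection for a run: the labeled bind edges are never
## eligible; the auxiliary edges obey the fold allowlist in drug mode.
.runMp <- function(plan, fold, useAuxMp) {
  if (!useAuxMp) return(list(bind_mp = FALSE))
  if (plan@mode == "drug") {
    allow <- plan@mpAllowlist[[fold]]
    list(bind_mp = if (is.null(allow)) .emptyBindFrame(label = FALSE) else allow)
  } else {
    list(bind_mp = isTRUE(plan@allowAllAux))
  }
}

.pairIdx <- function(gd, pairs) {
  list(d = unname(gd$di[pairs$drug]), t = unname(gd$ti[pairs$target]),
       y = as.numeric(pairs$label))
}

#' Train the link prediction model
#'
#' Trains with mean binary cross-entropy over the training supervision edges
#' (positives and negatives both come from the labeled set; no negative
#' sampling) and Adam. Each epoch the full graph is encoded with message
#' passing over the PPI, pocket-similarity, drug-similarity and virtual-hub
#' edges plus -- when `useAuxMp` -- the fold's auxiliary allowlist; labeled
#' binding edges never message-pass. The epoch with the best validation AUROC
#' is selected (earliest on ties). Training refuses to start if
#' [auditLeakage()] reports violations, and every epoch re-verifies that the
#' message-passing adjacency in use matches the allowlisted signature and is
#' disjoint from the labeled pairs.
#'
#' @param graph a [HeteroGraph-class].
#' @param plan a [SplitPlan-class].
#' @param fold fold label serving as validation (drug mode); ignored for
#'   random plans.
#' @param mcfg a [modelConfig()].
#' @param tcfg a [trainConfig()].
#' @return a [DTIFit-class].
#' @export
trainModel <- function(graph, plan, fold = NULL, mcfg = modelConfig(),
                       tcfg = trainConfig()) {
  audit <- auditLeakage(plan, graph)
  if (nrow(audit) > 0L)
    stop("refusing to train: leakage audit reports ", nrow(audit),
         " violation(s), first: ", audit$type[1L], " ", audit$detail[1L])
  parts <- .runPartitions(plan, fold)
  it <- plan@interactions
  trainSet <- it[it$partition %in% parts$train, , drop = FALSE]
  valSet <- it[it$partition %in% parts$validation, , drop = FALSE]
  if (!nrow(trainSet) || !nrow(valSet)) stop("empty train or validation set")
  gd <- .graphData(graph, .runMp(plan, fold, tcfg$useAuxMp))
  expectedSig <- .mpSignature(gd)
  ## supervision / message-passing separation, checked structurally:
  labeledKeys <- .pairKey(it$drug, it$target)
  mpKeys <- if (!is.null(gd$rel$bind_mp_d2t)) {
    .pairKey(names(gd$di)[gd$rel$bind_mp_d2t$src - gd$nT],
             names(gd$ti)[gd$rel$bind_mp_d2t$dst])
  } else character(0)
  if (length(intersect(labeledKeys, mpKeys)))
    stop("labeled supervision pair found in message-passing adjacency")

  model <- initModel(graph, mcfg, seed = tcfg$seed)
  theta <- unlist(model@params)
  skel <- model@params
  adam <- .adamInit(theta)
  tr <- .pairIdx(gd, trainSet)
  va <- .pairIdx(gd, valSet)
  ## epoch-end evaluation uses the dropout test-time scaling of the features
  gdEval <- gd
  gdEval$Xd <- gd$Xd * (1 - tcfg$featureDropout)
  nTrain <- length(tr$y)
  log <- vector("list", tcfg$maxEpochs)
  best <- list(auroc = -Inf, theta = theta, epoch = 0L)
  for (ep in seq_len(tcfg$maxEpochs)) {
    t0 <- proc.time()[["elapsed"]]
    gdEp <- gd
    if (tcfg$edgeDropout > 0) {
      ## drop each undirected edge jointly with its reverse direction:
      ## same-type relations store the two directions half-and-half, and the
      ## two bind_mp relations mirror each other row for row
      gdEp$rel <- list()
      mpKeep <- NULL
      for (nm in names(gd$rel)) {
        r <- gd$rel[[nm]]
        if (nm %in% c("bind_mp_d2t", "bind_mp_t2d")) {
          if (is.null(mpKeep)) mpKeep <- stats::runif(length(r$src)) >= tcfg$edgeDropout
          keep <- mpKeep
        } else {
          half <- stats::runif(length(r$src) / 2L) >= tcfg$edgeDropout
          keep <- c(half, half)
        }
        if (any(keep)) gdEp$rel[[nm]] <- .prepRel(r$src[keep], r$dst[keep], gd$n)
      }
    }
    perm <- sample.int(nTrain)
    batches <- split(perm, ceiling(seq_along(perm) / tcfg$batchSize))
    params <- utils::relist(theta, skel)
    for (bi in batches) {
      gdStep <- gdEp
      if (tcfg$featureDropout > 0) {
        keep <- stats::runif(gd$nD) >= tcfg$featureDropout
        gdStep$Xd <- gd$Xd * keep
      }
      if (tcfg$featureNoise > 0) {
        gdStep$Xt <- gd$Xt + tcfg$featureNoise *
          matrix(stats::rnorm(length(gd$Xt)), nrow(gd$Xt))
        gdStep$Xd <- gdStep$Xd + tcfg$featureNoise *
          matrix(stats::rnorm(length(gd$Xd)), nrow(gd$Xd))
      }
      fw <- .forwardTrunk(params, gdStep, mcfg)
      hd <- .headForward(params, fw$H, tr$d[bi], tr$t[bi], mcfg$leakySlope)
      grads <- .backwardFull(params, gdStep, mcfg, fw, hd, tr$d[bi], tr$t[bi],
                             tr$y[bi])
      upd <- .adamStep(theta, unlist(grads), adam, tcfg)
      theta <- upd$theta; adam <- upd$state
      params <- utils::relist(theta, skel)
    }
    fw <- .forwardTrunk(params, gdEval, mcfg)
    hdTr <- .headForward(params, fw$H, tr$d, tr$t, mcfg$leakySlope)
    hdVa <- .headForward(params, fw$H, va$d, va$t, mcfg$leakySlope)
    loss <- bceLoss(pmin(pmax(hdTr$p, 1e-12), 1 - 1e-12), tr$y)
    vAuc <- aurocScore(hdVa$p, va$y)
    sig <- .mpSignature(gd)
    log[[ep]] <- data.frame(
      epoch = ep, loss = loss, val_auroc = vAuc,
      seconds = proc.time()[["elapsed"]] - t0,
      mp_hash = sig, mp_ok = identical(sig, expectedSig) &&
        !length(intersect(labeledKeys, mpKeys)),
      stringsAsFactors = FALSE)
    if (vAuc > best$auroc) best <- list(auroc = vAuc, theta = theta, epoch = ep)
  }
  ## fold the dropout test-time feature scale into the drug projection so the
  ## checkpoints score full-feature graphs directly
  foldScale <- function(p) {
    p$proj$drug$W <- p$proj$drug$W * (1 - tcfg$featureDropout)
    p
  }
  model@params <- foldScale(utils::relist(best$theta, skel))
  new("DTIFit", model = model, epochLog = do.call(rbind, log),
      fold = fold %||% "random", bestEpoch = best$epoch,
      finalParams = foldScale(utils::relist(theta, skel)),
      trainConfig = unclass(tcfg), mpSignature = expectedSig)
}

setMethod("show", "DTIFit", function(object) {
  cat("DTIFit: fold ", object@fold, ", best epoch ", object@bestEpoch,
      " (val AUROC ", round(max(object@epochLog$val_auroc), 4), ")\n", sep = "")
  invisible(object)
})

#' Evaluate a trained model on a partition
#'
#' Re-encodes the graph under the fit's message-passing discipline and scores
#' the partition's labeled pairs. Deterministic given the fit.
#'
#' @param fit a [DTIFit-class] from [trainModel()].
#' @param graph,plan the graph and plan used for training.
#' @param partition `"test"`, `"validation"` or `"train"`.
#' @param at `"selected"` (default) scores with the best-validation-epoch
#'   parameters; `"final"` with the last epoch's (e.g. for memorization
#'   checks).
#' @return list with `auroc` and `scores` (data.frame `drug`, `target`,
#'   `label`, `score`).
#' @export
evaluateModel <- function(fit, graph, plan,
                          partition = c("test", "validation", "train"),
                          at = c("selected", "final")) {
  partition <- match.arg(partition)
  at <- match.arg(at)
  fold <- if (fit@fold == "random") NULL else fit@fold
  parts <- .runPartitions(plan, fold)
  sel <- plan@interactions$partition %in% parts[[partition]]
  pairs <- plan@interactions[sel, , drop = FALSE]
  if (!nrow(pairs)) stop("partition '", partition, "' is empty")
  gd <- .graphData(graph, .runMp(plan, fold, fit@trainConfig$useAuxMp))
  if (!identical(.mpSignature(gd), fit@mpSignature))
    stop("message-passing adjacency differs from the one used in training")
  params <- if (at == "final") fit@finalParams else fit@model@params
  fw <- .forwardTrunk(params, gd, fit@model@config)
  px <- .pairIdx(gd, pairs)
  hd <- .headForward(params, fw$H, px$d, px$t,
                     fit@model@config$leakySlope)
  list(auroc = aurocScore(hd$p, px$y),
       scores = data.frame(drug = pairs$drug, target = pairs$target,
                           label = pairs$label, score = hd$p,
                           stringsAsFactors = FALSE))
}

#' Auxiliary message-passing ablation
#'
#' Trains and evaluates the model with and without the auxiliary
#' message-passing binding edges, over the given seeds (and folds for drug
#' plans), and reports per-run AUROCs plus a mean/SD summary with one row per
#' (plan, setting).
#'
#' @param graph a [HeteroGraph-class].
#' @param plans named list of [SplitPlan-class] objects (e.g.
#'   `list(random = ..., drug = ...)`).
#' @param mcfg,tcfg model and training configurations (the `seed` and
#'   `useAuxMp` fields of `tcfg` are overridden per run).
#' @param seeds integer vector of run seeds.
#' @param folds optional subset of fold labels for drug plans (default all).
#' @return list with `runs` and `summary` data.frames.
#' @export
ablationRun <- function(graph, plans, mcfg = modelConfig(),
                        tcfg = trainConfig(), seeds = 1:4, folds = NULL) {
  if (is.null(names(plans))) stop("'plans' must be a named list")
  runs <- list()
  for (pn in names(plans)) {
    plan <- plans[[pn]]
    pf <- if (plan@mode == "drug") folds %||% .foldLabels(plan) else NA_character_
    for (seed in seeds) for (f in pf) for (aux in c(TRUE, FALSE)) {
      tc <- tcfg; tc$seed <- as.integer(seed); tc$useAuxMp <- aux
      fit <- trainModel(graph, plan, fold = if (is.na(f)) NULL else f,
                        mcfg = mcfg, tcfg = tc)
      runs[[length(runs) + 1L]] <- data.frame(
        plan = pn, aux_mp = aux, seed = seed,
        fold = if (is.na(f)) "random" else f,
        val_auroc = evaluateModel(fit, graph, plan, "validation")$auroc,
        test_auroc = evaluateModel(fit, graph, plan, "test")$auroc,
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  key <- interaction(runs$plan, runs$aux_mp, drop = TRUE)
  summary <- do.call(rbind, lapply(levels(key), function(k) {
    r <- runs[key == k, , drop = FALSE]
    data.frame(plan = r$plan[1L], aux_mp = r$aux_mp[1L], n_runs = nrow(r),
               val_auroc_mean = mean(r$val_auroc),
               val_auroc_sd = stats::sd(r$val_auroc),
               test_auroc_mean = mean(r$test_auroc),
               test_auroc_sd = stats::sd(r$test_auroc),
               stringsAsFactors = FALSE)
  }))
  list(runs = runs, summary = summary)
}
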