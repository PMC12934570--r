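#' Model configuration
#'
#' @param embedDim shared embedding dimension `d` of the trunk (default 128).
#' @param nTrunkLayers number of transformer-convolution layers (default 3).
#' @param headHidden hidden width of the link head's first layer (default
#'   `embedDim`).
#' @param leakySlope negative slope of the Leaky ReLU between head layers.
#' @param aggregation how per-edge-type message outputs are combined at a
#'   node: `"sum"` (default, preserves degree information across relation
#'   types) or `"mean"`.
#' @return list of class `ModelConfig`.
#' @export
modelConfig <- function(embedDim = 128L, nTrunkLayers = 3L,
                        headHidden = embedDim, leakySlope = 0.01,
                        aggregation = c("sum", "mean")) {
  structure(list(
    embedDim = .assertCount(embedDim, "embedDim"),
    nTrunkLayers = .assertCount(nTrunkLayers, "nTrunkLayers"),
    headHidden = .assertCount(headHidden, "headHidden"),
    leakySlope = as.numeric(leakySlope),
    aggregation = match.arg(aggregation)
  ), class = "ModelConfig")
}

.relTypes <- c("ppi", "target_sim", "drug_sim", "virtual",
               "bind_mp_d2t", "bind_mp_t2d")

## Prepare the static tensors for one training/scoring configuration:
## node indexing (targets, then drugs, then the virtual drug-hub node),
## projected raw features, and the directed edge arrays per relation.
## `mp` controls which edge sets message-pass; labeled bind edges have no
## relation here at all, so they cannot enter message passing.
.graphData <- function(graph, mp = list()) {
  ts <- graph@targetIds; ds <- graph@drugIds
  nT <- length(ts); nD <- length(ds)
  v <- nT + nD + 1L
  ti <- stats::setNames(seq_len(nT), ts)
  di <- stats::setNames(nT + seq_len(nD), ds)
  use <- function(nm, default = TRUE) mp[[nm]] %||% default

  rel <- list()
  undir <- function(ia, ib) list(src = c(ia, ib), dst = c(ib, ia))
  if (isTRUE(use("ppi")) && nrow(graph@ppi))
    rel$ppi <- undir(ti[graph@ppi$a], ti[graph@ppi$b])
  if (isTRUE(use("target_sim")) && nrow(graph@targetSim))
    rel$target_sim <- undir(ti[graph@targetSim$a], ti[graph@targetSim$b])
  if (isTRUE(use("drug_sim")) && nrow(graph@drugSim))
    rel$drug_sim <- undir(di[graph@drugSim$a], di[graph@drugSim$b])
  if (nD > 0L)
    rel$virtual <- undir(unname(di), rep(v, nD))
  mpBind <- use("bind_mp")
  mpPairs <- if (isTRUE(mpBind)) {
    graph@bindMP
  } else if (is.data.frame(mpBind)) {
    mpBind
  } else NULL
  if (!is.null(mpPairs) && nrow(mpPairs)) {
    bad <- setdiff(mpPairs$drug, ds)
    if (length(bad)) stop("message-passing pair references unknown drug")
    rel$bind_mp_d2t <- list(src = unname(di[mpPairs$drug]),
                            dst = unname(ti[mpPairs$target]))
    rel$bind_mp_t2d <- list(src = unname(ti[mpPairs$target]),
                            dst = unname(di[mpPairs$drug]))
  }
  ## precompute grouping (softmax is per destination node) and sparse
  ## edge-aggregation operators so the per-step cost is matrix products only
  rel <- lapply(rel, function(r) .prepRel(r$src, r$dst, v))
  list(nT = nT, nD = nD, n = v, rel = rel,
       targetRows = seq_len(nT), drugRows = nT + seq_len(nD), virtualRow = v,
       Xt = graph@targetFeatures, Xd = graph@drugFeatures,
       ti = ti, di = di, ids = c(ts, ds, "<virtual>"))
}

## Canonical signature of the message-passing adjacency actually in use.
.mpSignature <- function(gd) {
  rlang::hash(lapply(gd$rel[sort(names(gd$rel))],
                     function(r) list(sort(.pairKey(r$src, r$dst)))))
}

.glorot <- function(fin, fout) {
  a <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -a, a), fin, fout)
}

#' Initialize model parameters for a graph
#'
#' Per-node-type linear projections of the raw features to the embedding
#' dimension, a learned virtual-node feature vector, per-layer per-edge-type
#' transformer-convolution weights (message/query/key maps per relation and a
#' self-transform per node type), and the two-layer link head. Weights use a
#' seeded uniform Glorot scheme.
#'
#' @param graph a [HeteroGraph-class].
#' @param mcfg a [modelConfig()].
#' @param seed integer seed for initialization.
#' @return a [DTIModel-class].
#' @export
initModel <- function(graph, mcfg = modelConfig(), seed = 1L) {
  seed <- .assertCount(seed, "seed", min = 0L)
  set.seed(seed)
  d <- mcfg$embedDim
  pT <- ncol(graph@targetFeatures); pD <- ncol(graph@drugFeatures)
  trunk <- lapply(seq_len(mcfg$nTrunkLayers), function(l) {
    list(self = list(target = .glorot(d, d), drug = .glorot(d, d),
                     virtual = .glorot(d, d)),
         rel = stats::setNames(lapply(.relTypes, function(r)
           list(W2 = .glorot(d, d), W3 = .glorot(d, d), W4 = .glorot(d, d))),
           .relTypes))
  })
  params <- list(
    proj = list(target = list(W = .glorot(pT, d), b = matrix(0, 1, d)),
                drug = list(W = .glorot(pD, d), b = matrix(0, 1, d))),
    virtual = list(v = .glorot(1L, d)),
    trunk = trunk,
    head = list(W1 = .glorot(2L * d, mcfg$headHidden),
                b1 = matrix(0, 1, mcfg$headHidden),
                W2 = .glorot(mcfg$headHidden, 1L),
                b2 = matrix(0, 1, 1))
  )
  new("DTIModel", config = unclass(mcfg), params = params,
      graphHash = graphHash(graph), seed = seed)
}

setMethod("show", "DTIModel", function(object) {
  cat("DTIModel: d =", object@config$embedDim, ",",
      object@config$nTrunkLayers, "trunk layers, seed", object@seed, "\n")
  invisible(object)
})

## One relation's attention messages. Returns the aggregated message matrix
## (n x d) plus the cache needed for the backward pass.
## Edge arrays plus the destination grouping used by the per-node softmax.
.prepRel <- function(src, dst, n) {
  f <- factor(dst)
  list(src = as.integer(src), dst = as.integer(dst), gidx = as.integer(f),
       ng = nlevels(f), n = as.integer(n))
}

.relForward <- function(H, r, p, d) {
  Q <- H %*% p$W3; K <- H %*% p$W4; M <- H %*% p$W2
  s <- .edgeDot(Q, K, r$dst, r$src) / sqrt(d)
  e <- exp(s - .groupMax(s, r$gidx, r$ng)[r$gidx])
  alpha <- e / .groupSum(e, r$gidx, r$ng)[r$gidx]
  msg <- .scatterAddGather(M, r$src, r$dst, alpha, r$n)
  list(msg = msg, alpha = alpha, Q = Q, K = K, M = M)
}

.relBackward <- function(G, H, r, p, cache, d) {
  dalpha <- .edgeDot(G, cache$M, r$dst, r$src)
  dM <- .scatterAddGather(G, r$dst, r$src, cache$alpha, r$n)
  s1 <- .groupSum(cache$alpha * dalpha, r$gidx, r$ng)
  sc <- cache$alpha * (dalpha - s1[r$gidx]) / sqrt(d)
  dQ <- .scatterAddGather(cache$K, r$src, r$dst, sc, r$n)
  dK <- .scatterAddGather(cache$Q, r$dst, r$src, sc, r$n)
  list(dW2 = crossprod(H, dM), dW3 = crossprod(H, dQ), dW4 = crossprod(H, dK),
       dH = dM %*% t(p$W2) + dQ %*% t(p$W3) + dK %*% t(p$W4))
}

## Full trunk forward pass; caches every intermediate needed by backward.
.forwardTrunk <- function(params, gd, cfg) {
  d <- cfg$embedDim; L <- cfg$nTrunkLayers
  H0 <- rbind(
    gd$Xt %*% params$proj$target$W +
      matrix(params$proj$target$b, gd$nT, d, byrow = TRUE),
    gd$Xd %*% params$proj$drug$W +
      matrix(params$proj$drug$b, gd$nD, d, byrow = TRUE),
    params$virtual$v
  )
  if (any(!is.finite(H0))) stop("non-finite node features")
  ## mean aggregation divides a node's summed messages by the number of
  ## active relations that can reach its node type
  relCnt <- rep(1, gd$n)
  if (cfg$aggregation == "mean") {
    cnt <- rep(0, gd$n)
    for (r in gd$rel) cnt[unique(r$dst)] <- cnt[unique(r$dst)] + 1
    relCnt <- pmax(cnt, 1)
  }
  Hin <- vector("list", L); preact <- vector("list", L)
  caches <- vector("list", L)
  H <- H0
  for (l in seq_len(L)) {
    Hin[[l]] <- H
    lp <- params$trunk[[l]]
    out <- matrix(0, gd$n, d)
    out[gd$targetRows, ] <- H[gd$targetRows, , drop = FALSE] %*% lp$self$target
    out[gd$drugRows, ] <- H[gd$drugRows, , drop = FALSE] %*% lp$self$drug
    out[gd$virtualRow, ] <- H[gd$virtualRow, , drop = FALSE] %*% lp$self$virtual
    cl <- list()
    for (nm in names(gd$rel)) {
      fw <- .relForward(H, gd$rel[[nm]], lp$rel[[nm]], d)
      out <- out + fw$msg / relCnt
      cl[[nm]] <- fw[c("alpha", "Q", "K", "M")]
    }
    caches[[l]] <- cl
    preact[[l]] <- out
    H <- if (l < L) .relu(out) else out
  }
  list(H = H, H0 = H0, Hin = Hin, preact = preact, caches = caches,
       relCnt = relCnt)
}

.headForward <- function(params, H, di, ti, slope) {
  z <- cbind(H[di, , drop = FALSE], H[ti, , drop = FALSE])
  a1 <- z %*% params$head$W1 +
    matrix(params$head$b1, nrow(z), ncol(params$head$W1), byrow = TRUE)
  l1 <- .lrelu(a1, slope)
  a2 <- l1 %*% params$head$W2 + as.vector(params$head$b2)
  p <- .sigmoid(as.vector(a2))
  list(z = z, a1 = a1, l1 = l1, p = p)
}

## Analytic gradients of mean BCE loss over the supplied pairs with respect
## to every parameter. Verified against finite differences in the tests.
.backwardFull <- function(params, gd, cfg, fw, hd, di, ti, y) {
  d <- cfg$embedDim; L <- cfg$nTrunkLayers
  nb <- length(y)
  grads <- rapply(params, function(x) x * 0, how = "replace")
  da2 <- matrix((hd$p - y) / nb, ncol = 1)
  grads$head$W2 <- crossprod(hd$l1, da2)
  grads$head$b2 <- matrix(sum(da2), 1, 1)
  dl1 <- da2 %*% t(params$head$W2)
  da1 <- dl1 * ((hd$a1 > 0) + cfg$leakySlope * (hd$a1 <= 0))
  grads$head$W1 <- crossprod(hd$z, da1)
  grads$head$b1 <- matrix(colSums(da1), 1)
  dz <- da1 %*% t(params$head$W1)
  dH <- matrix(0, gd$n, d)
  agg <- rowsum(rbind(dz[, seq_len(d), drop = FALSE],
                      dz[, d + seq_len(d), drop = FALSE]), c(di, ti))
  dH[as.integer(rownames(agg)), ] <- agg
  for (l in rev(seq_len(L))) {
    G <- if (l < L) dH * (fw$preact[[l]] > 0) else dH
    lp <- params$trunk[[l]]
    H <- fw$Hin[[l]]
    dHin <- matrix(0, gd$n, d)
    for (tp in c("target", "drug", "virtual")) {
      rows <- switch(tp, target = gd$targetRows, drug = gd$drugRows,
                     virtual = gd$virtualRow)
      grads$trunk[[l]]$self[[tp]] <-
        crossprod(H[rows, , drop = FALSE], G[rows, , drop = FALSE])
      dHin[rows, ] <- dHin[rows, , drop = FALSE] +
        G[rows, , drop = FALSE] %*% t(lp$self[[tp]])
    }
    for (nm in names(gd$rel)) {
      Gm <- G / fw$relCnt
      bw <- .relBackward(Gm, H, gd$rel[[nm]], lp$rel[[nm]],
                         fw$caches[[l]][[nm]], d)
      grads$trunk[[l]]$rel[[nm]]$W2 <- bw$dW2
      grads$trunk[[l]]$rel[[nm]]$W3 <- bw$dW3
      grads$trunk[[l]]$rel[[nm]]$W4 <- bw$dW4
      dHin <- dHin + bw$dH
    }
    dH <- dHin
  }
  grads$proj$target$W <- crossprod(gd$Xt, dH[gd$targetRows, , drop = FALSE])
  grads$proj$target$b <- matrix(colSums(dH[gd$targetRows, , drop = FALSE]), 1)
  grads$proj$drug$W <- crossprod(gd$Xd, dH[gd$drugRows, , drop = FALSE])
  grads$proj$drug$b <- matrix(colSums(dH[gd$drugRows, , drop = FALSE]), 1)
  grads$virtual$v <- dH[gd$virtualRow, , drop = FALSE]
  grads
}

#' Transformer-convolution message passing over one edge type
#'
#' Implements `x_i' = W1 x_i + sum_{j in N(i)} alpha_ij W2 x_j` with
#' `alpha_ij = softmax_j((W3 x_i)^T (W4 x_j) / sqrt(d))`, the softmax taken
#' per destination node over its in-neighbors, `d` the output dimension. A
#' node with no in-neighbors gets `W1 x_i` (empty sum).
#'
#' @param x node feature matrix (nodes in rows).
#' @param edges 2-column integer matrix of directed edges (src, dst), or a
#'   zero-row matrix.
#' @param params list with matrices `W1`, `W2`, `W3`, `W4`.
#' @return updated node feature matrix, with per-edge attention weights in
#'   `attr(, "alpha")`.
#' @export
transformerConv <- function(x, edges, params) {
  if (any(!is.finite(x))) stop("non-finite node features")
  out <- x %*% params$W1
  if (is.null(edges) || nrow(edges) == 0L)
    return(structure(out, alpha = numeric(0)))
  if (any(edges < 1L) || any(edges > nrow(x))) stop("edge endpoint out of range")
  r <- .prepRel(edges[, 1L], edges[, 2L], nrow(x))
  fw <- .relForward(x, r, params, ncol(params$W4))
  structure(out + fw$msg, alpha = fw$alpha)
}

#' Encode a graph into node embeddings
#'
#' Runs the trunk: per-node-type projection of raw features to the embedding
#' dimension, then `nTrunkLayers` rounds of per-edge-type transformer
#' convolution (each undirected edge expanded to two directed messages;
#' auxiliary binding edges yield the two typed relations drug-to-target and
#' target-to-drug), per-type outputs aggregated by the configured rule, with
#' ReLU between (not after) layers. A virtual hub node is connected to every
#' drug node by a dedicated edge type and updated like any other node; its
#' row is the last of the returned matrix.
#'
#' @param graph a [HeteroGraph-class].
#' @param model a [DTIModel-class].
#' @param mp list controlling the message-passing edge sets: logical `ppi`,
#'   `target_sim`, `drug_sim` (default `TRUE`) and `bind_mp` (`TRUE` for all
#'   auxiliary edges, `FALSE` for none, or a data.frame allowlist with
#'   columns `drug`, `target`). Labeled binding edges never message-pass.
#' @return matrix `(n_targets + n_drugs + 1) x d` of embeddings, row names
#'   the node ids plus `"<virtual>"`; the adjacency signature is in
#'   `attr(, "mpSignature")`.
#' @export
encodeGraph <- function(graph, model, mp = list()) {
  gd <- .graphData(graph, mp)
  fw <- .forwardTrunk(model@params, gd, model@config)
  structure(fw$H, dimnames = list(gd$ids, NULL), mpSignature = .mpSignature(gd))
}

#' Score a drug-target pair from node embeddings
#'
#' Concatenates the drug and target embeddings (in that fixed order) and
#' applies the two-layer feedforward head: affine, Leaky ReLU, affine,
#' sigmoid.
#'
#' @param drugEmbedding,targetEmbedding numeric vectors of length `d`, or
#'   matrices with matching row counts.
#' @param model a [DTIModel-class] (its head parameters are used).
#' @return interaction score(s) strictly inside (0, 1).
#' @export
linkScore <- function(drugEmbedding, targetEmbedding, model) {
  de <- rbind(drugEmbedding); te <- rbind(targetEmbedding)
  if (ncol(de) != model@config$embedDim || ncol(te) != model@config$embedDim)
    stop("embedding length must equal the model embedding dimension")
  if (nrow(de) != nrow(te)) stop("drug/target embedding row mismatch")
  z <- cbind(de, te)
  a1 <- z %*% model@params$head$W1 +
    matrix(model@params$head$b1, nrow(z), ncol(model@params$head$W1), byrow = TRUE)
  a2 <- .lrelu(a1, model@config$leakySlope) %*% model@params$head$W2 +
    as.vector(model@params$head$b2)
  .sigmoid(as.vector(a2))
}
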