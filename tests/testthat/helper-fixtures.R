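## Fixtures are built in code; nothing is read from disk.

## Tiny bundle for fast unit tests.
tinyBundle <- function(seed = 3L, nLabeledInteractions = 24L,
                       targetsPerFamily = 4L, auxFraction = 0.5, ...) {
  generateBundle(simConfig(seed = seed, nTargetFamilies = 2L,
                           targetsPerFamily = targetsPerFamily,
                           nChemotypes = 2L, drugsPerChemotype = 4L,
                           nLabeledInteractions = nLabeledInteractions,
                           auxFraction = auxFraction, ...))
}

tinyGraph <- function(seed = 3L, ...) {
  b <- tinyBundle(seed, ...)
  assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
}

## Hand-constructed toy inputs exercising each assembly filter exactly once:
## 3 targets (t1 and t2 share an identical pocket residue), 2 drugs with
## identical embeddings, 1 passing PPI, 2 labeled bindings, 1 auxiliary.
toyAssemblyInputs <- function() {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); e3 <- c(0, 0, 1)
  residues <- data.frame(
    target_id = c("t1", "t1", "t2", "t3"),
    pocket_id = c("p1", "p2", "p1", "p1"),
    residue_id = c("r1", "r1", "r1", "r1"),
    stringsAsFactors = FALSE)
  residues$embedding <- rbind(e1, e2, e1, e3)
  drugs <- data.frame(drug_id = c("d1", "d2"), smiles = c("C", "CC"),
                      stringsAsFactors = FALSE)
  drugs$embedding <- rbind(c(1, 1), c(1, 1))
  ppi <- data.frame(target_a = c("t1", "t1"), target_b = c("t2", "t3"),
                    neighborhood = 0L, fusion = 0L, cooccurrence = 0L,
                    experimental = c(750L, 600L), database = c(0L, 600L),
                    textmining = 0L, combined = c(800L, 800L),
                    stringsAsFactors = FALSE)
  bind <- data.frame(drug = c("d1", "d2"), target = c("t1", "t3"),
                     label = c(1L, 0L), stringsAsFactors = FALSE)
  bindMP <- data.frame(drug = "d1", target = "t2", stringsAsFactors = FALSE)
  list(residues = residues, drugs = drugs, ppi = ppi, bind = bind,
       bindMP = bindMP)
}

## Brute-force oracles -------------------------------------------------------

## O(n^2) all-pairs similarity edge oracle using only cosineSimilarity.
bruteSimilarityEdges <- function(ids, mat, threshold) {
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && cosineSimilarity(mat[i, ], mat[j, ]) > threshold)
      out[[length(out) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(a = character(0), b = character(0)))
  do.call(rbind, out)
}

## Triple-nested-loop target similarity oracle (pockets x pockets x residues).
bruteTargetSimilarity <- function(ta, tb, residues) {
  ra <- residues[residues$target_id == ta, ]
  rb <- residues[residues$target_id == tb, ]
  best <- -Inf
  for (pa in unique(ra$pocket_id)) for (pb in unique(rb$pocket_id)) {
    ea <- ra$embedding[ra$pocket_id == pa, , drop = FALSE]
    eb <- rb$embedding[rb$pocket_id == pb, , drop = FALSE]
    for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
      best <- max(best, cosineSimilarity(ea[i, ], eb[j, ]))
    }
  }
  best
}

## Independent union-find for component membership.
unionFindComponents <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

## Dense masked-attention oracle for one relation of transformer convolution.
denseAttentionOracle <- function(x, edges, params) {
  n <- nrow(x)
  d <- ncol(params$W4)
  S <- matrix(-Inf, n, n)  # S[i, j]: score of source j for destination i
  for (k in seq_len(nrow(edges))) {
    j <- edges[k, 1]; i <- edges[k, 2]
    S[i, j] <- sum((x[i, ] %*% params$W3) * (x[j, ] %*% params$W4)) / sqrt(d)
  }
  out <- x %*% params$W1
  for (i in seq_len(n)) {
    if (all(!is.finite(S[i, ]))) next
    a <- exp(S[i, ] - max(S[i, ], na.rm = TRUE))
    a[!is.finite(S[i, ])] <- 0
    a <- a / sum(a)
    for (j in which(a > 0)) out[i, ] <- out[i, ] + a[j] * (x[j, ] %*% params$W2)
  }
  out
}

## Pairwise-concordance AUROC oracle with explicit tie handling.
pairwiseAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## Random params for a single transformer convolution relation.
randomConvParams <- function(dIn, dOut, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(dIn * dOut), dIn), W2 = matrix(rnorm(dIn * dOut), dIn),
       W3 = matrix(rnorm(dIn * dOut), dIn), W4 = matrix(rnorm(dIn * dOut), dIn))
}
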