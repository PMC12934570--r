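#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return cosine similarity in \[-1, 1\].
#' @examples
#' cosineSimilarity(c(1, 0), c(1, 1)) # 1/sqrt(2)
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero-norm vector")
  sum(a * b) / (na * nb)
}

## Validate a residue embedding table: data.frame with character columns
## target_id, pocket_id, residue_id and a numeric matrix column `embedding`.
.checkResidueTable <- function(residues) {
  need <- c("target_id", "pocket_id", "residue_id", "embedding")
  if (!all(need %in% names(residues)))
    stop("residue table must have columns: ", paste(need, collapse = ", "))
  emb <- residues$embedding
  if (!is.matrix(emb)) stop("residue table 'embedding' must be a matrix column")
  key <- paste(residues$target_id, residues$pocket_id, residues$residue_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (target, pocket, residue) triple in residue table")
  if (any(rowSums(emb^2) == 0)) stop("zero-norm residue embedding present")
  invisible(residues)
}

#' Pocket-level similarity between two targets
#'
#' The similarity of two targets is the maximum, over all pockets of each
#' target and all residue pairs across the two pockets, of the cosine
#' similarity between residue embeddings (a nested max over pockets and
#' residues, which equals the max over all residue pairs of the two targets).
#'
#' @param ta,tb target ids present in `residues`.
#' @param residues residue embedding table: data.frame with columns
#'   `target_id`, `pocket_id`, `residue_id` and a numeric matrix column
#'   `embedding` (fixed dimension across rows, nonzero norms).
#' @return maximal residue-pair cosine similarity.
#' @export
targetSimilarity <- function(ta, tb, residues) {
  .checkResidueTable(residues)
  ia <- residues$target_id == ta
  ib <- residues$target_id == tb
  if (!any(ia)) stop("target '", ta, "' has no pockets in the residue table")
  if (!any(ib)) stop("target '", tb, "' has no pockets in the residue table")
  A <- .normalizeRows(residues$embedding[ia, , drop = FALSE], "residue")
  B <- .normalizeRows(residues$embedding[ib, , drop = FALSE], "residue")
  max(A %*% t(B))
}

## All-pairs target similarity matrix via blocked matrix products over
## unit-normalized residue embeddings (all-pairs residue comparison is the
## scaling bottleneck, hence the chunking).
.targetSimMatrix <- function(residues, ids, chunkSize = 2048L) {
  keep <- residues$target_id %in% ids
  tid <- residues$target_id[keep]
  R <- .normalizeRows(residues$embedding[keep, , drop = FALSE], "residue")
  grp <- split(seq_along(tid), factor(tid, levels = ids))
  n <- length(ids)
  S <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    rows <- grp[[i]]
    if (!length(rows)) stop("target '", ids[i], "' has no residues")
    ## residue-level similarities of target i against everything, chunked
    cm <- rep(-Inf, length(tid))
    for (st in seq(1L, length(tid), by = chunkSize)) {
      en <- min(st + chunkSize - 1L, length(tid))
      blk <- R[rows, , drop = FALSE] %*% t(R[st:en, , drop = FALSE])
      cm[st:en] <- do.call(pmax, c(asplit(blk, 1), list(-Inf)))
    }
    S[i, ] <- vapply(grp, function(ix) max(cm[ix]), numeric(1))
  }
  ## symmetrize exactly (floating-point max order can differ per direction)
  pmax(S, t(S))
}

#' Build similarity edges by thresholded all-pairs comparison
#'
#' Drug mode compares embedding vectors by cosine similarity; target mode
#' compares targets by [targetSimilarity()] over a residue embedding table.
#' An edge is present iff similarity strictly exceeds `threshold`.
#' Comparison is chunked block matrix multiplication over unit-normalized
#' embeddings.
#'
#' @param ids ordered character vector of node ids.
#' @param x for `mode = "drug"`, a numeric matrix with one embedding row per
#'   id; for `mode = "target"`, a residue embedding table.
#' @param threshold similarity threshold in (0, 1); strict inequality.
#' @param mode `"drug"` or `"target"`.
#' @param chunkSize rows per block in the all-pairs scan.
#' @return data.frame of unordered edges (`a`, `b`) with `a < b`.
#' @export
buildSimilarityEdges <- function(ids, x, threshold,
                                 mode = c("drug", "target"),
                                 chunkSize = 2048L) {
  mode <- match.arg(mode)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("similarity threshold must lie strictly inside (0, 1)")
  }
  if (anyDuplicated(ids)) stop("duplicated ids")
  n <- length(ids)
  if (n < 2L) return(.emptyEdgeFrame())
  if (mode == "drug") {
    if (!is.matrix(x) || nrow(x) != n) stop("embedding matrix must have one row per id")
    Xn <- .normalizeRows(x, "drug")
    ai <- integer(0); bi <- integer(0)
    for (st in seq(1L, n, by = chunkSize)) {
      en <- min(st + chunkSize - 1L, n)
      S <- Xn[st:en, , drop = FALSE] %*% t(Xn)
      hit <- which(S > threshold, arr.ind = TRUE)
      gi <- hit[, 1L] + st - 1L
      gj <- hit[, 2L]
      keep <- gi < gj
      ai <- c(ai, gi[keep]); bi <- c(bi, gj[keep])
    }
    ord <- order(ai, bi)
    return(data.frame(a = ids[ai][ord], b = ids[bi][ord], stringsAsFactors = FALSE))
  }
  .checkResidueTable(x)
  S <- .targetSimMatrix(x, ids, chunkSize = chunkSize)
  hit <- which(S > threshold & upper.tri(S), arr.ind = TRUE)
  ord <- order(hit[, 1L], hit[, 2L])
  data.frame(a = ids[hit[ord, 1L]], b = ids[hit[ord, 2L]], stringsAsFactors = FALSE)
}

#' Graph assembly configuration
#'
#' Thresholds for the similarity and interaction edge filters. Similarity
#' thresholds are strict ("greater than"); the integer confidence-score
#' thresholds are inclusive ("at least").
#'
#' @param targetSimThreshold pocket-similarity threshold (default 0.95).
#' @param drugSimThreshold drug-similarity threshold (default 0.8).
#' @param ppiCombinedMin minimum combined PPI confidence score (default 700).
#' @param ppiEvidenceMin minimum score required on at least one accepted
#'   evidence channel (default 700).
#' @param evidenceChannels accepted evidence channels (default experimental
#'   and database).
#' @param chunkSize block size for all-pairs similarity scans.
#' @return list of class `GraphConfig`.
#' @export
graphConfig <- function(targetSimThreshold = 0.95, drugSimThreshold = 0.8,
                        ppiCombinedMin = 700L, ppiEvidenceMin = 700L,
                        evidenceChannels = c("experimental", "database"),
                        chunkSize = 2048L) {
  for (v in c(targetSimThreshold, drugSimThreshold)) {
    if (v <= 0 || v >= 1) stop("similarity thresholds must lie in (0, 1)")
  }
  for (v in c(ppiCombinedMin, ppiEvidenceMin)) {
    if (v < 0 || v > 1000) stop("PPI score thresholds must lie in [0, 1000]")
  }
  structure(list(targetSimThreshold = targetSimThreshold,
                 drugSimThreshold = drugSimThreshold,
                 ppiCombinedMin = as.integer(ppiCombinedMin),
                 ppiEvidenceMin = as.integer(ppiEvidenceMin),
                 evidenceChannels = evidenceChannels,
                 chunkSize = as.integer(chunkSize)),
            class = "GraphConfig")
}

.ppiChannels <- c("neighborhood", "fusion", "cooccurrence", "experimental",
                  "database", "textmining")

#' Filter protein-protein interaction records by confidence scores
#'
#' Keeps a record iff its combined score is at least `ppiCombinedMin` AND at
#' least one accepted evidence channel (by default experimental or database)
#' scores at least `ppiEvidenceMin`. Unordered pairs are deduplicated,
#' self-pairs dropped, and, when `targets` is given, records with endpoints
#' outside the target node set are removed.
#'
#' @param records data.frame with columns `target_a`, `target_b`, the
#'   evidence channels (`neighborhood`, `fusion`, `cooccurrence`,
#'   `experimental`, `database`, `textmining`; missing channels are treated
#'   as 0) and `combined`, scores integer 0-1000.
#' @param cfg a [graphConfig()].
#' @param targets optional character vector restricting endpoints.
#' @return data.frame of unordered edges (`a`, `b`).
#' @export
filterPPI <- function(records, cfg = graphConfig(), targets = NULL) {
  if (!nrow(records)) return(.emptyEdgeFrame())
  if (!all(c("target_a", "target_b", "combined") %in% names(records)))
    stop("PPI records need columns target_a, target_b, combined")
  chans <- intersect(cfg$evidenceChannels, names(records))
  scoreCols <- intersect(c(.ppiChannels, "combined"), names(records))
  for (cc in scoreCols) {
    v <- records[[cc]]
    bad <- which(!is.finite(v) | v < 0 | v > 1000)
    if (length(bad)) {
      stop("malformed PPI score in column '", cc, "' at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  ev <- if (length(chans)) {
    Reduce(`|`, lapply(chans, function(cc) records[[cc]] >= cfg$ppiEvidenceMin))
  } else rep(FALSE, nrow(records))
  keep <- records$combined >= cfg$ppiCombinedMin & ev &
    records$target_a != records$target_b
  if (!is.null(targets)) {
    keep <- keep & records$target_a %in% targets & records$target_b %in% targets
  }
  e <- .canonPairs(as.character(records$target_a[keep]),
                   as.character(records$target_b[keep]))
  e[order(e$a, e$b), , drop = FALSE] -> e
  rownames(e) <- NULL
  e
}
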