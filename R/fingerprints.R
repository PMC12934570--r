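#' Fingerprint set
#'
#' A collection of binary substructure fingerprints represented as sets of
#' on-bit positions (0-based, within `[0, size)`), keyed by drug id.
#'
#' @param bits named list of integer vectors of on-bit positions.
#' @param size fingerprint length in bits.
#' @return object of class `FingerprintSet`.
#' @export
fingerprintSet <- function(bits, size) {
  size <- .assertCount(size, "size")
  if (is.null(names(bits)) || anyDuplicated(names(bits)))
    stop("fingerprints must be uniquely named by drug id")
  bits <- lapply(bits, function(b) {
    b <- sort(unique(as.integer(b)))
    if (length(b) && (min(b) < 0L || max(b) >= size))
      stop("bit position outside [0, size)")
    b
  })
  structure(list(bits = bits, size = size), class = "FingerprintSet")
}

#' @export
print.FingerprintSet <- function(x, ...) {
  cat("FingerprintSet:", length(x$bits), "fingerprints of", x$size, "bits\n")
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 0 (with a warning) when both
#' bit sets are empty.
#'
#' @param a,b integer vectors of on-bit positions.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

## Pairwise Tanimoto similarity matrix via a dense 0/1 bit matrix.
.tanimotoMatrix <- function(fps, fps2 = NULL) {
  toMat <- function(f) {
    m <- matrix(0L, length(f$bits), f$size,
                dimnames = list(names(f$bits), NULL))
    for (i in seq_along(f$bits)) m[i, f$bits[[i]] + 1L] <- 1L
    m
  }
  A <- toMat(fps)
  B <- if (is.null(fps2)) A else toMat(fps2)
  inter <- A %*% t(B)
  ca <- rowSums(A); cb <- rowSums(B)
  un <- outer(ca, cb, `+`) - inter
  out <- ifelse(un == 0, 0, inter / un)
  other <- if (is.null(fps2)) fps else fps2
  dimnames(out) <- list(names(fps$bits), names(other$bits))
  out
}

#' Substructure fingerprints from SMILES strings
#'
#' Delegates to the OpenBabel FP2 path-based substructure fingerprint via the
#' ChemmineOB package when it is installed. Synthetic pipelines use the
#' planted fingerprints emitted by [generateBundle()] instead.
#'
#' @param smiles character vector of SMILES, named by drug id.
#' @return a [fingerprintSet()] (1024 bits for FP2).
#' @export
fingerprintsFromSmiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("fingerprintsFromSmiles requires the ChemmineOB package")
  if (is.null(names(smiles))) stop("SMILES vector must be named by drug id")
  bits <- lapply(smiles, function(s) {
    fp <- ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", s, identity), "FP2")
    which(as.numeric(fp) != 0) - 1L
  })
  fingerprintSet(bits, 1024L)
}
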