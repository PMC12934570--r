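`%||%` <- function(a, b) if (is.null(a)) b else a

.sigmoid <- function(x) 1 / (1 + exp(-x))

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

## Row-wise L2 normalization; errors on zero rows because downstream cosine
## similarity is undefined there.
.normalizeRows <- function(x, what = "embedding") {
  n <- sqrt(rowSums(x^2))
  if (any(n == 0) || any(!is.finite(n))) {
    stop("zero-norm or non-finite ", what, " vector at row(s): ",
         paste(utils::head(which(n == 0 | !is.finite(n)), 5L), collapse = ", "))
  }
  x / n
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min)
  }
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single value in [0, 1]")
  }
  as.numeric(x)
}

## Canonical unordered pair frame: a < b lexicographically, deduplicated.
.canonPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste0(a, "\r", b)) & a != b
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

## sample() without the scalar-x surprise: always samples from the vector.
.sampleFrom <- function(x, k) x[sample.int(length(x), k)]

.pairKey <- function(x, y) {
  if (!length(x)) return(character(0))
  paste0(x, "\r", y)
}

.emptyEdgeFrame <- function() {
  data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
}

.emptyBindFrame <- function(label = TRUE) {
  d <- data.frame(drug = character(0), target = character(0),
                  stringsAsFactors = FALSE)
  if (label) d$label <- integer(0)
  d
}
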