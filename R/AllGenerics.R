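#' @rdname HeteroGraph-accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname HeteroGraph-accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname HeteroGraph-accessors
#' @export
setGeneric("nodeFeatures", function(x, type) standardGeneric("nodeFeatures"))

#' @rdname HeteroGraph-accessors
#' @export
setGeneric("edgeTable", function(x, type) standardGeneric("edgeTable"))

#' @rdname graphStats
#' @export
setGeneric("graphStats", function(x) standardGeneric("graphStats"))

#' @rdname largestComponent
#' @export
setGeneric("largestComponent", function(x) standardGeneric("largestComponent"))

#' @rdname graphHash
#' @export
setGeneric("graphHash", function(x) standardGeneric("graphHash"))

#' Accessors for HeteroGraph objects
#'
#' @param x a [HeteroGraph-class].
#' @param type for `nodeFeatures`, one of `"target"`, `"drug"`; for
#'   `edgeTable`, one of `"ppi"`, `"target_sim"`, `"drug_sim"`, `"bind"`,
#'   `"bind_mp"`.
#' @return `targetIds`/`drugIds` return character vectors; `nodeFeatures` a
#'   matrix; `edgeTable` a data.frame.
#' @name HeteroGraph-accessors
NULL
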