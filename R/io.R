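## Tab-separated table IO. Embedding vectors travel either as a single
## comma-joined column named `embedding`, or as a plain-text sidecar matrix
## (TSV, no header) aligned row-by-row with the main table.

.parseEmbedding <- function(tab, path, embeddingFile) {
  if (!is.null(embeddingFile)) {
    m <- as.matrix(data.table::fread(embeddingFile, header = FALSE, sep = "\t"))
    dimnames(m) <- NULL
    if (nrow(m) != nrow(tab))
      stop("sidecar embedding matrix has ", nrow(m), " rows but the table has ",
           nrow(tab))
    return(m)
  }
  if (!"embedding" %in% names(tab))
    stop("no 'embedding' column in ", path, " and no sidecar matrix given")
  rows <- strsplit(tab$embedding, ",", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("embedding dimension differs across rows in ", path)
  matrix(as.numeric(unlist(rows)), nrow(tab), lens[1L], byrow = TRUE)
}

.joinEmbedding <- function(m, digits = 8) {
  apply(m, 1L, function(r) paste(format(r, digits = digits, trim = TRUE,
                                        scientific = FALSE), collapse = ","))
}

#' Read and write the delimited input tables
#'
#' All tables are tab-separated with a header row. Embedding vectors are a
#' single comma-joined column named `embedding`, or, when `embeddingFile` is
#' given, a sidecar plain-text matrix (TSV, no header) aligned with the table
#' rows.
#'
#' @param path TSV file path.
#' @param embeddingFile optional sidecar matrix path.
#' @return `readResidueTable` returns a residue embedding table (data.frame
#'   with matrix column `embedding`); `readDrugTable` a drug table;
#'   `readPPITable` a PPI record frame; `readBindingTable` a binding record
#'   frame (`drug`, `target`, `label`, `source`).
#' @name table-io
#' @export
readResidueTable <- function(path, embeddingFile = NULL) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(character = 1:3)))
  need <- c("target_id", "pocket_id", "residue_id")
  if (!all(need %in% names(tab)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  emb <- .parseEmbedding(tab, path, embeddingFile)
  out <- tab[need]
  out$embedding <- emb
  .checkResidueTable(out)
}

#' @rdname table-io
#' @export
readDrugTable <- function(path, embeddingFile = NULL) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!all(c("drug_id", "smiles") %in% names(tab)))
    stop(path, " must have columns drug_id, smiles")
  emb <- .parseEmbedding(tab, path, embeddingFile)
  out <- data.frame(drug_id = as.character(tab$drug_id),
                    smiles = as.character(tab$smiles),
                    stringsAsFactors = FALSE)
  out$embedding <- emb
  if (anyDuplicated(out$drug_id)) stop("duplicated drug_id in ", path)
  out
}

#' @rdname table-io
#' @export
readPPITable <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!all(c("target_a", "target_b", "combined") %in% names(tab)))
    stop(path, " must have columns target_a, target_b, combined")
  tab$target_a <- as.character(tab$target_a)
  tab$target_b <- as.character(tab$target_b)
  tab
}

#' @rdname table-io
#' @param source binding source tag: `"prediction_set"` (labeled) or
#'   `"message_passing_set"` (positive-only auxiliary).
#' @export
readBindingTable <- function(path, source = c("prediction_set",
                                              "message_passing_set")) {
  source <- match.arg(source)
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!all(c("drug", "target") %in% names(tab)))
    stop(path, " must have columns drug, target")
  lab <- if ("label" %in% names(tab)) as.integer(tab$label) else
    rep(1L, nrow(tab))
  if (source == "message_passing_set" && any(lab != 1L))
    stop("auxiliary (message-passing) binding table must be positive-only: ", path)
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1 in ", path)
  data.frame(drug = as.character(tab$drug), target = as.character(tab$target),
             label = lab, source = source, stringsAsFactors = FALSE)
}

#' @rdname table-io
#' @param residues,drugs tables as returned by the readers.
#' @export
writeResidueTable <- function(residues, path, embeddingFile = NULL) {
  out <- residues[c("target_id", "pocket_id", "residue_id")]
  if (is.null(embeddingFile)) {
    out$embedding <- .joinEmbedding(residues$embedding)
  } else {
    data.table::fwrite(as.data.frame(residues$embedding), embeddingFile,
                       sep = "\t", col.names = FALSE)
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname table-io
#' @export
writeDrugTable <- function(drugs, path, embeddingFile = NULL) {
  out <- drugs[c("drug_id", "smiles")]
  if (is.null(embeddingFile)) {
    out$embedding <- .joinEmbedding(drugs$embedding)
  } else {
    data.table::fwrite(as.data.frame(drugs$embedding), embeddingFile,
                       sep = "\t", col.names = FALSE)
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read a synthetic bundle as a directory of TSV tables
#'
#' Emits the five input tables (`residues.tsv`, `drugs.tsv`, `ppi.tsv`,
#' `bind.tsv`, `bind_mp.tsv`), the planted fingerprints
#' (`fingerprints.json`), and the ground truth (`truth.json`).
#'
#' @param bundle a [generateBundle()] result.
#' @param dir output directory (created if missing).
#' @return `writeBundle` returns `dir` invisibly; `readBundle` a list with
#'   the five tables and the fingerprints (ground truth is reloaded when
#'   present).
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeResidueTable(bundle$residues, file.path(dir, "residues.tsv"))
  writeDrugTable(bundle$drugs, file.path(dir, "drugs.tsv"))
  data.table::fwrite(bundle$ppi, file.path(dir, "ppi.tsv"), sep = "\t")
  data.table::fwrite(bundle$bind, file.path(dir, "bind.tsv"), sep = "\t")
  data.table::fwrite(bundle$bindMP, file.path(dir, "bind_mp.tsv"), sep = "\t")
  jsonlite::write_json(list(bits = bundle$fingerprints$bits,
                            size = bundle$fingerprints$size),
                       file.path(dir, "fingerprints.json"))
  truth <- bundle$truth
  truth$compatibility <- unclass(truth$compatibility) * 1L
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  fp <- jsonlite::fromJSON(file.path(dir, "fingerprints.json"))
  out <- list(
    residues = readResidueTable(file.path(dir, "residues.tsv")),
    drugs = readDrugTable(file.path(dir, "drugs.tsv")),
    ppi = readPPITable(file.path(dir, "ppi.tsv")),
    bind = readBindingTable(file.path(dir, "bind.tsv"), "prediction_set"),
    bindMP = readBindingTable(file.path(dir, "bind_mp.tsv"),
                              "message_passing_set"),
    fingerprints = fingerprintSet(lapply(fp$bits, as.integer),
                                  as.integer(fp$size))
  )
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::fromJSON(tj)
    tr$compatibility <- matrix(as.logical(tr$compatibility),
                               nrow = nrow(as.matrix(tr$compatibility)))
    tr$family <- unlist(tr$family); tr$chemotype <- unlist(tr$chemotype)
    out$truth <- tr
  }
  class(out) <- "SyntheticBundle"
  out
}

#' Write / read a graph bundle directory
#'
#' A graph bundle holds the node tables, one edge list per edge type, the
#' feature matrices, and a `stats.tsv` with the graph property summary.
#'
#' @param g a [HeteroGraph-class].
#' @param dir directory path.
#' @return `writeGraphBundle` returns `dir` invisibly; `readGraphBundle` a
#'   [HeteroGraph-class].
#' @export
writeGraphBundle <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  w(data.frame(target_id = g@targetIds), "targets.tsv")
  w(data.frame(drug_id = g@drugIds), "drugs.tsv")
  w(g@ppi, "edges_ppi.tsv"); w(g@targetSim, "edges_target_sim.tsv")
  w(g@drugSim, "edges_drug_sim.tsv"); w(g@bind, "edges_bind.tsv")
  w(g@bindMP, "edges_bind_mp.tsv")
  w(data.frame(id = g@targetIds,
               embedding = .joinEmbedding(g@targetFeatures)),
    "target_features.tsv")
  w(data.frame(id = g@drugIds, embedding = .joinEmbedding(g@drugFeatures)),
    "drug_features.tsv")
  w(graphStats(g), "stats.tsv")
  jsonlite::write_json(list(insertedDrugs = g@metadata$insertedDrugs %||%
                              character(0)),
                       file.path(dir, "metadata.json"))
  invisible(dir)
}

#' @rdname writeGraphBundle
#' @export
readGraphBundle <- function(dir) {
  r <- function(f, classes = NULL)
    as.data.frame(data.table::fread(file.path(dir, f), sep = "\t",
                                    header = TRUE, colClasses = classes))
  feat <- function(f) {
    tab <- r(f)
    m <- .parseEmbedding(tab, f, NULL)
    rownames(m) <- as.character(tab$id)
    m
  }
  chr2 <- function(d) { d[] <- lapply(d, as.character); d }
  bind <- r("edges_bind.tsv")
  bind$drug <- as.character(bind$drug); bind$target <- as.character(bind$target)
  bind$label <- as.integer(bind$label)
  md <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  new("HeteroGraph",
      targetIds = as.character(r("targets.tsv")$target_id),
      drugIds = as.character(r("drugs.tsv")$drug_id),
      targetFeatures = feat("target_features.tsv"),
      drugFeatures = feat("drug_features.tsv"),
      ppi = chr2(r("edges_ppi.tsv")), targetSim = chr2(r("edges_target_sim.tsv")),
      drugSim = chr2(r("edges_drug_sim.tsv")),
      bind = bind, bindMP = chr2(r("edges_bind_mp.tsv")),
      metadata = list(insertedDrugs = unlist(md$insertedDrugs) %||% character(0)))
}
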