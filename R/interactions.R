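#' Compound--target interaction edges
#'
#' Interaction edges are data frames with columns `compound_id`,
#' `target_id`, `kind` (`"protein"` or `"gene"`) and `confidence`
#' (STITCH-style score in \[0, 1\] for protein edges, `NA` for gene edges).
#' Gene interactions carry their evidence as row multiplicity: the same
#' (compound, gene) pair appearing twice means two evidence occurrences, so
#' duplicate rows are preserved by the reader.
#'
#' @name interaction_edges
NULL

#' Read compound--target interactions from delimited text
#'
#' Protein tables need columns `compound_id` (or `compound`), `target_id`
#' (or `protein_id`/`protein`/`target`) and `confidence`; gene tables need
#' the compound and target columns only (`gene_id`/`gene` accepted), one
#' row per evidence occurrence.
#'
#' @param path TSV/CSV path (delimiter sniffed from the header).
#' @param kind `"protein"` or `"gene"`.
#' @return an interaction-edge data frame, see [interaction_edges].
#' @export
read_interactions <- function(path, kind = c("protein", "gene")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_usage("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(raw[[nm]])) return(raw[[nm]])
    stop_usage("missing column (one of: ", paste(c(...), collapse = ", "),
               ") in ", path)
  }
  compound <- as.character(pick("compound_id", "compound"))
  target <- as.character(
    if (kind == "protein") pick("target_id", "protein_id", "protein", "target")
    else pick("target_id", "gene_id", "gene", "target"))
  conf <- rep(NA_real_, nrow(raw))
  if (kind == "protein") {
    conf <- suppressWarnings(as.numeric(pick("confidence", "score")))
    bad <- which(is.na(conf) | conf < 0 | conf > 1)
    if (length(bad))
      stop_usage("confidence outside [0, 1] (or non-numeric) at data row ", bad[1])
  }
  new_interaction_edges(compound, target, kind, conf)
}

new_interaction_edges <- function(compound_id, target_id, kind, confidence = NA_real_) {
  data.frame(compound_id = as.character(compound_id),
             target_id = as.character(target_id),
             kind = kind,
             confidence = as.numeric(confidence),
             stringsAsFactors = FALSE)
}

#' Target sets
#'
#' A `target_set` is a set of unique protein or gene identifiers with the
#' filter parameters that produced it kept as provenance.
#'
#' @param ids character vector (deduplicated, order of first appearance).
#' @param kind `"protein"` or `"gene"`.
#' @param provenance named list describing how the set was derived.
#' @return a `target_set` object.
#' @export
target_set <- function(ids, kind, provenance = list()) {
  structure(list(ids = unique(as.character(ids)), kind = kind,
                 provenance = provenance),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("Target set: ", length(x$ids), " ", x$kind, "(s)\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ",
        paste(names(x$provenance), unlist(x$provenance), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$ids)

#' Filter protein interactions by confidence score
#'
#' Retains the distinct proteins of edges whose confidence score reaches
#' `min_confidence`. The comparison is inclusive (`>=`) by default; set
#' `inclusive = FALSE` for a strict `>` cut.
#'
#' @param edges protein-kind [interaction_edges].
#' @param min_confidence confidence threshold in \[0, 1\] (default 0.5, the
#'   STITCH "medium confidence" level).
#' @param inclusive keep edges at exactly the threshold (default TRUE).
#' @return a [target_set] of proteins.
#' @export
filter_by_confidence <- function(edges, min_confidence = 0.5, inclusive = TRUE) {
  if (!all(edges$kind == "protein"))
    stop_usage("filter_by_confidence applies to protein edges only")
  keep <- if (inclusive) edges$confidence >= min_confidence
          else edges$confidence > min_confidence
  target_set(edges$target_id[keep], "protein",
             list(min_confidence = min_confidence, inclusive = inclusive))
}

#' Distinct targets of an edge list
#'
#' @param edges [interaction_edges] of one kind.
#' @return a [target_set] of the unique target identifiers.
#' @export
distinct_targets <- function(edges) {
  kind <- if (nrow(edges)) edges$kind[1] else "protein"
  target_set(edges$target_id, kind, list(filter = "none"))
}

#' Rank genes by interaction-occurrence frequency
#'
#' The frequency of a gene is the number of compound--gene interaction rows
#' pointing at it (duplicate rows are evidence, so they count). Sorted by
#' descending frequency, ties broken by gene identifier.
#'
#' @param edges gene-kind [interaction_edges].
#' @return data frame `gene_id`, `frequency`, sorted.
#' @export
gene_frequency <- function(edges) {
  if (nrow(edges) && !all(edges$kind == "gene"))
    stop_usage("gene_frequency applies to gene edges only")
  if (!nrow(edges))
    return(data.frame(gene_id = character(0), frequency = integer(0)))
  tab <- table(edges$target_id)
  out <- data.frame(gene_id = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Threshold a gene frequency table
#'
#' `mode = "mean"` retains genes whose frequency is at least the mean
#' frequency of the table (the data-driven reading of a
#' "remove below-average genes" rule); `mode = "fixed"` retains
#' `frequency >= fixed_value`. Both comparisons are inclusive.
#'
#' @param table frequency table from [gene_frequency()].
#' @param mode `"mean"` or `"fixed"`.
#' @param fixed_value threshold for `mode = "fixed"`.
#' @return a [target_set] of genes.
#' @export
frequency_threshold_filter <- function(table, mode = c("mean", "fixed"),
                                       fixed_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(fixed_value))
    stop_usage("mode = 'fixed' requires fixed_value")
  if (mode == "mean" && nrow(table) == 0)
    stop_usage("mode = 'mean' needs a non-empty frequency table")
  thr <- if (mode == "mean") mean(table$frequency) else fixed_value
  keep <- table$frequency >= thr
  target_set(table$gene_id[keep], "gene",
             list(mode = mode, threshold = thr))
}
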