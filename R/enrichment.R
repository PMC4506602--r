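#' Annotation collections
#'
#' Named target sets (pathways or disease classes) over a background
#' universe. Every set is intersected with the universe on construction;
#' empty sets are rejected.
#'
#' @param sets named list of character vectors (set name -> member ids).
#' @param universe background identifier universe; defaults to the union of
#'   all sets.
#' @param kind `"pathway"` or `"disease_class"`.
#' @return an `annotation_collection`.
#' @export
annotation_collection <- function(sets, universe = NULL,
                                  kind = c("pathway", "disease_class")) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets))))
    stop_usage("annotation sets need unique non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_usage("empty universe")
  sets <- lapply(sets, intersect, universe)
  if (any(lengths(sets) == 0))
    stop_usage("annotation set(s) with no member in the universe: ",
               paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(sets = sets, universe = universe, kind = kind),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("Annotation collection (", x$kind, "): ", length(x$sets),
      " set(s), universe of ", length(x$universe), "\n", sep = "")
  invisible(x)
}

#' Read annotation sets from a GMT file
#'
#' GMT lines are `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @param universe optional background universe (one id per line file path
#'   or character vector); default is the union of all sets.
#' @param kind passed to [annotation_collection()].
#' @return an [annotation_collection()].
#' @export
read_gmt <- function(path, universe = NULL, kind = "pathway") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop_usage("malformed GMT line ", bad[1], " (needs >= 3 fields)")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (is.character(universe) && length(universe) == 1 && file.exists(universe))
    universe <- readLines(universe)
  annotation_collection(sets, universe, kind)
}

#' Write annotation sets to a GMT file
#'
#' @param annotations an [annotation_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$sets), function(nm)
    paste(c(nm, "na", annotations$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Benjamini--Hochberg adjustment
#'
#' Standard BH step-up with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop_usage("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Fisher's exact over-representation test per annotation set
#'
#' For each set, computes the upper-tail hypergeometric probability of
#' observing at least the actual overlap when `|targets|` identifiers are
#' drawn from the universe with `set_size` of them marked. Target ids
#' outside the universe are dropped with a message (annotation coverage is
#' never complete). An empty effective target set yields p = 1 everywhere.
#'
#' @param targets a [target_set] or character vector of identifiers.
#' @param annotations an [annotation_collection()].
#' @return data frame `set_name`, `overlap`, `set_size`, `p_value`,
#'   `q_value` (BH-adjusted), one row per set, in the collection's order.
#' @export
fisher_enrichment <- function(targets, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  ids <- if (inherits(targets, "target_set")) targets$ids else unique(as.character(targets))
  if (!length(annotations$universe)) stop_usage("empty universe")
  inside <- intersect(ids, annotations$universe)
  dropped <- length(ids) - length(inside)
  if (dropped > 0)
    message(dropped, " target id(s) outside the universe dropped")
  N <- length(annotations$universe)
  n <- length(inside)
  overlap <- vapply(annotations$sets, function(s) length(intersect(inside, s)), integer(1))
  set_size <- lengths(annotations$sets)
  p <- ifelse(n == 0, 1,
              stats::phyper(overlap - 1L, set_size, N - set_size, n, lower.tail = FALSE))
  data.frame(set_name = names(annotations$sets),
             overlap = overlap, set_size = as.integer(set_size),
             p_value = pmin(p, 1), q_value = bh_adjust(pmin(p, 1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an undirected network from an edge-list file
#'
#' Two or three whitespace/tab-separated columns (`node  node  [weight]`),
#' no header required (a header line whose third field is non-numeric is
#' detected and skipped). Self-loops and duplicate edges are removed.
#'
#' @param path edge list path.
#' @return an undirected [igraph][igraph::graph_from_data_frame] graph.
#' @export
read_network <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", fill = TRUE)
  if (ncol(raw) < 2) stop_usage("edge list needs at least two columns")
  first <- raw[1, ]
  if (ncol(raw) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]]))) &&
      nzchar(as.character(first[[3]])))
    raw <- raw[-1, , drop = FALSE]
  g <- igraph::graph_from_data_frame(raw[, 1:2], directed = FALSE)
  if (ncol(raw) >= 3) igraph::E(g)$weight <- as.numeric(raw[[3]])
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Random walk with restart over a protein network
#'
#' Iterates `s <- (1 - r) * W s + r * e` where `W` is the column-normalized
#' adjacency matrix (edge weights honoured) and `e` the uniform restart
#' distribution over the seed nodes, until the L1 change falls below `tol`
#' or `max_iter` iterations. Mass leaving degree-zero nodes is redirected to
#' the restart distribution, so the scores sum to exactly 1 at every
#' iteration. Components holding no seed receive (near-)zero score.
#'
#' @param network undirected igraph graph.
#' @param seeds a [target_set] or character vector; seeds not on the
#'   network are ignored, but at least one must be present.
#' @param restart restart probability in (0, 1); 0.3 by default.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return named numeric vector of stationary scores over all nodes.
#' @export
propagate <- function(network, seeds, restart = 0.3, tol = 1e-10,
                      max_iter = 10000L) {
  if (!(restart > 0 && restart < 1)) stop_usage("restart must lie in (0, 1)")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  ids <- if (inherits(seeds, "target_set")) seeds$ids else as.character(seeds)
  seed_idx <- match(intersect(ids, nodes), nodes)
  if (!length(seed_idx)) stop_usage("no seed is present on the network")
  n <- length(nodes)
  A <- igraph::as_adjacency_matrix(network, attr =
         if ("weight" %in% igraph::edge_attr_names(network)) "weight" else NULL,
         sparse = TRUE)
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  W <- A %*% Matrix::Diagonal(n, x = ifelse(dangling, 0, 1 / pmax(deg, 1e-300)))
  e <- numeric(n); e[seed_idx] <- 1 / length(seed_idx)
  s <- e
  for (i in seq_len(max_iter)) {
    lost <- sum(s[dangling])              # mass on degree-0 nodes restarts
    s_new <- as.numeric((1 - restart) * (W %*% s)) +
      ((1 - restart) * lost + restart) * e
    if (sum(abs(s_new - s)) < tol) { s <- s_new; break }
    s <- s_new
  }
  stats::setNames(s, nodes)
}

#' Deviation-from-mean pathway proximity (XD-style) scores
#'
#' The raw score of an annotation set is the mean propagation score over
#' its members present on the network; the XD score is the raw score minus
#' the mean raw score across all scored sets, so a positive value marks a
#' set closer to the seeds than the average set. Sets with no member on the
#' network get `NA` and are excluded from the mean; scored XD values always
#' average to zero.
#'
#' @param node_scores named score vector from [propagate()].
#' @param annotations an [annotation_collection()].
#' @return data frame `set_name`, `raw_score`, `xd_score`.
#' @export
xd_scores <- function(node_scores, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  raw <- vapply(annotations$sets, function(s) {
    on_net <- intersect(s, names(node_scores))
    if (!length(on_net)) return(NA_real_)
    mean(node_scores[on_net])
  }, numeric(1))
  if (all(is.na(raw))) stop_usage("no annotation set intersects the network")
  xd <- raw - mean(raw, na.rm = TRUE)
  data.frame(set_name = names(annotations$sets), raw_score = raw,
             xd_score = xd, row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter enrichment rows by XD score and significance
#'
#' Retains rows meeting every supplied criterion: `xd_score >= xd_min`,
#' `p_value <= p_max`, `q_value <= q_max` (all inclusive). Row order is
#' preserved. At least one criterion must be supplied.
#'
#' @param rows data frame with any of `xd_score`, `p_value`, `q_value`.
#' @param xd_min,p_max,q_max optional thresholds.
#' @return the retained subset of `rows`.
#' @export
threshold_filter <- function(rows, xd_min = NULL, p_max = NULL, q_max = NULL) {
  if (is.null(xd_min) && is.null(p_max) && is.null(q_max))
    stop_usage("supply at least one of xd_min, p_max, q_max")
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(xd_min)) keep <- keep & !is.na(rows$xd_score) & rows$xd_score >= xd_min
  if (!is.null(p_max)) keep <- keep & rows$p_value <= p_max
  if (!is.null(q_max)) keep <- keep & rows$q_value <= q_max
  rows[keep, , drop = FALSE]
}

#' Barplot of enrichment overlap fractions
#'
#' A simple base-graphics overview of `overlap / set_size` for the top
#' rows of an enrichment table, ordered by p-value.
#'
#' @param rows data frame from [fisher_enrichment()].
#' @param top number of sets to show (default 15).
#' @return invisibly, the plotted subset.
#' @export
plot_enrichment <- function(rows, top = 15) {
  rows <- rows[order(rows$p_value), , drop = FALSE]
  rows <- utils::head(rows, top)
  frac <- rows$overlap / rows$set_size
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(frac), names.arg = rev(rows$set_name), horiz = TRUE,
                    las = 1, cex.names = 0.7, xlab = "overlap / set size",
                    main = "Enrichment overlap")
  invisible(rows)
}
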