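fixture <- function(name) {
  path <- system.file("extdata", name, package = "netpharm")
  if (!nzchar(path)) stop("missing fixture: ", name)
  path
}

read_table2 <- function() read_compound_table(fixture("table2_compounds.tsv"), "tcmsp")

## build a small in-memory catalog and round-trip it through the TSV reader
make_catalog <- function(df, source_tag = "src") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_compound_table(path, source_tag)
}

## protein edge list with one distinct protein per confidence value
new_edges3 <- function(confidences) {
  data.frame(compound_id = paste0("c", seq_along(confidences)),
             target_id = paste0("P", seq_along(confidences)),
             kind = "protein", confidence = confidences,
             stringsAsFactors = FALSE)
}

## exhaustive hypergeometric upper-tail oracle: probability that a uniform
## draw of n ids from a universe of N (K of them marked) overlaps the marked
## set by at least k — computed by enumerating every draw
enum_upper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

## direct dense linear-system solution of random walk with restart on a
## graph with no degree-zero nodes: s = r (I - (1 - r) W)^{-1} e
rwr_dense_solve <- function(graph, seeds, restart) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  W <- sweep(A, 2, colSums(A), "/")
  n <- nrow(W)
  e <- as.numeric(igraph::V(graph)$name %in% seeds)
  e <- e / sum(e)
  s <- solve(diag(n) - (1 - restart) * W, restart * e)
  stats::setNames(s, igraph::V(graph)$name)
}
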