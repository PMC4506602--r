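#' Compound catalogs
#'
#' A compound catalog is a data frame with one row per compound record and
#' class `compound_catalog`. Columns:
#' \describe{
#'   \item{compound_id}{canonical key ([normalize_compound_id()] of the name,
#'     or the structure key when supplied)}
#'   \item{name}{free-text compound name}
#'   \item{herbs}{semicolon-joined herb codes (a record may belong to
#'     several herbs)}
#'   \item{sources}{semicolon-joined source tags (database / literature
#'     labels)}
#'   \item{mw, alogp, hbd, hba, ob, dl}{molecular descriptors: molecular
#'     weight (Da), octanol-water partition coefficient, hydrogen-bond donor
#'     and acceptor counts, oral bioavailability (percent), drug-likeness
#'     index in \[0, 1\]. Missing descriptors are `NA`, never silently zero.}
#'   \item{flags}{free-form annotation tags}
#' }
#' Before deduplication a catalog may hold several records per compound_id
#' (one per source, or one per herb after [expand_herbs()]); afterwards the
#' compound_id is unique.
#'
#' @name compound_catalog
NULL

.catalog_cols <- c("compound_id", "name", "herbs", "sources",
                   "mw", "alogp", "hbd", "hba", "ob", "dl", "flags")
.descriptor_cols <- c("mw", "alogp", "hbd", "hba", "ob", "dl")

new_compound_catalog <- function(df) {
  if (nrow(df) == 0 || ncol(df) == 0)
    df <- data.frame(compound_id = character(0), stringsAsFactors = FALSE)
  for (col in .catalog_cols)
    if (is.null(df[[col]]))
      df[[col]] <- rep(if (col %in% .descriptor_cols) NA_real_ else NA_character_,
                       nrow(df))
  df <- df[, .catalog_cols, drop = FALSE]
  for (col in .descriptor_cols) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  class(df) <- c("compound_catalog", "data.frame")
  df
}

#' Validate structural invariants of a compound catalog
#'
#' Checks mw > 0, integer non-negative hbd/hba, dl within \[0, 1\] and
#' non-empty herb membership for every record. `NA` descriptors are allowed.
#'
#' @param catalog a [compound_catalog].
#' @return the catalog, invisibly; errors describe the first violation.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "compound_catalog"))
  bad <- which(!is.na(catalog$mw) & catalog$mw <= 0)
  if (length(bad)) stop_usage("mw must be > 0 (row ", bad[1], ")")
  for (col in c("hbd", "hba")) {
    v <- catalog[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad)) stop_usage(col, " must be a non-negative integer (row ", bad[1], ")")
  }
  bad <- which(!is.na(catalog$dl) & (catalog$dl < 0 | catalog$dl > 1))
  if (length(bad)) stop_usage("dl must lie in [0, 1] (row ", bad[1], ")")
  bad <- which(!nzchar(catalog$herbs) | is.na(catalog$herbs))
  if (length(bad)) stop_usage("every record needs at least one herb (row ", bad[1], ")")
  invisible(catalog)
}

#' Read a compound table from delimited text
#'
#' Expects a header with at least `name` and `herb` (or `herbs`) columns;
#' descriptor columns (`mw`, `alogp`, `hbd`, `hba`, `ob`, `dl`) and
#' `compound_id`, `source`, `flags` are optional. Multiple herbs may share
#' one cell, separated by commas, semicolons or slashes. Empty descriptor
#' cells become `NA`; non-numeric descriptor text is an error naming the row.
#'
#' @param path path to a TSV/CSV file (delimiter sniffed from the header).
#' @param source_tag label recorded in `sources` for every row; rows with
#'   their own `source` column keep it, and `source_tag` is appended.
#' @return a [compound_catalog] with one record per input row, row order
#'   preserved.
#' @export
read_compound_table <- function(path, source_tag = NULL) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  if (is.null(raw[["herb"]]) && !is.null(raw[["herbs"]])) raw$herb <- raw$herbs
  for (col in c("name", "herb"))
    if (is.null(raw[[col]])) stop_usage("missing mandatory column '", col, "' in ", path)

  n <- nrow(raw)
  parse_num <- function(col) {
    v <- raw[[col]]
    if (is.null(v)) return(rep(NA_real_, n))
    v <- trimws(v)
    v[!nzchar(v) | v %in% c("NA", ".")] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop_usage("non-numeric value '", v[bad[1]], "' in column '", col,
                 "' at data row ", bad[1])
    out
  }

  sources <- raw[["source"]] %||% rep("", n)
  if (!is.null(source_tag))
    sources <- ifelse(nzchar(sources), paste(sources, source_tag, sep = ";"), source_tag)
  herbs <- join_multi(split_multi(raw$herb))

  id <- raw[["compound_id"]]
  norm <- normalize_compound_id(raw$name)
  id <- if (is.null(id)) norm else ifelse(nzchar(trimws(id)), trimws(id), norm)

  cat <- new_compound_catalog(data.frame(
    compound_id = id, name = raw$name, herbs = herbs, sources = sources,
    mw = parse_num("mw"), alogp = parse_num("alogp"),
    hbd = parse_num("hbd"), hba = parse_num("hba"),
    ob = parse_num("ob"), dl = parse_num("dl"),
    flags = raw[["flags"]] %||% rep("", n),
    stringsAsFactors = FALSE))
  validate_catalog(cat)
}

#' Expand multi-herb records to one record per herb
#'
#' A compound listed under two herbs becomes two herb-level records that
#' share the compound_id; this is the representation summary tables and
#' per-herb screening counts operate on (a dual-herb compound counts once
#' per herb).
#'
#' @param catalog a [compound_catalog].
#' @return a [compound_catalog] with single-herb records.
#' @export
expand_herbs <- function(catalog) {
  stopifnot(inherits(catalog, "compound_catalog"))
  herbs <- split_multi(catalog$herbs)
  idx <- rep(seq_len(nrow(catalog)), lengths(herbs))
  out <- catalog[idx, , drop = FALSE]
  out$herbs <- unlist(herbs, use.names = FALSE)
  new_compound_catalog(out)
}

#' Merge compound catalogs from several sources
#'
#' Concatenates the inputs (pre-dedup record count equals the sum of input
#' sizes) without deduplicating; pass the result to [deduplicate()]. When
#' two sources disagree on a descriptor of the same compound beyond
#' `tolerance` (relative difference), a warning lists both values; the value
#' retained downstream is the one from the earliest input (input order is
#' source priority).
#'
#' @param catalogs list of [compound_catalog] objects, highest-priority
#'   first.
#' @param tolerance relative difference above which descriptor disagreement
#'   between sources is reported.
#' @return the concatenated [compound_catalog].
#' @export
merge_sources <- function(catalogs, tolerance = 1e-6) {
  if (length(catalogs) == 0) return(new_compound_catalog(data.frame()))
  stopifnot(all(vapply(catalogs, inherits, logical(1), "compound_catalog")))
  merged <- new_compound_catalog(do.call(rbind, lapply(catalogs, as.data.frame)))
  ## report cross-source descriptor conflicts
  by_id <- split(seq_len(nrow(merged)), merged$compound_id)
  for (rows in by_id[lengths(by_id) > 1L]) {
    for (col in .descriptor_cols) {
      v <- merged[[col]][rows]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      rng <- range(v)
      scale <- max(abs(rng), .Machine$double.eps)
      if (diff(rng) / scale > tolerance)
        warning("descriptor conflict for '", merged$compound_id[rows[1]],
                "' on ", col, ": ", rng[1], " vs ", rng[2],
                " (keeping highest-priority source)", call. = FALSE)
    }
  }
  merged
}

#' Deduplicate a compound catalog by canonical identifier
#'
#' Collapses records sharing a compound_id into one: herbs and sources are
#' unioned, flags concatenated (unique tags), and each descriptor takes its
#' first non-missing value in record order (record order encodes source
#' priority, see [merge_sources()]). Idempotent.
#'
#' @param catalog a [compound_catalog].
#' @return a [compound_catalog] with unique compound_id, first-seen order.
#' @export
deduplicate <- function(catalog) {
  stopifnot(inherits(catalog, "compound_catalog"))
  if (nrow(catalog) == 0) return(catalog)
  first <- !duplicated(catalog$compound_id)
  out <- catalog[first, , drop = FALSE]
  groups <- split(seq_len(nrow(catalog)), match(catalog$compound_id, out$compound_id))
  union_col <- function(rows, col)
    paste(unique(unlist(split_multi(catalog[[col]][rows]))), collapse = ";")
  out$herbs <- vapply(groups, union_col, character(1), col = "herbs")
  out$sources <- vapply(groups, union_col, character(1), col = "sources")
  out$flags <- vapply(groups, union_col, character(1), col = "flags")
  for (col in .descriptor_cols) {
    out[[col]] <- vapply(groups, function(rows) {
      v <- catalog[[col]][rows]
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  new_compound_catalog(out)
}

#' Count catalog records by herb or by source
#'
#' Grouping by herb counts herb memberships: a dual-herb compound
#' contributes one count to each of its herbs, so counts sum to the total
#' herb-membership, not the record count.
#'
#' @param catalog a [compound_catalog].
#' @param axis `"herb"` or `"source"`.
#' @return data frame with columns `group` and `n`, sorted by group.
#' @export
count_by <- function(catalog, axis = c("herb", "source")) {
  stopifnot(inherits(catalog, "compound_catalog"))
  axis <- match.arg(axis)
  col <- if (axis == "herb") "herbs" else "sources"
  if (nrow(catalog) == 0)
    return(data.frame(group = character(0), n = integer(0)))
  toks <- unlist(split_multi(catalog[[col]]), use.names = FALSE)
  tab <- table(toks)
  data.frame(group = names(tab), n = as.integer(tab), row.names = NULL)
}

#' Write a catalog as canonical TSV
#'
#' One row per record; `herbs` and `sources` stay semicolon-joined. The
#' file round-trips through [read_compound_table()].
#'
#' @param catalog a [compound_catalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(catalog, path) {
  df <- as.data.frame(catalog)
  names(df)[names(df) == "herbs"] <- "herb"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.compound_catalog <- function(x, ...) {
  cat("Compound catalog: ", nrow(x), " record(s), ",
      length(unique(x$compound_id)), " unique compound(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
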