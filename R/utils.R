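#' Normalize a compound name into a canonical identifier
#'
#' Compound identity across catalogs is name-based: the name is case-folded
#' and runs of whitespace/punctuation are collapsed to single spaces, so
#' `"Beta-Sitosterol"` and `"beta sitosterol"` map to the same key. An
#' explicit structure key (e.g. an InChIKey), when present on a record,
#' overrides the name-derived key.
#'
#' @param name character vector of compound names.
#' @return character vector of normalized identifiers.
#' @examples
#' normalize_compound_id(c("Beta-Sitosterol", "beta  sitosterol"))
#' @export
normalize_compound_id <- function(name) {
  x <- tolower(trimws(as.character(name)))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

## round half away from zero, the convention used in the printed summary tables
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## split a multi-valued cell ("a;b" or "a,b" or "a/b") into trimmed tokens
split_multi <- function(x) {
  out <- strsplit(as.character(x), "[;,/]")
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_multi <- function(x) vapply(x, paste, character(1), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) stop(..., call. = FALSE)
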