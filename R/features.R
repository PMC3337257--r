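#' Tokenize and stem free text
#'
#' Lowercases, splits on non-alphanumeric boundaries, drops stop words
#' ([mesh_stopwords()]) and Porter-stems the remaining tokens. Token order is
#' preserved — the exact-matching baseline and literal containment tests rely
#' on contiguity of the stemmed sequence.
#'
#' @param text Character scalar (empty string allowed).
#' @return Character vector of stems (possibly empty), in text order.
#' @examples
#' tokenize_and_stem("the diseases of the heart")
#' @export
tokenize_and_stem <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% mesh_stopwords())]
  if (length(toks) == 0L) return(character(0))
  porter_stem(toks)
}

#' Publication-year features
#'
#' Encodes a publication year as a fixed-size block of binary features:
#' `year:afterY` for every year Y from `range_start + 1` up to the publication
#' year, and `year:beforeY` for every Y from the following year up to
#' `range_end - 1`. The two range endpoints are excluded from feature
#' generation, so the block always contains exactly
#' `range_end - range_start - 1` features — 59 under the default 1950–2010
#' range — regardless of the publication year. Years outside the open range
#' are clamped to its ends (with a warning), so early/late documents still get
#' a full, constant-size year block.
#'
#' @param pub_year Integer publication year.
#' @param range_start,range_end Closed bounds of the configured year range
#'   (defaults 1950 and 2010).
#' @return Character vector of `year:` features of constant length.
#' @examples
#' length(year_features(1990))  # 59
#' @export
year_features <- function(pub_year, range_start = 1950, range_end = 2010) {
  stopifnot(range_end - range_start >= 2)
  y <- as.integer(pub_year)
  lo <- range_start + 1L
  hi <- range_end - 1L
  if (y < lo || y > hi) {
    meshent_warn("publication year %d outside (%d, %d); clamped", y,
                 range_start, range_end)
    y <- min(max(y, lo), hi)
  }
  c(sprintf("year:after%d", lo:y),
    if (y < hi) sprintf("year:before%d", (y + 1L):hi))
}

normalize_journal <- function(journal) {
  j <- tolower(trimws(journal))
  gsub("[[:space:]]+", " ", j)
}

#' Build the labeled feature set of a document
#'
#' Produces the binary feature set of one literature record: stemmed title
#' tokens (`title:`), stemmed abstract tokens (`abstract:`), the normalized
#' journal name (`journal:`), and the constant-size publication-year block
#' (`year:`, see [year_features()]). Each feature carries its namespace label,
#' so the same token in title and abstract yields two distinct features. The
#' `use` argument restricts which namespaces are emitted, supporting feature
#' ablation experiments.
#'
#' @param doc A [document()].
#' @param use Character subset of `c("title", "abstract", "journal", "year")`.
#' @param year_range Length-2 integer vector, the configured year range.
#' @return Sorted character vector of unique namespaced feature strings.
#' @export
build_feature_set <- function(doc,
                              use = c("title", "abstract", "journal", "year"),
                              year_range = c(1950L, 2010L)) {
  use <- match.arg(use, c("title", "abstract", "journal", "year"),
                   several.ok = TRUE)
  feats <- character(0)
  if ("title" %in% use && nzchar(doc$title)) {
    feats <- c(feats, paste0("title:", tokenize_and_stem(doc$title)))
  }
  if ("abstract" %in% use && nzchar(doc$abstract)) {
    feats <- c(feats, paste0("abstract:", tokenize_and_stem(doc$abstract)))
  }
  if ("journal" %in% use && nzchar(doc$journal)) {
    feats <- c(feats, paste0("journal:", normalize_journal(doc$journal)))
  }
  if ("year" %in% use) {
    feats <- c(feats, year_features(doc$year, year_range[1], year_range[2]))
  }
  sort(unique(feats))
}

#' Serialize a feature set
#'
#' Writes one feature string per line, sorted, for golden-file comparisons.
#'
#' @param features Character vector of namespaced features.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, path) {
  writeLines(sort(unique(features)), path, useBytes = TRUE)
  invisible(path)
}
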