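#' Literature records and corpora
#'
#' A `document` is one literature record: identifier, title, abstract (may be
#' empty), journal name, 4-digit publication year and a set of gold MeSH
#' annotations (term ids; may be empty for unlabeled test documents). A
#' `corpus` is an ordered collection of documents plus an inverted
#' `term_index` mapping each term id to the ids of the documents annotated
#' with it.
#'
#' @param doc_id Unique document identifier.
#' @param title Title string (required, non-empty).
#' @param abstract Abstract string (may be empty).
#' @param journal Journal or forum name.
#' @param year Integer 4-digit publication year.
#' @param annotations Character vector of gold MeSH term ids.
#' @return `document()` returns an object of class `"document"`.
#' @export
document <- function(doc_id, title, abstract = "", journal = "", year,
                     annotations = character()) {
  year <- suppressWarnings(as.integer(year))
  if (is.na(year) || year < 1000L || year > 9999L) {
    meshent_stop("document '%s': year must be a 4-digit integer", doc_id)
  }
  structure(
    list(doc_id = as.character(doc_id),
         title = as.character(title),
         abstract = as.character(abstract %||% ""),
         journal = as.character(journal %||% ""),
         year = year,
         annotations = sort(unique(as.character(annotations)))),
    class = "document"
  )
}

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document %s (%d, %s): \"%s\" [%d annotations]>\n",
              x$doc_id, x$year, x$journal, x$title, length(x$annotations)))
  invisible(x)
}

build_term_index <- function(documents) {
  idx <- list()
  for (d in documents) {
    for (term in d$annotations) {
      idx[[term]] <- c(idx[[term]], d$doc_id)
    }
  }
  lapply(idx, sort)
}

#' @rdname document
#' @param documents List of [document()] objects with unique ids.
#' @return `corpus()` returns an object of class `"corpus"` with elements
#'   `documents` (named list by doc id, in input order) and `term_index`.
#' @export
corpus <- function(documents) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    meshent_stop("duplicate document id '%s'", ids[duplicated(ids)][1])
  }
  names(documents) <- ids
  structure(list(documents = documents, term_index = build_term_index(documents)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d documents, %d annotated terms>\n",
              length(x$documents), length(x$term_index)))
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$documents)

corpus_doc_ids <- function(corp) names(corp$documents)

term_positives <- function(corp, term_id) {
  corp$term_index[[term_id]] %||% character(0)
}

#' Read and write corpora as JSON Lines
#'
#' The canonical, lossless on-disk corpus format: one JSON object per line
#' with keys `doc_id`, `title`, `abstract`, `journal`, `year` and
#' `annotations`. `write_jsonl()` followed by `read_jsonl()` reproduces the
#' corpus exactly (up to document order, which is preserved).
#'
#' @param path File path.
#' @return `read_jsonl()` returns a [corpus()].
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("doc_id", "title", "abstract", "journal", "year", "annotations")
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      meshent_stop("line %d: invalid JSON (%s)", i, conditionMessage(e))
                    })
    missing_keys <- setdiff(required, names(rec))
    if (length(missing_keys)) {
      meshent_stop("line %d: missing key(s) %s", i,
                   paste(missing_keys, collapse = ", "))
    }
    if (!is.numeric(rec$year) || length(rec$year) != 1L ||
        rec$year != as.integer(rec$year)) {
      meshent_stop("line %d: year must be an integer, got %s", i,
                   deparse(rec$year))
    }
    docs[[i]] <- document(rec$doc_id, rec$title, rec$abstract, rec$journal,
                          rec$year, as.character(unlist(rec$annotations)))
  }
  corpus(docs)
}

#' @rdname read_jsonl
#' @param corp A [corpus()].
#' @export
write_jsonl <- function(corp, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in corp$documents) {
    rec <- list(doc_id = d$doc_id, title = d$title, abstract = d$abstract,
                journal = d$journal, year = d$year,
                annotations = as.list(d$annotations))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read MEDLINE-style tagged records
#'
#' Best-effort import of the plain-text tagged MEDLINE layout (fields `PMID-`,
#' `TI  -`, `AB  -`, `TA  -`/`JT  -`, `DP  -`, `MH  -`; continuation lines are
#' indented). `MH` values are mapped to term ids by exact (case-insensitive)
#' match of the bare heading — qualifier suffixes after `/` and the
#' major-topic `*` are stripped — against the labels and synonyms of the
#' supplied tree; headings not in the tree are dropped with a warning. The
#' year is the leading 4 digits of the `DP` field. Records missing a PMID or a
#' title are skipped with a warning.
#'
#' @param path Path to the MEDLINE text file.
#' @param tree A [mesh_tree()] used to resolve `MH` headings to term ids.
#' @return A [corpus()].
#' @export
read_medline <- function(path, tree) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # label/synonym -> term id lookup (lowercased)
  lab2id <- character(0)
  for (t in tree$terms) {
    for (s in c(t$preferred_label, t$synonyms)) {
      lab2id[[tolower(trimws(s))]] <- t$term_id
    }
  }
  # split into record blocks on blank lines
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  docs <- list()
  for (blk in split(lines[!blank], block_id[!blank])) {
    rec <- parse_medline_block(blk)
    if (is.null(rec$PMID) || is.null(rec$TI)) {
      meshent_warn("MEDLINE record skipped: missing PMID or TI near '%s'",
                   substr(blk[1], 1, 40))
      next
    }
    dp <- rec$DP[1] %||% ""
    ym <- regmatches(dp, regexpr("[0-9]{4}", dp))
    if (length(ym) == 0L) {
      meshent_warn("record %s: unparseable date '%s'; skipped", rec$PMID[1], dp)
      next
    }
    anns <- character(0)
    for (mh in rec$MH %||% character(0)) {
      bare <- tolower(trimws(sub("/.*$", "", gsub("\\*", "", mh))))
      id <- unname(lab2id[bare])
      if (is.na(id)) {
        meshent_warn("record %s: MH '%s' not in tree; annotation dropped",
                     rec$PMID[1], mh)
      } else {
        anns <- c(anns, id)
      }
    }
    journal <- (rec$TA %||% rec$JT %||% "")[1]
    abstract <- paste(rec$AB %||% character(0), collapse = " ")
    docs[[length(docs) + 1L]] <- document(rec$PMID[1], paste(rec$TI, collapse = " "),
                                          abstract, journal, as.integer(ym), anns)
  }
  corpus(docs)
}

parse_medline_block <- function(blk) {
  rec <- list()
  tag <- NULL
  for (ln in blk) {
    if (grepl("^[A-Z0-9]{1,4} *- ", ln)) {
      tag <- trimws(sub(" *-.*$", "", ln))
      val <- sub("^[A-Z0-9]{1,4} *- ", "", ln)
      rec[[tag]] <- c(rec[[tag]], val)
    } else if (grepl("^\\s+", ln) && !is.null(tag)) {
      n <- length(rec[[tag]])
      rec[[tag]][n] <- paste(rec[[tag]][n], trimws(ln))
    } else {
      meshent_stop("unparseable MEDLINE line: '%s'", ln)
    }
  }
  rec
}
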