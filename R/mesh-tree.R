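#' MeSH terms and the MeSH tree
#'
#' A `mesh_term` is one controlled-vocabulary heading: an identifier, a
#' preferred label, optional synonyms, and one or more dotted tree numbers
#' (e.g. `"C01.252.400"`) giving its positions in the hierarchy. A term with
#' several tree numbers is polyhierarchic. A `mesh_tree` holds a set of terms
#' together with an index from tree number to term id; every non-top-level
#' tree number must have its parent prefix present in the index. Top-level
#' category roots ("diseases", "anatomy", ...) are labels of the letter
#' prefixes, not terms, and never appear in the index.
#'
#' @param term_id Opaque term identifier (e.g. `"D013597"`).
#' @param preferred_label Preferred heading string; must be non-empty after
#'   trimming.
#' @param synonyms Character vector of entry terms (may be empty).
#' @param tree_numbers Non-empty character vector of dotted position codes.
#' @return `mesh_term()` returns an object of class `"mesh_term"`.
#' @examples
#' t1 <- mesh_term("T1", "Tricuspid Atresia", character(), "C14.280.400")
#' t1$tree_numbers
#' @export
mesh_term <- function(term_id, preferred_label, synonyms = character(),
                      tree_numbers) {
  preferred_label <- trimws(preferred_label)
  if (!nzchar(preferred_label)) {
    meshent_stop("term '%s': preferred label is empty", term_id)
  }
  tree_numbers <- unique(as.character(tree_numbers))
  if (length(tree_numbers) == 0L) {
    meshent_stop("term '%s': no tree numbers", term_id)
  }
  bad <- tree_numbers[!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", tree_numbers)]
  if (length(bad)) {
    meshent_stop("term '%s': malformed tree number '%s'", term_id, bad[1])
  }
  structure(
    list(term_id = as.character(term_id),
         preferred_label = preferred_label,
         synonyms = unique(as.character(synonyms)),
         tree_numbers = tree_numbers),
    class = "mesh_term"
  )
}

#' @export
print.mesh_term <- function(x, ...) {
  cat(sprintf("<mesh_term %s: \"%s\" [%s]>\n", x$term_id, x$preferred_label,
              paste(x$tree_numbers, collapse = ", ")))
  invisible(x)
}

tn_components <- function(tn) strsplit(tn, ".", fixed = TRUE)[[1]]

tn_parent <- function(tn) {
  comp <- tn_components(tn)
  if (length(comp) <= 1L) return(NA_character_)
  paste(comp[-length(comp)], collapse = ".")
}

#' Construct a MeSH tree from a list of terms
#'
#' Validates the structural invariants: every tree number maps to exactly one
#' term, and every non-top-level tree number has its parent position present.
#'
#' @param terms List of [mesh_term()] objects.
#' @return An object of class `"mesh_tree"` with elements `terms` (named list
#'   by term id) and `index` (named character vector, tree number -> term id).
#' @export
mesh_tree <- function(terms) {
  if (length(terms) == 0L) meshent_stop("empty term set")
  ids <- vapply(terms, function(t) t$term_id, character(1))
  if (anyDuplicated(ids)) {
    meshent_stop("duplicate term id '%s'", ids[duplicated(ids)][1])
  }
  names(terms) <- ids
  index <- character(0)
  for (t in terms) {
    for (tn in t$tree_numbers) {
      if (tn %in% names(index)) {
        meshent_stop("tree number '%s' assigned to both '%s' and '%s'",
                     tn, index[[tn]], t$term_id)
      }
      index[[tn]] <- t$term_id
    }
  }
  for (tn in names(index)) {
    p <- tn_parent(tn)
    if (!is.na(p) && !(p %in% names(index))) {
      meshent_stop("orphan tree number '%s': parent position '%s' not in tree",
                   tn, p)
    }
  }
  structure(list(terms = terms, index = index), class = "mesh_tree")
}

#' @export
print.mesh_tree <- function(x, ...) {
  cat(sprintf("<mesh_tree: %d terms, %d tree positions>\n",
              length(x$terms), length(x$index)))
  invisible(x)
}

#' Load a MeSH tree from a TSV file
#'
#' Expected columns (header required, UTF-8): `term_id`, `label`, `synonyms`
#' (pipe-separated, may be empty) and `tree_numbers` (pipe-separated, at least
#' one). Rows violating the tree invariants (duplicate or orphan tree numbers)
#' raise a load error naming the offending tree number.
#'
#' @param path Path to the TSV file.
#' @return A [mesh_tree()].
#' @export
load_mesh_tree <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8")
  required <- c("term_id", "label", "synonyms", "tree_numbers")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    meshent_stop("tree TSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) meshent_stop("tree TSV '%s' has no rows", path)
  split_pipe <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  }
  terms <- lapply(seq_len(nrow(df)), function(i) {
    mesh_term(df$term_id[i], df$label[i],
              synonyms = split_pipe(df$synonyms[i]),
              tree_numbers = split_pipe(df$tree_numbers[i]))
  })
  mesh_tree(terms)
}

#' Write a MeSH tree to TSV
#'
#' Inverse of [load_mesh_tree()] (up to term order, which is sorted by id).
#'
#' @param tree A [mesh_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_tree <- function(tree, path) {
  terms <- tree$terms[order(names(tree$terms))]
  df <- data.frame(
    term_id = vapply(terms, function(t) t$term_id, character(1)),
    label = vapply(terms, function(t) t$preferred_label, character(1)),
    synonyms = vapply(terms, function(t) paste(t$synonyms, collapse = "|"),
                      character(1)),
    tree_numbers = vapply(terms, function(t) paste(sort(t$tree_numbers),
                                                   collapse = "|"),
                          character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

get_term <- function(tree, term_id) {
  t <- tree$terms[[term_id]]
  if (is.null(t)) meshent_stop("unknown term id '%s'", term_id)
  t
}

#' Minimal depth of a term in the tree
#'
#' Depth of a tree number is its number of dotted components, so a top-level
#' code like `"A01"` has depth 1. For polyhierarchic terms the minimum over
#' their tree numbers is taken.
#'
#' @param tree A [mesh_tree()].
#' @param term_id Term identifier.
#' @return Positive integer depth.
#' @export
min_depth <- function(tree, term_id) {
  t <- get_term(tree, term_id)
  min(vapply(t$tree_numbers, function(tn) length(tn_components(tn)), integer(1)))
}

#' Number of common parents of two terms
#'
#' The maximum, over all pairs of tree numbers of the two terms, of the length
#' (in components) of their longest common prefix. `common_parents(t, t)`
#' equals the depth of the term's deepest tree number.
#'
#' @param tree A [mesh_tree()].
#' @param t1,t2 Term identifiers.
#' @return Non-negative integer.
#' @export
common_parents <- function(tree, t1, t2) {
  a <- get_term(tree, t1)$tree_numbers
  b <- get_term(tree, t2)$tree_numbers
  best <- 0L
  for (na in a) {
    ca <- tn_components(na)
    for (nb in b) {
      cb <- tn_components(nb)
      k <- min(length(ca), length(cb))
      cp <- 0L
      while (cp < k && ca[cp + 1L] == cb[cp + 1L]) cp <- cp + 1L
      if (cp > best) best <- cp
    }
  }
  best
}

#' Tree-based semantic distance between two MeSH terms
#'
#' `L(t1) + L(t2) - 2 * CP(t1, t2)`, where `L` is the minimal depth
#' ([min_depth()]) and `CP` the number of common parents
#' ([common_parents()]). On a strict monohierarchy this is the undirected
#' shortest-path edge count between the two positions (through a virtual root
#' above the top-level codes). For polyhierarchic terms the convention
#' (minimal depths, maximal common prefix) yields the most generous — i.e.
#' smallest — distance.
#'
#' @param tree A [mesh_tree()].
#' @param t1,t2 Term identifiers.
#' @return Non-negative number.
#' @export
term_distance <- function(tree, t1, t2) {
  min_depth(tree, t1) + min_depth(tree, t2) - 2 * common_parents(tree, t1, t2)
}

#' Semantic distance between a term and an annotated abstract
#'
#' Defined as the maximum [term_distance()] between `term_id` and any MeSH
#' term annotating the abstract. Undefined (an error) when the abstract
#' carries no annotations.
#'
#' @param tree A [mesh_tree()].
#' @param term_id Term identifier.
#' @param abstract_terms Non-empty character vector of term ids annotating the
#'   abstract.
#' @return Non-negative number.
#' @export
term_abstract_distance <- function(tree, term_id, abstract_terms) {
  if (length(abstract_terms) == 0L) {
    meshent_stop("term-abstract distance is undefined for an abstract with no MeSH annotations")
  }
  max(vapply(abstract_terms, function(a) term_distance(tree, term_id, a),
             numeric(1)))
}

#' Is a term semantically distant from an annotated abstract?
#'
#' `TRUE` iff the term-abstract distance is strictly above `depth_threshold`.
#' The default threshold is 6.
#'
#' @inheritParams term_abstract_distance
#' @param depth_threshold Strict cut-off on the distance (default 6).
#' @return Logical scalar.
#' @export
is_semantically_distant <- function(tree, term_id, abstract_terms,
                                    depth_threshold = 6) {
  term_abstract_distance(tree, term_id, abstract_terms) > depth_threshold
}
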