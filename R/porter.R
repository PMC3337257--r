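#' Porter stemming
#'
#' An implementation of Porter's (1980) suffix-stripping algorithm, the
#' stemmer used throughout the feature pipeline and the literal-match rules.
#' Input words are expected lowercase; non-alphabetic characters are treated
#' as consonants, which leaves tokens containing digits essentially untouched.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("diseases", "caresses", "ponies", "relational"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_cached, character(1), USE.NAMES = FALSE)
}

.stem_cache <- new.env(parent = emptyenv())

porter_stem_cached <- function(word) {
  hit <- .stem_cache[[word]]
  if (!is.null(hit)) return(hit)
  s <- porter_stem1(word)
  assign(word, s, envir = .stem_cache)
  s
}

porter_stem1 <- function(word) {
  if (nchar(word) <= 2L) return(word)
  b <- strsplit(word, "", fixed = TRUE)[[1]]

  is_cons <- function(i) {
    ch <- b[i]
    if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
    if (ch == "y") return(i == 1L || !is_cons(i - 1L))
    TRUE
  }
  # measure m of b[1..j]: number of VC sequences
  measure <- function(j) {
    n <- 0L; i <- 1L
    while (TRUE) {
      if (i > j) return(n)
      if (!is_cons(i)) break
      i <- i + 1L
    }
    i <- i + 1L
    repeat {
      while (TRUE) {
        if (i > j) return(n)
        if (is_cons(i)) break
        i <- i + 1L
      }
      i <- i + 1L; n <- n + 1L
      while (TRUE) {
        if (i > j) return(n)
        if (!is_cons(i)) break
        i <- i + 1L
      }
      i <- i + 1L
    }
  }
  has_vowel <- function(j) {
    for (i in seq_len(j)) if (!is_cons(i)) return(TRUE)
    FALSE
  }
  double_cons <- function(j) {
    j >= 2L && b[j] == b[j - 1L] && is_cons(j)
  }
  # consonant-vowel-consonant ending, final consonant not w, x or y
  cvc <- function(j) {
    if (j < 3L || !is_cons(j) || is_cons(j - 1L) || !is_cons(j - 2L)) return(FALSE)
    !(b[j] %in% c("w", "x", "y"))
  }
  k <- length(b)
  ends <- function(suf) {
    ns <- nchar(suf)
    if (ns >= k) return(FALSE)
    paste(b[(k - ns + 1L):k], collapse = "") == suf
  }
  set_to <- function(stem_len, repl) {
    b <<- c(b[seq_len(stem_len)], strsplit(repl, "", fixed = TRUE)[[1]])
    k <<- length(b)
  }
  # replace suffix `suf` by `repl` when measure of the stem is > m_min
  r <- function(suf, repl, m_min) {
    stem_len <- k - nchar(suf)
    if (measure(stem_len) > m_min) set_to(stem_len, repl)
    TRUE
  }

  # Step 1a
  if (b[k] == "s") {
    if (ends("sses")) set_to(k - 4L, "ss")
    else if (ends("ies")) set_to(k - 3L, "i")
    else if (k >= 2L && b[k - 1L] != "s") set_to(k - 1L, "")
  }

  # Step 1b
  step1b2 <- FALSE
  if (ends("eed")) {
    if (measure(k - 3L) > 0L) set_to(k - 1L, "")
  } else if (ends("ed") && has_vowel(k - 2L)) {
    set_to(k - 2L, ""); step1b2 <- TRUE
  } else if (ends("ing") && has_vowel(k - 3L)) {
    set_to(k - 3L, ""); step1b2 <- TRUE
  }
  if (step1b2) {
    if (ends("at") || ends("bl") || ends("iz")) {
      set_to(k, "e")
    } else if (double_cons(k) && !(b[k] %in% c("l", "s", "z"))) {
      set_to(k - 1L, "")
    } else if (measure(k) == 1L && cvc(k)) {
      set_to(k, "e")
    }
  }

  # Step 1c
  if (b[k] == "y" && has_vowel(k - 1L)) b[k] <- "i"

  # Step 2 (longest matching suffix per final letter, m > 0)
  step2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
    c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
    c("iviti", "ive"), c("biliti", "ble")
  )
  for (p in step2) if (ends(p[1])) { r(p[1], p[2], 0L); break }

  # Step 3
  step3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  for (p in step3) if (ends(p[1])) { r(p[1], p[2], 0L); break }

  # Step 4 (m > 1); "ion" only after s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
             "ic", "ou")
  for (suf in step4) {
    if (ends(suf)) {
      stem_len <- k - nchar(suf)
      if (suf == "ion" && !(stem_len >= 1L && b[stem_len] %in% c("s", "t"))) next
      if (measure(stem_len) > 1L) set_to(stem_len, "")
      break
    }
  }

  # Step 5a
  if (b[k] == "e") {
    m <- measure(k - 1L)
    if (m > 1L || (m == 1L && !cvc(k - 1L))) set_to(k - 1L, "")
  }
  # Step 5b
  if (b[k] == "l" && double_cons(k) && measure(k) > 1L) set_to(k - 1L, "")

  paste(b, collapse = "")
}
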