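#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# All stochastic steps in the package (subsampling, fold assignment, corpus
# generation) go through this, so identical seeds give identical results.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Stable 31-bit hash of a string, combined with a master seed. Used to fan a
# single master seed out to per-term streams so that per-term draws do not
# depend on the order terms are processed in.
derive_seed <- function(master_seed, key) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(as.character(key)))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h + as.numeric(master_seed) %% 2147483647) %% 2147483647)
}

# sample() without the length-1 surprise: sample_ids(c("d5"), 1) returns "d5".
sample_ids <- function(x, size) {
  x <- sort(x)
  if (length(x) == 1L && size >= 1L) return(x)
  sample(x, size)
}

meshent_warn <- function(...) warning(sprintf(...), call. = FALSE)
meshent_stop <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
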