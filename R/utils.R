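# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one integer master seed; each
#' stochastic step draws from its own named substream so that, e.g., adding
#' an extra covariate draw does not shift the genotype stream.
#'
#' @param master integer master seed
#' @param name character stream label
#' @return an integer seed in [0, 2^31 - 1)
#' @keywords internal
substream_seed <- function(master, name) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
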