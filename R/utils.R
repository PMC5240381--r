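## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream. `seed = NULL` evaluates without seeding.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## serialize integer offset vectors for the TSV dialect ("." = none)
offsets_to_chr <- function(x) {
  vapply(x, function(v) if (length(v) == 0L) "." else paste(v, collapse = ","),
         character(1))
}

chr_to_offsets <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "." || s == "") integer(0)
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

## sequences: accept DNAStringSet or named character vector; return named
## character vector (used internally for fast substring work)
as_seq_chr <- function(sequences) {
  if (is.character(sequences)) {
    if (is.null(names(sequences))) stop("sequences must be named")
    return(sequences)
  }
  if (methods::is(sequences, "DNAStringSet")) {
    s <- as.character(sequences)
    if (is.null(names(s))) stop("sequences must be named")
    return(s)
  }
  stop("unsupported sequence container: ", class(sequences)[1])
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single probability in [0, 1]")
  invisible(x)
}
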