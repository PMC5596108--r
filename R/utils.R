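`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' disturb the global random stream. A `NULL` seed leaves the RNG alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be a single integer (got %s)", deparse(seed))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count_scalar <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min
}

# case-insensitive fixed-substring match of any pattern against x
lineage_matches <- function(x, patterns) {
  x <- tolower(x)
  hit <- rep(FALSE, length(x))
  for (p in tolower(patterns)) {
    hit <- hit | grepl(p, x, fixed = TRUE)
  }
  hit
}
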