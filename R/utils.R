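#' Evaluate an expression under a temporary RNG seed
#'
#' Used by every stochastic entry point so a `seed` argument gives exact
#' reproducibility without clobbering the caller's RNG stream.
#'
#' @param seed integer seed or `NULL` (use the current stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# stage counters are logged to stderr, vcftools-style
log_counter <- function(stage, ...) {
  msg <- paste0("[famsel] ", stage, ": ",
                paste(names(c(...)), unlist(c(...)), sep = "=", collapse = ", "))
  message(msg)
}

# derive independent sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}
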