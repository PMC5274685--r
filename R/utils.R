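#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulations do not
#' perturb the global random stream. A `NULL` seed evaluates the expression
#' with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# scalar validation helpers
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Draw integer sub-seeds from the current RNG stream
#' @noRd
draw_seed <- function(n = 1L) {
  sample.int(.Machine$integer.max, n)
}

#' Hash an R object (configuration provenance)
#' @noRd
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  # version = 2 keeps the hash stable across R >= 3.5 serialization defaults
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
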