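#' @importFrom stats median pnorm pt qnorm quantile rbinom rlnorm rnorm rpois
#'   sd setNames t.test p.adjust complete.cases
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local, restored RNG state
#'
#' All generators in the package are pure functions of (config, seed): the
#' global RNG state is saved, the seed applied, and the previous state
#' restored on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
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
  set.seed(as.integer(seed))
  expr
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

# deterministic, locale-independent chromosome ordering
sort_chroms <- function(x) sort(unique(x), method = "radix")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
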