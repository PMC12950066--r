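#' @useDynLib imuwalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median qnorm quantile rlnorm rnorm runif rpois rexp
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

iw_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("imuwalk_", class, "_error"),
                                     "imuwalk_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' seeded package operations (balancing, splitting, simulation) do not
#' perturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}
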