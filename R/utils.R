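`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name),
                           call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

as_obs_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    check_numeric(x, name)
    return(x)
  }
  check_numeric(x, name)
  matrix(x, ncol = 1)
}

#' Validate a balance weight vector
#'
#' Weights must be nonnegative, finite, and sum to the sample size within
#' a relative tolerance of 1e-8.
#'
#' @param w numeric vector of weights.
#' @param n expected length (sample size).
#' @return `w`, invisibly, if valid; otherwise an error.
#' @export
check_weights <- function(w, n = length(w)) {
  check_numeric(w, "w")
  if (length(w) != n)
    stop("weight vector has length ", length(w), ", expected ", n,
         call. = FALSE)
  if (any(w < -1e-12)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - n) > 1e-8 * max(1, n))
    stop("weights must sum to the sample size (got ",
         format(sum(w)), " for n = ", n, ")", call. = FALSE)
  invisible(w)
}
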