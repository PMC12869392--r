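# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_positive_int <- function(x, name) {
  if (length(x) < 1L || anyNA(x) || any(x != floor(x)) || any(x <= 0))
    stop_input(sprintf("'%s' must be a positive integer", name))
  as.integer(x)
}

#' Log(1 + x) transform for event counts
#'
#' Count-valued features enter the hazard models per unit of
#' \code{log(1 + count)}, which tempers the influence of extreme utilization
#' counts while keeping zero counts at zero.  Recency ("days since last")
#' features are left on their natural scale.
#'
#' @param x Nonnegative numeric vector of counts.
#' @return \code{log1p(x)}.
#' @examples
#' transform_counts(0)       # 0
#' transform_counts(exp(1) - 1)  # 1
#' @export
transform_counts <- function(x) {
  if (any(is.na(x)) || any(x < 0))
    stop_input("counts must be nonnegative and non-missing")
  log1p(x)
}
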