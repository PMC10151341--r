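#' @importFrom rlang abort warn %||%
#' @import tibble
#' @importFrom stats median rnorm runif predict
#' @importFrom utils head tail
NULL

# run expr under a fixed RNG state, restoring the caller's stream afterwards
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
  set.seed(seed)
  force(expr)
}

assert_image_matrix <- function(x, arg = "img") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", arg), class = "mammoqc_input_error")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort(sprintf("`%s` must have at least 2 rows and 2 columns", arg),
          class = "mammoqc_input_error")
  }
  invisible(x)
}

# reflect-pad a matrix by (pr, pc) on each side; pad of 0 is identity
reflect_pad <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc) {
    abort("reflect padding wider than the image", class = "mammoqc_input_error")
  }
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
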