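#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov coef dhyper fft glm oneway.test phyper plogis
#'   predict quantile rnorm runif sd t.test TukeyHSD var binom.test
#'   binomial ks.test pf
#' @importFrom utils head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_smf <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "smfdecode_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

vnorm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))
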