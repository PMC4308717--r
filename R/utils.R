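#' @keywords internal
"_PACKAGE"

#' @importFrom stats var sd cor dnorm rnorm runif rbinom rpois rbeta quantile
#'   median ks.test wilcox.test plogis qlogis aggregate setNames IQR
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so no exported function perturbs global randomness.
local_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific sub-seed from a master seed, kept below 2^31.
sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 1103L + offset) %% 2147483629
}

#' Logit transform with clipping
#'
#' `log(p/(1-p))` after clipping `p` into `[eps, 1-eps]` so that complete
#' inclusion/exclusion does not map to infinity.
#'
#' @param p numeric vector of proportions.
#' @param eps clipping bound, default `1e-3`.
#' @return numeric vector of logits.
#' @export
logit <- function(p, eps = 1e-3) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
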