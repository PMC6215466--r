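#' @useDynLib arealmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif quantile sd lm pf coef dist
#'   kmeans cor.test var residuals
#' @importFrom utils head read.delim write.table
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629L)
}

#' Fisher r-to-z transform with clipping
#'
#' Correlations are clipped to +/- (1 - 1e-7) before `atanh` so the
#' transform stays finite (identical series otherwise map to infinity).
#'
#' @param r numeric vector or matrix of correlation coefficients.
#' @return `atanh` of the clipped input, same shape.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

r_clip_ceiling <- function() atanh(1 - 1e-7)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
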