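# Internal helpers shared across modules.

#' @useDynLib widecal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` uses the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive reproducible sub-seeds from a master seed so that the random draws of
# one simulator component (placement, events, motion, ...) do not perturb the
# others when its parameters change.
subSeeds <- function(seed, names) {
  s <- withSeed(seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(as.list(s), names)
}

# Round half away from zero (base round() goes to even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Collect and hand freed pages back to the OS; used between heavy stages and
# periodically inside frame loops so long sessions stay within memory.
trimMemory <- function() {
  invisible(gc(FALSE))
  .memTrim()
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Cache of separable Gaussian smoothing matrices keyed by "n:sigma".
.blurCache <- new.env(parent = emptyenv())

# Gaussian-weighted local-linear smoothing matrix (truncated at 3 sigma).
# In the interior this equals a normalized Gaussian kernel; near the edges
# the local-linear fit keeps the smoother exact on linear trends, avoiding
# the boundary bias of plain kernel renormalization (which would leak
# illumination gradients into the high-pass residual).
gaussSmoothingMatrix <- function(n, sigma) {
  key <- paste0(n, ":", signif(sigma, 12))
  hit <- .blurCache[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(3 * sigma)
  A <- matrix(0, n, n)
  k <- stats::dnorm(-r:r, sd = sigma)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1L & j <= n
    jj <- j[keep]
    w <- k[keep]
    d <- jj - i
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d * d)
    den <- s0 * s2 - s1 * s1
    A[i, jj] <- if (den > 0) w * (s2 - d * s1) / den else w / s0
  }
  .blurCache[[key]] <- A
  A
}

# Separable Gaussian low-pass of a matrix (rows then columns).
gaussBlur <- function(x, sigma) {
  A <- gaussSmoothingMatrix(nrow(x), sigma)
  B <- gaussSmoothingMatrix(ncol(x), sigma)
  A %*% x %*% t(B)
}
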