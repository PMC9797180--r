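#' Construct an ImageVolume
#'
#' @param data 3D numeric array of HU values, axis order (slice, row, column).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) position of the first voxel in mm.
#' @return an \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an RoiMask
#'
#' Any nonzero voxel of \code{data} becomes foreground.
#'
#' @param data 3D array (logical or numeric).
#' @param spacing numeric(3) voxel spacing in mm.
#' @return an \linkS4class{RoiMask}.
#' @export
RoiMask <- function(data, spacing = c(1, 1, 1)) {
  m <- array(as.logical(data != 0), dim = dim(data))
  new("RoiMask", data = m, spacing = as.numeric(spacing))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

# Polynomial rolling hash of a string folded with the master seed into
# [0, 2^31). All intermediates stay below 2^48, so double arithmetic is
# exact and the sub-seed is stable across platforms. Used to derive
# per-patient sub-seeds independent of patient order.
stableSubSeed <- function(masterSeed, id) {
  h <- 5381
  for (b in utf8ToInt(as.character(id)))
    h <- (h * 127 + b) %% 2147483647
  as.integer((h * 69069 + as.numeric(masterSeed) * 7919 + 17) %% 2147483647)
}

# Shift a 3D array by integer offset (slice, row, col), filling with NA.
shiftArray <- function(a, off) {
  d <- dim(a)
  out <- array(a[1][NA], dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { src[[k]] <- seq_len(d[k] - o); dst[[k]] <- src[[k]] + o }
    else        { dst[[k]] <- seq_len(d[k] + o); src[[k]] <- dst[[k]] - o }
    if (length(src[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Shannon entropy (bits) of a probability vector; 0 log 0 = 0.
entropyBits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

# Probability histogram of values on integer-width (1 HU) bins.
histProbs <- function(v) {
  lv <- floor(v)
  counts <- tabulate(lv - min(lv) + 1L)
  counts / sum(counts)
}

# ---- weighted descriptive statistics on a discrete distribution ------------
# x: support points (e.g. histogram bin centers), w: non-negative weights.
# Degenerate inputs (total weight 0, or a single point) yield 0 for every
# spread/shape statistic; skewness and kurtosis of a zero-variance
# distribution are 0 by convention (documented in the vignette).

wStats <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) { x <- 0; w <- 1 }
  w <- w / sum(w)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  m3 <- sum(w * (x - mu)^3)
  m4 <- sum(w * (x - mu)^4)
  list(x = x, w = w, mean = mu, var = m2,
       skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurt = if (m2 > 0) m4 / m2^2 else 0)
}

# Weighted quantile: smallest support point whose CDF reaches p.
wQuantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(p, function(pp) x[match(TRUE, cw >= pp - 1e-12)], numeric(1))
}

# Non-excess sample kurtosis (population moments, normal = 3).
sampleKurtosis <- function(v) {
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(0)
  mean((v - m)^4) / m2^2
}

sampleSkewness <- function(v) {
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(0)
  mean((v - m)^3) / m2^1.5
}
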