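#' Glcm: gray-level co-occurrence matrix
#'
#' @slot p nLevels x nLevels matrix of pair probabilities (sums to 1 when at
#'   least one pair exists; all zero when empty).
#' @slot direction integer(3) offset direction (slice, row, column).
#' @slot distance integer offset distance.
#' @slot symmetric logical, whether pairs were accumulated symmetrically.
#' @slot nPairs number of voxel pairs accumulated (0 marks an empty matrix).
#' @export
setClass("Glcm",
  representation(p = "matrix", direction = "integer", distance = "integer",
                 symmetric = "logical", nPairs = "integer"),
  validity = function(object) {
    if (nrow(object@p) != ncol(object@p)) return("p must be square")
    if (any(object@p < 0)) return("p entries must be non-negative")
    if (object@nPairs > 0 && abs(sum(object@p) - 1) > 1e-12)
      return("p must sum to 1 when pairs exist")
    if (object@symmetric && object@nPairs > 0 &&
        max(abs(object@p - t(object@p))) > 1e-12)
      return("p must be symmetric when the symmetry flag is set")
    TRUE
  }
)

#' Compute a gray-level co-occurrence matrix
#'
#' Counts ordered pairs of in-mask gray levels separated by
#' \code{direction * distance}; with \code{symmetric = TRUE} the transposed
#' pairs are accumulated too (Haralick convention). Pair counts from all
#' slices are pooled before normalization, so an in-plane direction applied
#' to a multi-slice ROI gives the per-slice-pooled 2D matrix.
#'
#' @param q a \linkS4class{QuantizedRoi}.
#' @param direction integer(3) offset (slice, row, column).
#' @param distance integer step length along the direction (default 1).
#' @param symmetric symmetric accumulation (default TRUE).
#' @return a \linkS4class{Glcm}; zero pairs yield an explicitly empty matrix.
#' @export
computeGlcm <- function(q, direction, distance = 1L, symmetric = TRUE) {
  ng <- q@nLevels
  off <- as.integer(direction) * as.integer(distance)
  A <- q@levels
  B <- shiftArray(A, -off)           # B[x] = levels[x + off]
  ok <- !is.na(A) & !is.na(B)
  counts <- matrix(0, ng, ng)
  n <- sum(ok)
  if (n > 0) {
    idx <- (A[ok] - 1L) * ng + B[ok]
    counts <- matrix(tabulate(idx, ng * ng), ng, ng, byrow = TRUE)
    if (symmetric) {
      counts <- counts + t(counts)
      n <- 2L * n
    }
    counts <- counts / sum(counts)
  }
  new("Glcm", p = counts, direction = as.integer(direction),
      distance = as.integer(distance), symmetric = isTRUE(symmetric),
      nPairs = as.integer(n))
}

#' Haralick features of a co-occurrence matrix
#'
#' Computes the 22 co-occurrence features used by the registry. Entropies are
#' in bits with 0 log 0 = 0. The normalized homogeneities divide the
#' gray-level difference by the number of discrete levels Ng:
#' IDN = sum p(i,j) / (1 + |i-j|/Ng) and
#' IDMN = sum p(i,j) / (1 + (i-j)^2/Ng^2), so IDN >= Homogeneity
#' (= sum p/(1+|i-j|)) and IDMN >= Homogeneity2 (= sum p/(1+(i-j)^2))
#' termwise.
#'
#' @param m a \linkS4class{Glcm}.
#' @return named numeric of length 22; all NA when the matrix is empty.
#' @export
glcmFeatures <- function(m) {
  nms <- glcmFeatureNames()
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (m@nPairs == 0L) return(out)
  p <- m@p
  ng <- nrow(p)
  i <- seq_len(ng)
  I <- matrix(i, ng, ng)
  J <- t(I)
  D <- I - J
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(i * px); my <- sum(i * py)
  sx <- sqrt(sum((i - mx)^2 * px)); sy <- sqrt(sum((i - my)^2 * py))
  # diagonal-sum and diagonal-difference distributions
  pxy <- tapply(p, I + J, sum)                      # k = 2..2Ng
  kSum <- as.numeric(names(pxy))
  pdiff <- tapply(p, abs(D), sum)                   # k = 0..Ng-1
  auto <- sum(I * J * p)

  out["AutoCorrelation"] <- auto
  cdev <- I + J - mx - my
  out["ClusterTendency"] <- sum(cdev^2 * p)
  out["ClusterShade"] <- sum(cdev^3 * p)
  out["ClusterProminence"] <- sum(cdev^4 * p)
  out["Contrast"] <- sum(D^2 * p)
  out["Correlation"] <- if (sx > 0 && sy > 0) (auto - mx * my) / (sx * sy)
                        else NA_real_
  out["DifferenceEntropy"] <- entropyBits(pdiff)
  out["Dissimilarity"] <- sum(abs(D) * p)
  out["Energy"] <- sum(p^2)
  hxy <- entropyBits(p)
  out["Entropy"] <- hxy
  out["Homogeneity"] <- sum(p / (1 + abs(D)))
  out["Homogeneity2"] <- sum(p / (1 + D^2))
  pxpy <- outer(px, py)
  pos <- p > 0 & pxpy > 0
  hxy1 <- -sum(p[pos] * log2(pxpy[pos]))
  pos2 <- pxpy > 0
  hxy2 <- -sum(pxpy[pos2] * log2(pxpy[pos2]))
  hx <- entropyBits(px); hy <- entropyBits(py)
  out["InformationMeasureCorr1"] <-
    if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  arg <- 1 - 2^(-2 * (hxy2 - hxy))
  out["InformationMeasureCorr2"] <- sqrt(max(arg, 0))
  out["InverseDiffMomentNorm"] <- sum(p / (1 + D^2 / ng^2))
  out["InverseDiffNorm"] <- sum(p / (1 + abs(D) / ng))
  offd <- D != 0
  out["InverseVariance"] <- sum(p[offd] / D[offd]^2)
  out["MaxProbability"] <- max(p)
  sa <- sum(kSum * pxy)
  out["SumAverage"] <- sa
  out["SumEntropy"] <- entropyBits(pxy)
  out["SumVariance"] <- sum((kSum - sa)^2 * pxy)
  out["Variance"] <- sum((I - mx)^2 * p)
  out
}
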