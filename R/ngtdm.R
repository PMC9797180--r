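# Neighbor offsets for the neighborhood gray-tone difference matrix.
ngtdmOffsets <- function(mode) {
  g <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  g <- g[!(g$ds == 0 & g$dr == 0 & g$dc == 0), ]
  if (mode == "2D") g <- g[g$ds == 0, ]
  as.matrix(g)
}

#' Neighborhood gray-tone difference features
#'
#' Builds the Amadasun-King neighborhood gray-tone difference matrix over
#' in-mask neighbors (8-neighborhood per slice in 2D mode, 26-neighborhood in
#' 3D mode) and computes Coarseness, Contrast, Busyness, Complexity and
#' Strength. Voxels with no in-mask neighbor are excluded. Coarseness uses an
#' epsilon of 1e-6 in the denominator, capping its value at 1e6 for constant
#' regions; a single-voxel ROI has no neighbors and yields all-NA.
#'
#' @param q a \linkS4class{QuantizedRoi}.
#' @param mode "2D" or "3D".
#' @return named numeric of length 5.
#' @export
nidFeatures <- function(q, mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  eps <- 1e-6
  nms <- ngtdmFeatureNames()
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  L <- q@levels
  offs <- ngtdmOffsets(mode)
  nsum <- array(0, dim = dim(L))
  ncnt <- array(0L, dim = dim(L))
  for (r in seq_len(nrow(offs))) {
    B <- shiftArray(L, -as.integer(offs[r, ]))
    hit <- !is.na(B)
    nsum[hit] <- nsum[hit] + B[hit]
    ncnt <- ncnt + hit
  }
  use <- !is.na(L) & ncnt > 0L
  if (!any(use)) return(out)
  lev <- L[use]
  abar <- nsum[use] / ncnt[use]
  ng <- q@nLevels
  si <- vapply(seq_len(ng), function(i) sum(abs(i - abar[lev == i])),
               numeric(1))
  ni <- tabulate(lev, ng)
  N <- sum(ni)
  pi <- ni / N
  pres <- which(pi > 0)
  ngp <- length(pres)

  psi <- sum(pi * si)
  out["Coarseness"] <- min(1 / (eps + psi), 1e6)
  if (ngp > 1) {
    ij2 <- outer(pres, pres, function(a, b) (a - b)^2)
    pp <- outer(pi[pres], pi[pres])
    out["Contrast"] <- (sum(pp * ij2) / (ngp * (ngp - 1))) * (sum(si) / N)
    ipi <- pres * pi[pres]
    den <- sum(abs(outer(ipi, ipi, "-")))
    out["Busyness"] <- if (den > 0) psi / den else 0
    ij <- abs(outer(pres, pres, "-"))
    ps <- pi[pres] * si[pres]
    num <- outer(ps, ps, "+")
    pden <- outer(pi[pres], pi[pres], "+")
    out["Complexity"] <- sum(ij * num / (N * pden))
    out["Strength"] <- sum(outer(pi[pres], pi[pres], "+") * ij2) /
      (eps + sum(si))
  } else {
    out["Contrast"] <- 0
    out["Busyness"] <- 0
    out["Complexity"] <- 0
    out["Strength"] <- 0
  }
  out
}
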