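# Independent brute-force oracles: naive enumeration implementations used to
# verify the vectorized package code on small inputs. Deliberately written as
# plain loops over voxels/cells, sharing no code with the package internals.

# Ordered-pair co-occurrence matrix by looping over every voxel.
bruteGlcm <- function(lev, ng, dir, dist = 1L, symmetric = TRUE) {
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  o <- dir * dist
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    a <- lev[s, r, c]
    if (is.na(a)) next
    s2 <- s + o[1]; r2 <- r + o[2]; c2 <- c + o[3]
    if (s2 < 1 || s2 > d[1] || r2 < 1 || r2 > d[2] || c2 < 1 || c2 > d[3])
      next
    b <- lev[s2, r2, c2]
    if (is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    if (symmetric) counts[b, a] <- counts[b, a] + 1
  }
  if (sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# Haralick features by direct double loops over the matrix cells.
oracleGlcmFeatures <- function(p) {
  ng <- nrow(p)
  lg2 <- function(x) log(x, 2)
  px <- rowSums(p); py <- colSums(p)
  mx <- 0; my <- 0
  for (i in 1:ng) { mx <- mx + i * px[i]; my <- my + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:ng) { sx <- sx + (i - mx)^2 * px[i]; sy <- sy + (i - my)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)        # indices k and k+1
  acc <- list(auto = 0, cp = 0, cs = 0, ct = 0, con = 0, dis = 0, en = 0,
              ent = 0, h1 = 0, h2 = 0, idmn = 0, idn = 0, iv = 0, var = 0,
              cor = 0)
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
    acc$auto <- acc$auto + i * j * v
    dd <- i + j - mx - my
    acc$ct <- acc$ct + dd^2 * v
    acc$cs <- acc$cs + dd^3 * v
    acc$cp <- acc$cp + dd^4 * v
    acc$con <- acc$con + (i - j)^2 * v
    acc$dis <- acc$dis + abs(i - j) * v
    acc$en <- acc$en + v^2
    if (v > 0) acc$ent <- acc$ent - v * lg2(v)
    acc$h1 <- acc$h1 + v / (1 + abs(i - j))
    acc$h2 <- acc$h2 + v / (1 + (i - j)^2)
    acc$idmn <- acc$idmn + v / (1 + (i - j)^2 / ng^2)
    acc$idn <- acc$idn + v / (1 + abs(i - j) / ng)
    if (i != j) acc$iv <- acc$iv + v / (i - j)^2
    acc$var <- acc$var + (i - mx)^2 * v
  }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * lg2(q)
      hxy2 <- hxy2 - q * lg2(q)
    }
  }
  hx <- -sum(px[px > 0] * lg2(px[px > 0]))
  hy <- -sum(py[py > 0] * lg2(py[py > 0]))
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * lg2(psum[k])
  }
  sv <- 0
  for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  de <- 0
  for (k in 1:ng) if (pdif[k] > 0) de <- de - pdif[k] * lg2(pdif[k])
  c(AutoCorrelation = acc$auto, ClusterProminence = acc$cp,
    ClusterShade = acc$cs, ClusterTendency = acc$ct, Contrast = acc$con,
    Correlation = if (sx > 0 && sy > 0) (acc$auto - mx * my) / (sx * sy)
                  else NA_real_,
    DifferenceEntropy = de, Dissimilarity = acc$dis, Energy = acc$en,
    Entropy = acc$ent, Homogeneity = acc$h1, Homogeneity2 = acc$h2,
    InformationMeasureCorr1 = if (max(hx, hy) > 0)
      (acc$ent - hxy1) / max(hx, hy) else NA_real_,
    InformationMeasureCorr2 = sqrt(max(0, 1 - 2^(-2 * (hxy2 - acc$ent)))),
    InverseDiffMomentNorm = acc$idmn, InverseDiffNorm = acc$idn,
    InverseVariance = acc$iv, MaxProbability = max(p), SumAverage = sa,
    SumEntropy = se, SumVariance = sv, Variance = acc$var)
}

# Run-length features by explicitly walking every line of every slice.
oracleRunLength <- function(lev, ng, dir) {
  d <- dim(lev)
  runs <- list()
  dr <- dir[2]; dc <- dir[3]
  inb <- function(r, c) r >= 1 && r <= d[2] && c >= 1 && c <= d[3]
  for (s in seq_len(d[1])) {
    for (r0 in seq_len(d[2])) for (c0 in seq_len(d[3])) {
      # line starts where the predecessor cell is out of bounds
      if (inb(r0 - dr, c0 - dc)) next
      r <- r0; c <- c0
      cur <- NA; len <- 0
      while (inb(r, c)) {
        v <- lev[s, r, c]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- 1
        }
        r <- r + dr; c <- c + dc
      }
      if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
    }
  }
  np <- sum(!is.na(lev))
  nr <- length(runs)
  f <- c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
         GrayLevelNonuniformity = 0, RunLengthNonuniformity = 0,
         RunPercentage = nr / np, LowGrayLevelRunEmpha = 0,
         HighGrayLevelRunEmpha = 0, ShortRunLowGrayLevelEmpha = 0,
         ShortRunHighGrayLevelEmpha = 0, LongRunLowGrayLevelEmpha = 0,
         LongRunHighGrayLevelEmpha = 0)
  if (nr == 0) return(f + NA_real_)
  byLevel <- rep(0, ng)
  byLen <- rep(0, max(vapply(runs, `[`, 0, 2)))
  for (rn in runs) {
    i <- rn[1]; l <- rn[2]
    byLevel[i] <- byLevel[i] + 1
    byLen[l] <- byLen[l] + 1
    f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] + 1 / l^2
    f["LongRunEmphasis"] <- f["LongRunEmphasis"] + l^2
    f["LowGrayLevelRunEmpha"] <- f["LowGrayLevelRunEmpha"] + 1 / i^2
    f["HighGrayLevelRunEmpha"] <- f["HighGrayLevelRunEmpha"] + i^2
    f["ShortRunLowGrayLevelEmpha"] <-
      f["ShortRunLowGrayLevelEmpha"] + 1 / (i^2 * l^2)
    f["ShortRunHighGrayLevelEmpha"] <-
      f["ShortRunHighGrayLevelEmpha"] + i^2 / l^2
    f["LongRunLowGrayLevelEmpha"] <-
      f["LongRunLowGrayLevelEmpha"] + l^2 / i^2
    f["LongRunHighGrayLevelEmpha"] <-
      f["LongRunHighGrayLevelEmpha"] + i^2 * l^2
  }
  f["GrayLevelNonuniformity"] <- sum(byLevel^2)
  f["RunLengthNonuniformity"] <- sum(byLen^2)
  sel <- names(f) != "RunPercentage"
  f[sel] <- f[sel] / nr
  f
}

# Neighborhood gray-tone difference features by per-voxel loops.
oracleNgtdm <- function(lev, ng, mode) {
  d <- dim(lev)
  eps <- 1e-6
  si <- rep(0, ng); ni <- rep(0, ng)
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    v <- lev[s, r, c]
    if (is.na(v)) next
    nb <- c()
    srange <- if (mode == "2D") 0 else -1:1
    for (ds in srange) for (dr in -1:1) for (dc in -1:1) {
      if (ds == 0 && dr == 0 && dc == 0) next
      s2 <- s + ds; r2 <- r + dr; c2 <- c + dc
      if (s2 < 1 || s2 > d[1] || r2 < 1 || r2 > d[2] ||
          c2 < 1 || c2 > d[3]) next
      w <- lev[s2, r2, c2]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (length(nb) == 0) next
    si[v] <- si[v] + abs(v - mean(nb))
    ni[v] <- ni[v] + 1
  }
  N <- sum(ni)
  if (N == 0)
    return(c(Coarseness = NA_real_, Contrast = NA_real_, Busyness = NA_real_,
             Complexity = NA_real_, Strength = NA_real_))
  pi <- ni / N
  pres <- which(pi > 0)
  ngp <- length(pres)
  coars <- min(1 / (eps + sum(pi * si)), 1e6)
  if (ngp == 1)
    return(c(Coarseness = coars, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  con1 <- 0; busyDen <- 0; comp <- 0; str <- 0
  for (i in pres) for (j in pres) {
    con1 <- con1 + pi[i] * pi[j] * (i - j)^2
    busyDen <- busyDen + abs(i * pi[i] - j * pi[j])
    comp <- comp + abs(i - j) * (pi[i] * si[i] + pi[j] * si[j]) /
      (N * (pi[i] + pi[j]))
    str <- str + (pi[i] + pi[j]) * (i - j)^2
  }
  c(Coarseness = coars,
    Contrast = con1 / (ngp * (ngp - 1)) * sum(si) / N,
    Busyness = if (busyDen > 0) sum(pi * si) / busyDen else 0,
    Complexity = comp,
    Strength = str / (eps + sum(si)))
}

# All rigid offsets placing every ROI voxel inside the label, by full
# enumeration.
bruteValidOffsets <- function(maskArr, labelArr) {
  d <- dim(maskArr)
  coords <- which(maskArr, arr.ind = TRUE)
  valid <- NULL
  for (dz in -(d[1] - 1):(d[1] - 1))
    for (dy in -(d[2] - 1):(d[2] - 1))
      for (dx in -(d[3] - 1):(d[3] - 1)) {
        p <- sweep(coords, 2, c(dz, dy, dx), "+")
        if (any(p < 1) || any(p[, 1] > d[1]) || any(p[, 2] > d[2]) ||
            any(p[, 3] > d[3])) next
        if (all(labelArr[p])) valid <- rbind(valid, c(dz, dy, dx))
      }
  valid
}

# A small random ROI embedded in a random volume, for oracle-equivalence
# property tests.
makeSmallRoi <- function(seed, dims = c(3, 5, 5), nLevels = 4) {
  set.seed(seed)
  vol <- ImageVolume(array(stats::runif(prod(dims), -100, 100), dims))
  m <- array(stats::runif(prod(dims)) > 0.35, dims)
  if (sum(m) < 4) m[sample(prod(dims), 4)] <- TRUE
  mask <- RoiMask(m)
  list(vol = vol, mask = mask, q = quantizeRoi(vol, mask, nLevels))
}
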