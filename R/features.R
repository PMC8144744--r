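# IBSI-style first-order and texture feature mathematics.
#
# Grey levels are discretised with a fixed bin width anchored at the ROI
# minimum: g = floor((x - min) / bw) + 1. Texture matrices use 26-connected
# 3-D neighbourhoods at distance 1; GLCM and GLRLM are computed per unique
# direction (13 in 3-D) and feature values averaged across directions.
# The enabled set mirrors the common default of IBSI-compliant engines:
# 18 first order + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM = 93.

log2p <- function(p) ifelse(p > 0, log2(p), 0)

discretise_fixed_bin <- function(x, bin_width) {
  stopifnot(bin_width > 0, all(is.finite(x)))
  pmax(1L, as.integer(floor((x - min(x)) / bin_width)) + 1L)
}

# ---- first order (18) -------------------------------------------------------

firstorder_features <- function(x, bin_width, voxel_volume = 1) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  mid <- x[x >= p10 & x <= p90]
  g <- discretise_fixed_bin(x, bin_width)
  p <- tabulate(g) / n
  c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2p(p)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# ---- shared neighbourhood plumbing -----------------------------------------

# 13 unique direction offsets in 3-D (one of each +/- pair).
directions13 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
})

# grey-level array with NA outside the ROI
grey_array <- function(g_values, roi_idx, dims) {
  garr <- array(NA_integer_, dims)
  garr[roi_idx] <- g_values
  garr
}

shift_num <- function(arr, off) {
  dims <- dim(arr)
  out <- array(NA_integer_, dims)
  src <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) - off[a]
    i[i >= 1 & i <= dims[a]]
  })
  if (any(!lengths(src))) return(out)
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# ---- GLCM (24) --------------------------------------------------------------

glcm_matrix <- function(garr, off, ng) {
  nb <- shift_num(garr, off)
  ok <- !is.na(garr) & !is.na(nb)
  if (!any(ok)) return(NULL)
  i <- garr[ok]; j <- nb[ok]
  m <- matrix(0, ng, ng)
  tab <- table(factor(i, levels = 1:ng), factor(j, levels = 1:ng))
  m <- m + tab + t(tab)       # symmetric co-occurrence
  m / sum(m)
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng); J <- t(I)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) distributions
  kdiff <- 0:(ng - 1)
  pd <- vapply(kdiff, function(k) sum(p[abs(I - J) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  ps <- vapply(ksum, function(k) sum(p[(I + J) == k]), numeric(1))
  hx <- -sum(px * log2p(px)); hy <- -sum(py * log2p(py))
  hxy <- -sum(p * log2p(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2p(pxpy))
  hxy2 <- -sum(pxpy * log2p(pxpy))
  da <- sum(kdiff * pd)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 0 && sy > 0) (sum(I * J * p) - mux * muy) / (sx * sy) else 1
  mcc <- glcm_mcc(p, px, py)
  c(
    Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - mux - muy)^4 * p),
    ClusterShade = sum((I + J - mux - muy)^3 * p),
    ClusterTendency = sum((I + J - mux - muy)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2p(pd)),
    DifferenceVariance = sum((kdiff - da)^2 * pd),
    Id = sum(pd / (1 + kdiff)),
    Idm = sum(pd / (1 + kdiff^2)),
    Idmn = sum(pd / (1 + kdiff^2 / ng^2)),
    Idn = sum(pd / (1 + kdiff / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pd[-1] / kdiff[-1]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ksum * ps),
    SumEntropy = -sum(ps * log2p(ps)),
    SumSquares = sum((I - mux)^2 * p)
  )
}

glcm_mcc <- function(p, px, py) {
  ng <- nrow(p)
  if (ng == 1) return(1)
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  A <- p[keep, keep, drop = FALSE] / px[keep]
  B <- t(p[keep, keep, drop = FALSE]) / py[keep]
  Q <- A %*% B
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(0, ev[2]))
}

glcm_features <- function(garr, ng) {
  vals <- lapply(seq_len(nrow(directions13)), function(r) {
    m <- glcm_matrix(garr, directions13[r, ], ng)
    if (is.null(m)) NULL else glcm_features_one(m)
  })
  vals <- Filter(Negate(is.null), vals)
  if (!length(vals)) stop("no co-occurring voxel pairs in ROI")
  colMeans(do.call(rbind, vals))
}

# ---- GLRLM (16) -------------------------------------------------------------

# run-length matrix along one direction: traverse each lattice line, breaking
# runs at grey-level changes, ROI gaps, and non-adjacent positions
glrlm_matrix <- function(garr, off, ng) {
  dims <- dim(garr)
  idx <- which(!is.na(garr))
  if (!length(idx)) return(NULL)
  coords <- arrayInd(idx, dims)
  a <- which(off != 0)[1]
  s <- coords[, a] * sign(off[a])
  base <- coords - s %o% off  # constant along a line
  line <- (base[, 1] + 1000L) + (base[, 2] + 1000L) * 4000L + (base[, 3] + 1000L) * 16000000
  ord <- order(line, s)
  g <- garr[idx][ord]; line <- line[ord]; s <- s[ord]
  new_run <- c(TRUE, g[-1] != g[-length(g)] | line[-1] != line[-length(line)] |
                 s[-1] != s[-length(s)] + 1L)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_grey <- g[new_run]
  nr <- max(run_len)
  m <- matrix(0, ng, nr)
  for (k in seq_along(run_len)) m[run_grey[k], run_len[k]] <- m[run_grey[k], run_len[k]] + 1
  m
}

glrlm_features_one <- function(P, np) {
  nr_levels <- ncol(P)
  iv <- seq_len(nrow(P)); rv <- seq_len(nr_levels)
  Nr <- sum(P)
  p <- P / Nr
  pg <- rowSums(P); pr <- colSums(P)
  mu_i <- sum(rowSums(p) * iv); mu_r <- sum(colSums(p) * rv)
  I <- matrix(iv, nrow(P), nr_levels); Rm <- matrix(rv, nrow(P), nr_levels, byrow = TRUE)
  c(
    GrayLevelNonUniformity = sum(pg^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nr^2,
    GrayLevelVariance = sum(p * (I - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(P * I^2) / Nr,
    LongRunEmphasis = sum(P * Rm^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * I^2 * Rm^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * Rm^2 / I^2) / Nr,
    LowGrayLevelRunEmphasis = sum(P / I^2) / Nr,
    RunEntropy = -sum(p * log2p(p)),
    RunLengthNonUniformity = sum(pr^2) / Nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / Nr^2,
    RunPercentage = Nr / np,
    RunVariance = sum(p * (Rm - mu_r)^2),
    ShortRunEmphasis = sum(P / Rm^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * I^2 / Rm^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (I^2 * Rm^2)) / Nr
  )
}

glrlm_features <- function(garr, ng, np) {
  vals <- lapply(seq_len(nrow(directions13)), function(r) {
    m <- glrlm_matrix(garr, directions13[r, ], ng)
    if (is.null(m)) NULL else glrlm_features_one(m, np)
  })
  vals <- Filter(Negate(is.null), vals)
  colMeans(do.call(rbind, vals))
}

# ---- GLSZM (16) -------------------------------------------------------------

# 26-connected zones of constant grey level, by iterative minimum-label
# propagation (vectorised; converges in at most the largest zone diameter)
glszm_zones <- function(garr) {
  dims <- dim(garr)
  lab <- array(NA_real_, dims)
  roi <- !is.na(garr)
  lab[roi] <- which(roi)
  all_off <- rbind(directions13, -directions13)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(all_off))) {
      nb_lab <- shift_num(lab, all_off[r, ])
      nb_g <- shift_num(garr, all_off[r, ])
      upd <- roi & !is.na(nb_lab) & nb_g == garr & nb_lab < lab
      upd[is.na(upd)] <- FALSE
      if (any(upd)) {
        lab[upd] <- nb_lab[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  zones <- data.frame(lab = lab[roi], g = garr[roi])
  agg <- aggregate(rep(1L, nrow(zones)), by = list(lab = zones$lab, g = zones$g), FUN = sum)
  data.frame(grey = agg$g, size = agg$x)
}

glszm_features <- function(garr, ng, np) {
  z <- glszm_zones(garr)
  ns <- max(z$size)
  P <- matrix(0, ng, ns)
  for (k in seq_len(nrow(z))) P[z$grey[k], z$size[k]] <- P[z$grey[k], z$size[k]] + 1
  iv <- seq_len(ng); sv <- seq_len(ns)
  Nz <- sum(P)
  p <- P / Nz
  pg <- rowSums(P); pz <- colSums(P)
  I <- matrix(iv, ng, ns); S <- matrix(sv, ng, ns, byrow = TRUE)
  mu_i <- sum(p * I); mu_s <- sum(p * S)
  c(
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nz^2,
    GrayLevelVariance = sum(p * (I - mu_i)^2),
    HighGrayLevelZoneEmphasis = sum(P * I^2) / Nz,
    LargeAreaEmphasis = sum(P * S^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * I^2 * S^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * S^2 / I^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(P / I^2) / Nz,
    SizeZoneNonUniformity = sum(pz^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(pz^2) / Nz^2,
    SmallAreaEmphasis = sum(P / S^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * I^2 / S^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (I^2 * S^2)) / Nz,
    ZoneEntropy = -sum(p * log2p(p)),
    ZonePercentage = Nz / np,
    ZoneVariance = sum(p * (S - mu_s)^2)
  )
}

# ---- NGTDM (5) and GLDM (14) ------------------------------------------------

# per-voxel neighbourhood aggregates over the 26-neighbourhood
neighbourhood_stats <- function(garr) {
  roi <- !is.na(garr)
  dims <- dim(garr)
  nsum <- array(0, dims); ncount <- array(0, dims); ndep <- array(0, dims)
  all_off <- rbind(directions13, -directions13)
  for (r in seq_len(nrow(all_off))) {
    nb <- shift_num(garr, all_off[r, ])
    ok <- roi & !is.na(nb)
    nsum[ok] <- nsum[ok] + nb[ok]
    ncount[ok] <- ncount[ok] + 1
    dep <- ok & nb == garr
    dep[is.na(dep)] <- FALSE
    ndep[dep] <- ndep[dep] + 1
  }
  list(g = garr[roi], nsum = nsum[roi], ncount = ncount[roi], ndep = ndep[roi])
}

ngtdm_features <- function(nstats, ng) {
  has_nb <- nstats$ncount > 0
  g <- nstats$g[has_nb]
  A <- nstats$nsum[has_nb] / nstats$ncount[has_nb]
  N <- length(g)
  s <- vapply(seq_len(ng), function(i) sum(abs(g[g == i] - A[g == i])), numeric(1))
  n_i <- tabulate(g, nbins = ng)
  p <- n_i / N
  present <- which(n_i > 0)
  ngp <- length(present)
  iv <- seq_len(ng)
  coarse_den <- sum(p * s)
  pij_contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  for (i in present) for (j in present) {
    pij_contrast <- pij_contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  c(
    Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Complexity = complexity / N,
    Contrast = if (ngp > 1) pij_contrast / (ngp * (ngp - 1)) * sum(s) / N else 0,
    Strength = if (sum(s) > 0) strength_num / sum(s) else 0
  )
}

gldm_features <- function(nstats, ng) {
  g <- nstats$g
  j <- nstats$ndep + 1   # dependence size includes the centre voxel
  np <- length(g)
  nd <- max(j)
  P <- matrix(0, ng, nd)
  for (k in seq_len(np)) P[g[k], j[k]] <- P[g[k], j[k]] + 1
  iv <- seq_len(ng); jv <- seq_len(nd)
  Nz <- sum(P)
  p <- P / Nz
  pg <- rowSums(P); pd <- colSums(P)
  I <- matrix(iv, ng, nd); Jm <- matrix(jv, ng, nd, byrow = TRUE)
  mu_i <- sum(p * I); mu_j <- sum(p * Jm)
  c(
    DependenceEntropy = -sum(p * log2p(p)),
    DependenceNonUniformity = sum(pd^2) / Nz,
    DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    DependenceVariance = sum(p * (Jm - mu_j)^2),
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelVariance = sum(p * (I - mu_i)^2),
    HighGrayLevelEmphasis = sum(P * I^2) / Nz,
    LargeDependenceEmphasis = sum(P * Jm^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * I^2 * Jm^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * Jm^2 / I^2) / Nz,
    LowGrayLevelEmphasis = sum(P / I^2) / Nz,
    SmallDependenceEmphasis = sum(P / Jm^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * I^2 / Jm^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (I^2 * Jm^2)) / Nz
  )
}

# ---- the 93-feature panel ---------------------------------------------------

# All enabled features for one (image, ROI) pair; names "class|Feature".
compute_feature_panel <- function(values, roi_idx, dims, bin_width, voxel_volume) {
  x <- values[roi_idx]
  g <- discretise_fixed_bin(x, bin_width)
  ng <- max(g)
  garr <- grey_array(g, roi_idx, dims)
  np <- length(x)
  nstats <- neighbourhood_stats(garr)
  panel <- list(
    firstorder = firstorder_features(x, bin_width, voxel_volume),
    glcm = glcm_features(garr, ng),
    glrlm = glrlm_features(garr, ng, np),
    glszm = glszm_features(garr, ng, np),
    ngtdm = ngtdm_features(nstats, ng),
    gldm = gldm_features(nstats, ng)
  )
  unlist(lapply(names(panel), function(cl) {
    setNames(panel[[cl]], paste0(cl, "|", names(panel[[cl]])))
  }))
}
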