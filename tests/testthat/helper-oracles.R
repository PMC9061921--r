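# Literal brute-force transcriptions of the texture-matrix and feature
# definitions, written as plain loops over pixels and matrix cells. They are
# deliberately independent of the package implementation and serve as the
# reference in equivalence tests.

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                       `135` = c(-1L, -1L))

oracle_glcm <- function(sl, ng, dir) {
  off <- oracle_offsets[[dir]]
  C <- matrix(0, ng, ng)
  for (i in seq_len(nrow(sl))) for (j in seq_len(ncol(sl))) {
    if (sl[i, j] == 0) next
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(sl) || j2 < 1 || j2 > ncol(sl)) next
    if (sl[i2, j2] == 0) next
    C[sl[i, j], sl[i2, j2]] <- C[sl[i, j], sl[i2, j2]] + 1
  }
  C <- C + t(C)
  if (sum(C) > 0) C / sum(C) else C
}

oracle_glcm_features <- function(P, ng) {
  lg2 <- function(x) log(x, 2)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) { px[i] <- px[i] + P[i, j]
                                    py[j] <- py[j] + P[i, j] }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  psum <- numeric(2 * ng); pd <- numeric(ng)  # psum[k]=p_{x+y}(k); pd[k+1]=p_{x-y}(k)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  f <- c(autocorrelation = 0, cluster_prominence = 0, cluster_shade = 0,
         cluster_tendency = 0, contrast = 0, correlation = 0,
         difference_average = 0, difference_entropy = 0,
         difference_variance = 0, dissimilarity = 0, id = 0, idm = 0,
         idmn = 0, idn = 0, imc1 = 0, imc2 = 0, inverse_variance = 0,
         joint_average = mux, joint_energy = 0, joint_entropy = 0,
         joint_maximum = max(P), sum_average = 0, sum_entropy = 0,
         sum_squares = 0, sum_variance = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - mux - muy)^4 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mux - muy)^3 * p
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - mux - muy)^2 * p
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["id"] <- f["id"] + p / (1 + abs(i - j))
    f["idm"] <- f["idm"] + p / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + p / (1 + (i - j)^2 / ng^2)
    f["idn"] <- f["idn"] + p / (1 + abs(i - j) / ng)
    f["joint_energy"] <- f["joint_energy"] + p^2
    f["sum_squares"] <- f["sum_squares"] + (i - mux)^2 * p
    if (p > 0) f["joint_entropy"] <- f["joint_entropy"] - p * lg2(p)
  }
  for (k in 0:(ng - 1)) {
    p <- pd[k + 1]
    f["difference_average"] <- f["difference_average"] + k * p
    if (p > 0) f["difference_entropy"] <- f["difference_entropy"] - p * lg2(p)
    if (k > 0) f["inverse_variance"] <- f["inverse_variance"] + p / k^2
  }
  for (k in 0:(ng - 1))
    f["difference_variance"] <- f["difference_variance"] +
      (k - f["difference_average"])^2 * pd[k + 1]
  for (k in 2:(2 * ng)) {
    p <- psum[k]
    f["sum_average"] <- f["sum_average"] + k * p
    if (p > 0) f["sum_entropy"] <- f["sum_entropy"] - p * lg2(p)
  }
  for (k in 2:(2 * ng))
    f["sum_variance"] <- f["sum_variance"] +
      (k - f["sum_average"])^2 * psum[k]
  f["correlation"] <- if (sx > 0 && sy > 0)
    (f[["autocorrelation"]] - mux * muy) / (sx * sy) else 0
  hxy <- f[["joint_entropy"]]
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (P[i, j] > 0 && q > 0) hxy1 <- hxy1 - P[i, j] * lg2(q)
    if (q > 0) hxy2 <- hxy2 - q * lg2(q)
  }
  hx <- -sum(ifelse(px > 0, px * lg2(px), 0))
  hy <- -sum(ifelse(py > 0, py * lg2(py), 0))
  f["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  f["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f
}

oracle_glrlm <- function(sl, ng, dir) {
  off <- oracle_offsets[[dir]]
  nr <- nrow(sl); nc <- ncol(sl)
  runs <- list()
  visited <- matrix(FALSE, nr, nc)
  inb <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc
  for (i in 1:nr) for (j in 1:nc) {
    if (sl[i, j] == 0 || visited[i, j]) next
    # only start a run at a pixel whose backward neighbour does not continue it
    bi <- i - off[1]; bj <- j - off[2]
    if (inb(bi, bj) && sl[bi, bj] == sl[i, j]) next
    len <- 0L; ci <- i; cj <- j
    while (inb(ci, cj) && sl[ci, cj] == sl[i, j]) {
      visited[ci, cj] <- TRUE
      len <- len + 1L
      ci <- ci + off[1]; cj <- cj + off[2]
    }
    runs[[length(runs) + 1L]] <- c(sl[i, j], len)
  }
  mx <- max(1L, if (length(runs)) max(sapply(runs, `[`, 2)) else 1L)
  P <- matrix(0, ng, mx)
  for (r in runs) P[r[1], r[2]] <- P[r[1], r[2]] + 1
  P
}

# iterative min-label propagation: an algorithm distinct from the BFS used
# in the implementation
oracle_zone_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in 1:nr) for (j in 1:nc) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.integer(table(lab[mask]))
}

oracle_glszm <- function(sl, ng) {
  zones <- list()
  for (g in 1:ng) {
    if (!any(sl == g)) next
    for (s in oracle_zone_sizes(sl == g))
      zones[[length(zones) + 1L]] <- c(g, s)
  }
  mx <- max(1L, if (length(zones)) max(sapply(zones, `[`, 2)) else 1L)
  P <- matrix(0, ng, mx)
  for (z in zones) P[z[1], z[2]] <- P[z[1], z[2]] + 1
  P
}

oracle_rl_features <- function(P, np, names16) {
  ns <- sum(P)
  ni <- nrow(P); nj <- ncol(P)
  p <- P / ns
  mu_i <- 0; mu_j <- 0
  for (i in 1:ni) for (j in 1:nj) { mu_i <- mu_i + i * p[i, j]
                                    mu_j <- mu_j + j * p[i, j] }
  acc <- setNames(numeric(16), names16)
  rs <- numeric(ni); cs <- numeric(nj)
  for (i in 1:ni) for (j in 1:nj) {
    v <- P[i, j]
    rs[i] <- rs[i] + v; cs[j] <- cs[j] + v
    acc[1] <- acc[1] + v / j^2
    acc[2] <- acc[2] + v * j^2
    acc[8] <- acc[8] + (i - mu_i)^2 * p[i, j]
    acc[9] <- acc[9] + (j - mu_j)^2 * p[i, j]
    if (v > 0) acc[10] <- acc[10] - p[i, j] * log(p[i, j], 2)
    acc[11] <- acc[11] + v / i^2
    acc[12] <- acc[12] + v * i^2
    acc[13] <- acc[13] + v / (i^2 * j^2)
    acc[14] <- acc[14] + v * i^2 / j^2
    acc[15] <- acc[15] + v * j^2 / i^2
    acc[16] <- acc[16] + v * i^2 * j^2
  }
  acc[c(1, 2, 11:16)] <- acc[c(1, 2, 11:16)] / ns
  acc[3] <- sum(rs^2) / ns
  acc[4] <- sum(rs^2) / ns^2
  acc[5] <- sum(cs^2) / ns
  acc[6] <- sum(cs^2) / ns^2
  acc[7] <- ns / np
  acc
}

oracle_ngtdm <- function(sl, ng) {
  nr <- nrow(sl); nc <- ncol(sl)
  n <- numeric(ng); s <- numeric(ng)
  for (i in 1:nr) for (j in 1:nc) {
    if (sl[i, j] == 0) next
    tot <- 0; cnt <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (sl[ii, jj] > 0) { tot <- tot + sl[ii, jj]; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    g <- sl[i, j]
    n[g] <- n[g] + 1
    s[g] <- s[g] + abs(g - tot / cnt)
  }
  list(n = n, s = s)
}

oracle_ngtdm_features <- function(n, s, ng) {
  N <- sum(n)
  p <- n / N
  pres <- which(p > 0)
  ngp <- length(pres)
  den <- 0
  for (i in pres) den <- den + p[i] * s[i]
  coars <- if (den > 0) 1 / den else 1e6
  contr <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in pres) for (j in pres) acc <- acc + p[i] * p[j] * (i - j)^2
    contr <- acc / (ngp * (ngp - 1)) * sum(s) / N
  }
  bden <- 0
  for (i in pres) for (j in pres) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 0) den / bden else 0
  comp <- 0
  for (i in pres) for (j in pres)
    comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  comp <- comp / N
  stren <- 0
  if (sum(s) > 0) {
    acc <- 0
    for (i in pres) for (j in pres) acc <- acc + (p[i] + p[j]) * (i - j)^2
    stren <- acc / sum(s)
  }
  c(coarseness = coars, contrast = contr, busyness = busy,
    complexity = comp, strength = stren)
}

oracle_gldm <- function(sl, ng, alpha = 0) {
  nr <- nrow(sl); nc <- ncol(sl)
  P <- matrix(0, ng, 9)
  for (i in 1:nr) for (j in 1:nc) {
    if (sl[i, j] == 0) next
    d <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (sl[ii, jj] > 0 && abs(sl[ii, jj] - sl[i, j]) <= alpha) d <- d + 1L
    }
    P[sl[i, j], d + 1L] <- P[sl[i, j], d + 1L] + 1
  }
  P
}

# random ROI slice: rectangular grid with a random hole pattern, levels in
# 1..n_levels, at least min_pix ROI pixels
random_slice <- function(nr, nc, n_levels, roi_frac = 0.8) {
  repeat {
    sl <- matrix(sample(1:n_levels, nr * nc, replace = TRUE), nr, nc)
    hole <- matrix(runif(nr * nc) > roi_frac, nr, nc)
    sl[hole] <- 0L
    if (sum(sl > 0) >= 4) return(sl)
  }
}
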