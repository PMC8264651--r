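# Independent brute-force oracles. These are deliberately written as plain
# loops over voxels and enumerations of neighbours/runs/zones, sharing no
# code with the package implementations they check.

# random discretized VOI on a small grid
make_disc <- function(dim, n_g, seed, p_mask = 1) {
  set.seed(seed)
  lev <- array(sample.int(n_g, prod(dim), replace = TRUE), dim)
  if (p_mask < 1) {
    drop <- array(runif(prod(dim)) > p_mask, dim)
    # keep at least two voxels
    if (sum(!drop) < 2) drop[seq_len(2)] <- FALSE
    lev[drop] <- NA_integer_
  }
  structure(list(levels = lev, n_bins = as.integer(n_g),
                 range = c(0, 1), spacing = c(1, 1, 1)),
            class = "discretized_voi")
}

oracle_offsets26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx != 0 || dy != 0 || dz != 0) out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

ok_at <- function(lev, p) {
  d <- dim(lev)
  all(p >= 1) && all(p <= d) && !is.na(lev[p[1], p[2], p[3]])
}

# symmetric merged GLCM by enumerating every ordered neighbour pair
oracle_glcm_matrix <- function(lev, n_g) {
  d <- dim(lev)
  M <- matrix(0, n_g, n_g)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z])) next
    for (off in oracle_offsets26()) {
      q <- c(x, y, z) + off
      if (ok_at(lev, q)) {
        M[lev[x, y, z], lev[q[1], q[2], q[3]]] <-
          M[lev[x, y, z], lev[q[1], q[2], q[3]]] + 1
      }
    }
  }
  M
}

oracle_glcm_features <- function(lev, n_g) {
  P <- oracle_glcm_matrix(lev, n_g)
  P <- P / sum(P)
  ja <- 0; sa <- 0; ac <- 0
  hxy <- 0; hxy1 <- 0
  px <- rowSums(P); py <- colSums(P)
  for (i in seq_len(n_g)) for (j in seq_len(n_g)) {
    p <- P[i, j]
    ja <- ja + i * p
    sa <- sa + (i + j) * p
    ac <- ac + i * j * p
    if (p > 0) {
      hxy <- hxy - p * log2(p)
      hxy1 <- hxy1 - p * log2(px[i] * py[j])
    }
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  list(GLCM_222_1JointAverage = ja, GLCM_222_1SumAverage = sa,
       GLCM_222_1AutoCorrelation = ac, GLCM_222_1InformationMeasureCor1 = imc1)
}

# run-length matrix by walking maximal runs voxel by voxel
oracle_glrlm_matrix <- function(lev, n_g, directions) {
  d <- dim(lev)
  R <- matrix(0, n_g, max(d))
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      p <- c(x, y, z)
      if (!ok_at(lev, p)) next
      l <- lev[x, y, z]
      prev <- p - off
      if (ok_at(lev, prev) && lev[prev[1], prev[2], prev[3]] == l) next
      len <- 1
      q <- p + off
      while (ok_at(lev, q) && lev[q[1], q[2], q[3]] == l) {
        len <- len + 1
        q <- q + off
      }
      R[l, len] <- R[l, len] + 1
    }
  }
  R
}

oracle_glrlm_features <- function(lev, n_g, directions) {
  R <- oracle_glrlm_matrix(lev, n_g, directions)
  nr <- sum(R)
  nv <- sum(!is.na(lev))
  sre <- lre <- hgl <- srh <- lrh <- 0
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    sre <- sre + R[i, l] / l^2
    lre <- lre + R[i, l] * l^2
    hgl <- hgl + R[i, l] * i^2
    srh <- srh + R[i, l] * i^2 / l^2
    lrh <- lrh + R[i, l] * i^2 * l^2
  }
  list(GLRLM_ShortRunEmphasis = sre / nr, GLRLM_LongRunEmphasis = lre / nr,
       GLRLM_HighGLRunEmpha = hgl / nr, GLRLM_ShortRunHighGLEmpha = srh / nr,
       GLRLM_LongRunHighGLEmpha = lrh / nr,
       GLRLM_GLNonuniformity = sum(rowSums(R)^2) / nr,
       GLRLM_RLNonuniformity = sum(colSums(R)^2) / nr,
       GLRLM_RunPercentage = nr / (nv * nrow(directions)))
}

# zones by explicit stack-based flood fill (26-connectivity, equal level)
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    l <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members[[length(members) + 1]] <- p
      for (off in oracle_offsets26()) {
        q <- p + off
        if (ok_at(lev, q) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == l) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- list(level = l, members = members)
  }
  zones
}

# Chebyshev distance of a voxel to the nearest background position, where
# everything outside the array also counts as background
oracle_border_distance <- function(lev, p) {
  d <- dim(lev)
  best <- Inf
  for (x in 0:(d[1] + 1)) for (y in 0:(d[2] + 1)) for (z in 0:(d[3] + 1)) {
    inside <- x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3]
    if (inside && !is.na(lev[x, y, z])) next
    best <- min(best, max(abs(c(x, y, z) - p)))
  }
  best
}

oracle_glszm_features <- function(lev) {
  zs <- oracle_zones(lev)
  nz <- length(zs)
  lvls <- vapply(zs, function(z) z$level, numeric(1))
  sizes <- vapply(zs, function(z) length(z$members), numeric(1))
  list(GLSZM_LargeZoneHighGLEmpha = sum(lvls^2 * sizes^2) / nz,
       GLSZM_GLNonuniformity = sum(table(lvls)^2) / nz)
}

oracle_gldzm_features <- function(lev) {
  zs <- oracle_zones(lev)
  nz <- length(zs)
  lvls <- vapply(zs, function(z) z$level, numeric(1))
  dists <- vapply(zs, function(z) {
    min(vapply(z$members, function(p) oracle_border_distance(lev, p),
               numeric(1)))
  }, numeric(1))
  list(GLDZM_GLNonuniformity = sum(table(lvls)^2) / nz,
       GLDZM_ZDNonuniformity = sum(table(dists)^2) / nz)
}

oracle_ngldm_features <- function(lev) {
  d <- dim(lev)
  iv <- c(); kv <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z])) next
    k <- 0
    for (off in oracle_offsets26()) {
      q <- c(x, y, z) + off
      if (ok_at(lev, q) && lev[q[1], q[2], q[3]] == lev[x, y, z]) k <- k + 1
    }
    iv <- c(iv, lev[x, y, z]); kv <- c(kv, k)
  }
  ns <- length(iv)
  list(NGLD_HighGLCountEmpha = sum(iv^2) / ns,
       NGLD_HighDepenHighFLEmpha = sum(iv^2 * kv^2) / ns,
       NGLD_GLNonuniformity = sum(table(iv)^2) / ns,
       NGLD_DepCountNonuniformity = sum(table(kv)^2) / ns)
}

oracle_ngtdm_coarseness <- function(lev, n_g, eps = 1e-6) {
  d <- dim(lev)
  iv <- c(); diffs <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z])) next
    nb <- c()
    for (off in oracle_offsets26()) {
      q <- c(x, y, z) + off
      if (ok_at(lev, q)) nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    iv <- c(iv, lev[x, y, z])
    diffs <- c(diffs, abs(lev[x, y, z] - mean(nb)))
  }
  n <- length(iv)
  tot <- 0
  for (l in unique(iv)) {
    tot <- tot + (sum(iv == l) / n) * sum(diffs[iv == l])
  }
  1 / (eps + tot)
}

# voxel centres within radius of a centre voxel, by triple loop
oracle_sphere_mean <- function(arr, spacing, centre, radius) {
  d <- dim(arr)
  vals <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    dist <- sqrt(sum(((c(x, y, z) - centre) * spacing)^2))
    if (dist <= radius + 1e-9) vals <- c(vals, arr[x, y, z])
  }
  mean(vals)
}

# ICC(A,1) mean squares taken from an anova(lm(...)) decomposition
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::lm(y ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# direct-formula first-order statistics on a vector
oracle_intensity <- function(x) {
  n <- length(x)
  q <- quantile(x, c(.10, .25, .50, .75, .90), names = FALSE)
  xr <- x[x >= q[1] & x <= q[5]]
  m2 <- sum((x - mean(x))^2) / n
  list(
    ID_Mean = sum(x) / n,
    ID_Variance = m2,
    ID_Median = median(x),
    ID_Min = min(x),
    ID_Max = max(x),
    ID_10thPercentile = q[1],
    ID_90thPercentile = q[5],
    ID_InterquartileRange = q[4] - q[2],
    ID_Range = max(x) - min(x),
    ID_MeanAbsoluteDeviation = sum(abs(x - mean(x))) / n,
    ID_RobustMeanAbsoluteDeviation = sum(abs(xr - mean(xr))) / length(xr),
    ID_MedianAbsoluteDeviation = sum(abs(x - median(x))) / n,
    ID_CoefficientOfVariation = sqrt(m2) / mean(x),
    ID_QuartileCoefficientOfDispersion = (q[4] - q[2]) / (q[4] + q[2]),
    ID_Energy = sum(x^2),
    ID_RootMeanSquare = sqrt(sum(x^2) / n),
    ID_Skewness = (sum((x - mean(x))^3) / n) / m2^1.5,
    ID_Kurtosis = (sum((x - mean(x))^4) / n) / m2^2 - 3
  )
}
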