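# Texture-matrix feature families on the discretized VOI. All matrices use
# the 13 unique 3D directions at Chebyshev distance 1 (26-neighbourhood),
# merged into a single matrix before feature computation.

#' Unique 3D neighbourhood directions
#'
#' The 13 direction offsets covering one half of the 26-neighbourhood; the
#' other half is obtained by negation.
#'
#' @return Integer matrix with 13 rows and columns `dx`, `dy`, `dz`.
#' @export
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

all_neighbour_offsets <- function() {
  d <- texture_directions()
  rbind(d, -d)
}

# level of the neighbour at `off`, NA where out of mask/volume
neighbour_levels <- function(lev, off) shift_array(lev, off, fill = NA_integer_)

#' Gray-level co-occurrence matrix features
#'
#' Counts co-occurrences of gray-level pairs over all 13 unique directions at
#' distance 1, symmetrized (both voxel orders) and merged into one matrix
#' normalized to probabilities `p(i, j)`. Entropies use log base 2 with the
#' `0 * log 0 = 0` convention; for a constant VOI the information measure of
#' correlation is defined as 0.
#'
#' @param disc a `discretized_voi` from [discretize_fbn()].
#' @param directions integer matrix of direction offsets (default all 13).
#' @return Named list: `GLCM_222_1JointAverage`, `GLCM_222_1SumAverage`,
#'   `GLCM_222_1AutoCorrelation`, `GLCM_222_1InformationMeasureCor1`.
#' @export
glcm_features <- function(disc, directions = texture_directions()) {
  M <- glcm_matrix(disc, directions)
  if (sum(M) == 0) {
    stop("no valid voxel pairs for GLCM computation", call. = FALSE)
  }
  P <- M / sum(M)
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  plog <- function(p) ifelse(p > 0, log2(p), 0)
  hxy <- -sum(P * plog(P))
  hxy1 <- -sum(P * plog(outer(px, py)))
  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  list(
    GLCM_222_1JointAverage = sum(i * P),
    GLCM_222_1SumAverage = sum((i + j) * P),
    GLCM_222_1AutoCorrelation = sum(i * j * P),
    GLCM_222_1InformationMeasureCor1 =
      if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  )
}

#' @rdname glcm_features
#' @export
glcm_matrix <- function(disc, directions = texture_directions()) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  ng <- disc$n_bins
  M <- matrix(0, ng, ng)
  for (k in seq_len(nrow(directions))) {
    nb <- neighbour_levels(lev, directions[k, ])
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    idx <- lev[ok] + ng * (nb[ok] - 1L)
    M <- M + matrix(tabulate(idx, nbins = ng * ng), ng, ng)
  }
  M + t(M)
}

#' Gray-level run-length matrix features
#'
#' Maximal same-level runs are enumerated along each direction and the
#' run-length matrices merged before feature computation. With the merged
#' convention the run percentage is `N_runs / (N_voxels * n_directions)`.
#'
#' @inheritParams glcm_features
#' @return Named list of the 8 `GLRLM_*` features.
#' @export
glrlm_features <- function(disc, directions = texture_directions()) {
  R <- glrlm_matrix(disc, directions)
  nr <- sum(R)
  nv <- sum(!is.na(disc$levels))
  i <- row(R); l <- col(R)
  list(
    GLRLM_ShortRunEmphasis = sum(R / l^2) / nr,
    GLRLM_LongRunEmphasis = sum(R * l^2) / nr,
    GLRLM_HighGLRunEmpha = sum(R * i^2) / nr,
    GLRLM_ShortRunHighGLEmpha = sum(R * i^2 / l^2) / nr,
    GLRLM_LongRunHighGLEmpha = sum(R * i^2 * l^2) / nr,
    GLRLM_GLNonuniformity = sum(rowSums(R)^2) / nr,
    GLRLM_RLNonuniformity = sum(colSums(R)^2) / nr,
    GLRLM_RunPercentage = nr / (nv * nrow(directions))
  )
}

#' @rdname glrlm_features
#' @export
glrlm_matrix <- function(disc, directions = texture_directions()) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  d <- dim(lev)
  ng <- disc$n_bins
  in_mask <- !is.na(lev)
  max_len <- max(d)
  R <- matrix(0, ng, max_len)
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ]
    nxt <- neighbour_levels(lev, off)
    prv <- neighbour_levels(lev, -off)
    cont <- in_mask & !is.na(nxt) & (lev == nxt)
    cont[is.na(cont)] <- FALSE
    start <- in_mask & (is.na(prv) | lev != prv)
    start[is.na(start)] <- TRUE
    start <- in_mask & start
    sidx <- which(start)
    if (!length(sidx)) next
    lv <- lev[sidx]
    cur <- which(start, arr.ind = TRUE)
    alive <- seq_along(sidx)
    len <- rep(1L, length(sidx))
    while (length(alive)) {
      lin <- cur[, 1] + d[1] * (cur[, 2] - 1L) + d[1] * d[2] * (cur[, 3] - 1L)
      go <- cont[lin]
      alive <- alive[go]
      if (!length(alive)) break
      len[alive] <- len[alive] + 1L
      cur <- cur[go, , drop = FALSE]
      cur[, 1] <- cur[, 1] + off[1]
      cur[, 2] <- cur[, 2] + off[2]
      cur[, 3] <- cur[, 3] + off[3]
    }
    R <- R + matrix(tabulate(lv + ng * (len - 1L), nbins = ng * max_len),
                    ng, max_len)
  }
  R
}

# 26-connected same-level zones. Returns a tibble with one row per zone:
# level, size (voxels) and min Chebyshev distance to the VOI border.
gray_level_zones <- function(disc, with_distance = FALSE) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  d <- dim(lev)
  in_idx <- which(!is.na(lev))
  vmap <- integer(length(lev))
  vmap[in_idx] <- seq_along(in_idx)
  edges <- list()
  dirs <- texture_directions()
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    nb <- neighbour_levels(lev, off)
    ok <- !is.na(lev) & !is.na(nb) & (lev == nb)
    ok[is.na(ok)] <- FALSE
    from <- which(ok)
    if (!length(from)) next
    off_lin <- off[1] + d[1] * off[2] + d[1] * d[2] * off[3]
    edges[[k]] <- cbind(vmap[from], vmap[from + off_lin])
  }
  ed <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(in_idx), directed = FALSE)
  if (!is.null(ed) && nrow(ed)) g <- igraph::add_edges(g, t(ed))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  zl <- lev[in_idx][match(seq_along(sizes), comp)]
  out <- tibble::tibble(level = zl, size = sizes)
  if (with_distance) {
    D <- border_distance_map(!is.na(lev))
    out$distance <- as.integer(tapply(D[in_idx], comp, min))
  }
  out
}

# Chebyshev distance (in voxels) of every in-mask voxel to the VOI border;
# border voxels (any 26-neighbour outside the mask or the volume) have
# distance 1. Iterative peeling; the 3x3x3 box erosion is separable into
# three axial min-filters.
border_distance_map <- function(in_mask) {
  D <- array(NA_integer_, dim(in_mask))
  cur <- in_mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    interior <- cur
    for (ax in 1:3) {
      off <- c(0L, 0L, 0L)
      off[ax] <- 1L
      interior <- interior & shift_array(interior, off, fill = FALSE) &
        shift_array(interior, -off, fill = FALSE)
    }
    D[cur & !interior] <- k
    cur <- interior
  }
  D
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level.
#'
#' @inheritParams glcm_features
#' @param zones optional precomputed zone table from an internal call (lets
#'   the size-zone and distance-zone families share one labelling pass).
#' @return Named list: `GLSZM_LargeZoneHighGLEmpha`, `GLSZM_GLNonuniformity`.
#' @export
glszm_features <- function(disc, zones = NULL) {
  z <- if (is.null(zones)) gray_level_zones(disc) else zones
  nz <- nrow(z)
  list(
    GLSZM_LargeZoneHighGLEmpha = sum(z$level^2 * z$size^2) / nz,
    GLSZM_GLNonuniformity = sum(table(z$level)^2) / nz
  )
}

#' Gray-level distance-zone matrix features
#'
#' Same zones as [glszm_features()], indexed by the per-zone minimum
#' Chebyshev distance (in voxels) to the VOI border.
#'
#' @inheritParams glcm_features
#' @param zones optional precomputed zone table (must include `distance`).
#' @return Named list: `GLDZM_GLNonuniformity`, `GLDZM_ZDNonuniformity`.
#' @export
gldzm_features <- function(disc, zones = NULL) {
  z <- if (is.null(zones)) gray_level_zones(disc, with_distance = TRUE) else zones
  stopifnot("distance" %in% names(z))
  nz <- nrow(z)
  list(
    GLDZM_GLNonuniformity = sum(table(z$level)^2) / nz,
    GLDZM_ZDNonuniformity = sum(table(z$distance)^2) / nz
  )
}

#' Neighbouring gray-level dependence matrix features
#'
#' For each in-mask voxel the dependence count is the number of in-mask
#' 26-neighbours with the same gray level (coarseness threshold alpha = 0).
#' Every in-mask voxel contributes one matrix entry.
#'
#' @inheritParams glcm_features
#' @return Named list of the four `NGLD_*` features.
#' @export
ngldm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  in_mask <- !is.na(lev)
  dep <- array(0L, dim(lev))
  offs <- all_neighbour_offsets()
  for (i in seq_len(nrow(offs))) {
    nb <- neighbour_levels(lev, offs[i, ])
    same <- in_mask & !is.na(nb) & (lev == nb)
    same[is.na(same)] <- FALSE
    dep <- dep + same
  }
  iv <- lev[in_mask]
  kv <- dep[in_mask]
  ns <- length(iv)
  list(
    NGLD_HighGLCountEmpha = sum(iv^2) / ns,
    NGLD_HighDepenHighFLEmpha = sum(iv^2 * kv^2) / ns,
    NGLD_GLNonuniformity = sum(table(iv)^2) / ns,
    NGLD_DepCountNonuniformity = sum(table(kv)^2) / ns
  )
}

#' Neighbourhood gray-tone difference coarseness
#'
#' For each in-mask voxel with at least one in-mask 26-neighbour, the
#' neighbourhood average gray level is computed; `s_i` sums the absolute
#' differences from that average over all voxels of level `i`. Coarseness is
#' `1 / (eps + sum_i p_i s_i)` with `eps = 1e-6` guarding the constant-VOI
#' case.
#'
#' @inheritParams glcm_features
#' @param eps guard value for zero total difference.
#' @return A single numeric value (`NID_Coarseness`).
#' @export
ngtdm_coarseness <- function(disc, eps = 1e-6) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  in_mask <- !is.na(lev)
  nb_sum <- array(0, dim(lev))
  nb_cnt <- array(0L, dim(lev))
  offs <- all_neighbour_offsets()
  for (i in seq_len(nrow(offs))) {
    nb <- neighbour_levels(lev, offs[i, ])
    has <- !is.na(nb)
    nb_sum[has] <- nb_sum[has] + nb[has]
    nb_cnt <- nb_cnt + has
  }
  use <- in_mask & nb_cnt > 0
  avg <- nb_sum[use] / nb_cnt[use]
  iv <- lev[use]
  n <- length(iv)
  # s_i sums |i - neighbourhood average| over the level-i voxels, so the
  # population term is sum_i (n_i / n) * s_i / n_i * n_i = (n_i / n) * s_i
  si <- tapply(abs(iv - avg), iv, sum)
  ni <- tabulate(iv, nbins = disc$n_bins)
  lv <- as.integer(names(si))
  tot <- sum((ni[lv] / n) * si)
  1 / (eps + tot)
}
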