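#' Texture matrices on a 2D discretized ROI slice
#'
#' All matrices operate on a single axial slice holding integer grey levels
#' in `1..n_levels` with 0 marking background. Neighbourhoods use a
#' Chebyshev distance of 1. Runs, zones and dependences are confined to ROI
#' pixels: a background pixel breaks a run, is never part of a zone, and is
#' not counted as a neighbour (it is ignored, not treated as level 0).
#'
#' In-plane directions for GLCM/GLRLM, as (row, col) offsets:
#' 0 deg = (0,1), 45 deg = (-1,1), 90 deg = (-1,0), 135 deg = (-1,-1).
#'
#' @name texture-matrices
NULL

#' The four in-plane directions
#' @return list of integer (drow, dcol) offsets named by angle.
#' @export
inplane_directions <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

# shifted-copy helper: returns cbind(level at p, level at p+offset) for all
# pixel pairs where both endpoints are inside the grid
.pair_levels <- function(slice, off) {
  nr <- nrow(slice); nc <- ncol(slice)
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- slice[r0, c0, drop = FALSE]
  b <- slice[r0 + off[1], c0 + off[2], drop = FALSE]
  cbind(as.vector(a), as.vector(b))
}

#' Grey-level co-occurrence matrix (GLCM)
#'
#' Counts co-occurring level pairs at distance 1 along one direction, both
#' endpoints inside the ROI, symmetrized by adding the transpose, then
#' normalized to unit mass.
#'
#' @param slice integer matrix, levels 1..n_levels, 0 = background.
#' @param n_levels number of grey levels of the discretization.
#' @param direction angle as character (`"0"`, `"45"`, `"90"`, `"135"`).
#' @return object of class `texture_matrix` (family `"glcm"`): normalized
#'   matrix `p`, raw counts, `n_levels`.
#' @export
glcm_matrix <- function(slice, n_levels, direction = "0") {
  off <- inplane_directions()[[as.character(direction)]]
  if (is.null(off)) stop("unknown direction: ", direction)
  pr <- .pair_levels(slice, off)
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0, , drop = FALSE]
  counts <- matrix(0, n_levels, n_levels)
  if (nrow(pr)) {
    tb <- table(factor(pr[, 1], levels = 1:n_levels),
                factor(pr[, 2], levels = 1:n_levels))
    counts <- matrix(as.numeric(tb), n_levels, n_levels)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  structure(list(family = "glcm", counts = counts,
                 p = if (tot > 0) counts / tot else counts,
                 n_levels = n_levels, direction = as.character(direction)),
            class = "texture_matrix")
}

# split one line of levels into maximal constant runs inside the ROI
.line_runs <- function(v) {
  r <- rle(v)
  keep <- r$values > 0
  cbind(level = r$values[keep], length = r$lengths[keep])
}

# extract the lines of a matrix along a direction offset
.direction_lines <- function(slice, off) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (identical(off, c(0L, 1L))) {
    lapply(seq_len(nr), function(i) slice[i, ])
  } else if (identical(off, c(-1L, 0L))) {
    lapply(seq_len(nc), function(j) slice[, j])
  } else if (identical(off, c(-1L, 1L))) {
    # anti-diagonals, traversed up-right
    lapply(seq_len(nr + nc - 1L), function(s) {
      i <- min(nr, s):max(1L, s - nc + 1L)
      j <- s + 1L - i
      slice[cbind(i, j)]
    })
  } else if (identical(off, c(-1L, -1L))) {
    # main diagonals, traversed up-left
    lapply(seq(-(nc - 1L), nr - 1L), function(d) {
      i <- max(1L, d + 1L):min(nr, nc + d)
      j <- i - d
      slice[cbind(rev(i), rev(j))]
    })
  } else stop("unknown offset")
}

#' Grey-level run-length matrix (GLRLM)
#'
#' Counts maximal constant-level runs along one direction; runs break at
#' background pixels and at the ROI boundary.
#'
#' @inheritParams glcm_matrix
#' @return `texture_matrix` (family `"glrlm"`): counts `n_levels x max_run`,
#'   plus `n_pixels`, the in-ROI pixel count of the slice.
#' @export
glrlm_matrix <- function(slice, n_levels, direction = "0") {
  off <- inplane_directions()[[as.character(direction)]]
  if (is.null(off)) stop("unknown direction: ", direction)
  runs <- do.call(rbind, lapply(.direction_lines(slice, off), .line_runs))
  np <- sum(slice > 0)
  max_run <- max(1L, if (length(runs)) max(runs[, "length"]) else 1L)
  counts <- matrix(0, n_levels, max_run)
  if (length(runs))
    for (k in seq_len(nrow(runs)))
      counts[runs[k, 1], runs[k, 2]] <- counts[runs[k, 1], runs[k, 2]] + 1
  structure(list(family = "glrlm", counts = counts, n_levels = n_levels,
                 n_pixels = np, direction = as.character(direction)),
            class = "texture_matrix")
}

# 8-connected component labelling of a logical matrix; returns component sizes
.zone_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- length(sizes) + 1L
    stack <- start
    lab[start] <- comp
    n <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      n <- n + 1L
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      ni <- i + nb$dr; nj <- j + nb$dc
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      cand <- (nj[ok] - 1L) * nr + ni[ok]
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- comp
        stack <- c(stack, cand)
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

#' Grey-level size-zone matrix (GLSZM)
#'
#' Counts 8-connected zones of equal grey level within the ROI, by level and
#' zone size. Direction-free.
#'
#' @inheritParams glcm_matrix
#' @return `texture_matrix` (family `"glszm"`): counts `n_levels x max_size`,
#'   plus `n_pixels`.
#' @export
glszm_matrix <- function(slice, n_levels) {
  np <- sum(slice > 0)
  zl <- list()
  for (g in sort(unique(slice[slice > 0]))) {
    sz <- .zone_sizes(slice == g)
    if (length(sz)) zl[[length(zl) + 1L]] <- cbind(level = g, size = sz)
  }
  zones <- do.call(rbind, zl)
  max_sz <- max(1L, if (length(zones)) max(zones[, "size"]) else 1L)
  counts <- matrix(0, n_levels, max_sz)
  if (length(zones))
    for (k in seq_len(nrow(zones)))
      counts[zones[k, 1], zones[k, 2]] <- counts[zones[k, 1], zones[k, 2]] + 1
  structure(list(family = "glszm", counts = counts, n_levels = n_levels,
                 n_pixels = np),
            class = "texture_matrix")
}

# per-pixel sum and count of in-ROI 8-neighbour levels
.neighbour_stats <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- slice
  nsum <- matrix(0, nr, nc); ncnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    nsum <- nsum + sh
    ncnt <- ncnt + (sh > 0)
  }
  list(sum = nsum, count = ncnt)
}

#' Neighbourhood grey-tone difference matrix (NGTDM)
#'
#' For each level i: `n_i` = number of ROI pixels of level i having at least
#' one in-ROI 8-neighbour, and `s_i` = summed absolute difference between i
#' and the mean level of those valid neighbours.
#'
#' @inheritParams glcm_matrix
#' @return `texture_matrix` (family `"ngtdm"`): vectors `n`, `s` indexed by
#'   level, plus `n_pixels` (= sum of `n`).
#' @export
ngtdm_matrix <- function(slice, n_levels) {
  st <- .neighbour_stats(slice)
  roi <- slice > 0 & st$count > 0
  lev <- slice[roi]
  diffs <- abs(lev - st$sum[roi] / st$count[roi])
  n <- as.numeric(tabulate(lev, nbins = n_levels))
  s <- numeric(n_levels)
  if (length(lev)) {
    agg <- tapply(diffs, factor(lev, levels = 1:n_levels), sum)
    s[!is.na(agg)] <- agg[!is.na(agg)]
  }
  structure(list(family = "ngtdm", n = n, s = s, n_levels = n_levels,
                 n_pixels = sum(n)),
            class = "texture_matrix")
}

#' Grey-level dependence matrix (GLDM)
#'
#' The dependence of an ROI pixel is the number of its in-ROI 8-neighbours
#' whose level differs by at most `alpha`. Counts are indexed by
#' (level, dependence + 1); every ROI pixel contributes, including isolated
#' ones (dependence 0).
#'
#' @inheritParams glcm_matrix
#' @param alpha dependence tolerance on the level difference.
#' @return `texture_matrix` (family `"gldm"`): counts `n_levels x 9`,
#'   column k holding dependence k-1.
#' @export
gldm_matrix <- function(slice, n_levels, alpha = 0) {
  nr <- nrow(slice); nc <- ncol(slice)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- slice
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    dep <- dep + (sh > 0 & abs(sh - slice) <= alpha)
  }
  roi <- slice > 0
  counts <- matrix(0, n_levels, 9L)
  if (any(roi)) {
    tb <- table(factor(slice[roi], levels = 1:n_levels),
                factor(dep[roi], levels = 0:8))
    counts <- matrix(as.numeric(tb), n_levels, 9L)
  }
  structure(list(family = "gldm", counts = counts, n_levels = n_levels,
                 alpha = alpha),
            class = "texture_matrix")
}

#' Build a texture matrix of any family
#'
#' Dispatcher over the five families; directional families require
#' `direction`.
#'
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @inheritParams glcm_matrix
#' @param min_slice_pixels minimum ROI pixel count for the slice.
#' @param ... passed to the family builder.
#' @export
build_texture_matrix <- function(family, slice, n_levels, direction = "0",
                                 min_slice_pixels = 2, ...) {
  if (sum(slice > 0) < min_slice_pixels)
    stop("slice has fewer ROI pixels than required (", min_slice_pixels, ")")
  switch(match.arg(family, c("glcm", "glrlm", "glszm", "ngtdm", "gldm")),
         glcm = glcm_matrix(slice, n_levels, direction),
         glrlm = glrlm_matrix(slice, n_levels, direction),
         glszm = glszm_matrix(slice, n_levels),
         ngtdm = ngtdm_matrix(slice, n_levels),
         gldm = gldm_matrix(slice, n_levels, ...))
}
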