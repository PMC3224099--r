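## Relevance scoring between TFA profiles and gene expression profiles
## across conditions: Pearson correlation, or mutual information estimated
## by Darbellay-Vajda adaptive partitioning of the rank-transformed sample.

#' Pearson relevance score matrix between TFAs and genes
#'
#' Entry (j, i) is the sample Pearson correlation between the activity
#' profile of TF j and the expression profile of gene i across conditions.
#' Zero-variance profiles score 0 (a constant profile carries no regulatory
#' signal), with a warning.
#'
#' @param tfa TFA matrix (TFs x conditions).
#' @param er Expression matrix (genes x conditions); condition columns must
#'   match \code{tfa}'s exactly and in order.
#' @return Score matrix (TFs x genes) with entries in [-1, 1].
#' @export
pearson_score_matrix <- function(tfa, er) {
  stopifnot(identical(colnames(tfa), colnames(er)))
  if (ncol(er) < 3L) stop("need at least 3 conditions for correlation")
  scores <- suppressWarnings(stats::cor(t(tfa), t(er)))
  if (anyNA(scores)) {
    warning("zero-variance profile(s); their correlations set to 0")
    scores[is.na(scores)] <- 0
  }
  dimnames(scores) <- list(rownames(tfa), rownames(er))
  scores
}

# Recursive adaptive partition of the rank-transformed sample. Cells are
# half-open rectangles (xlo, xhi] x (ylo, yhi] in rank space, split into 4
# sub-cells at the rectangle midpoints — marginally equiprobable cut points,
# since global ranks are uniform — so under the independence null the
# expected sub-cell counts are proportional to sub-rectangle areas. A split
# is kept when the first-order chi-square statistic (4 cells) exceeds `chi2`
# or the second-order statistic (the 4 x 4 midpoint grid, 15 df) exceeds
# `chi2_2`; the deeper test catches dependence too weak to unbalance a
# single 4-way split. Every occupied sub-cell must hold >= `min_cell`
# points. Returns the terminal cells (point count + rectangle bounds).
apmi_partition <- function(rx, ry, chi2, min_cell, chi2_2 = 24.996) {
  M <- length(rx)
  cells <- list()
  stack <- list(list(idx = seq_len(M), xlo = 0, xhi = M, ylo = 0, yhi = M))
  while (length(stack) > 0L) {
    cell <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- cell$idx
    n <- length(idx)
    terminal <- TRUE
    mx <- floor((cell$xlo + cell$xhi) / 2)
    my <- floor((cell$ylo + cell$yhi) / 2)
    if (n >= 4L && mx > cell$xlo && mx < cell$xhi &&
        my > cell$ylo && my < cell$yhi) {
      left <- rx[idx] <= mx
      low <- ry[idx] <= my
      counts <- c(sum(left & low), sum(!left & low),
                  sum(left & !low), sum(!left & !low))
      wx <- c(mx - cell$xlo, cell$xhi - mx)
      wy <- c(my - cell$ylo, cell$yhi - my)
      areas <- as.vector(outer(wx, wy))
      e4 <- n * areas / sum(areas)
      accept <- sum((counts - e4)^2 / e4) > chi2
      if (!accept) {
        qx <- c(cell$xlo, floor((cell$xlo + mx) / 2), mx,
                floor((mx + cell$xhi) / 2), cell$xhi)
        qy <- c(cell$ylo, floor((cell$ylo + my) / 2), my,
                floor((my + cell$yhi) / 2), cell$yhi)
        if (all(diff(qx) > 0) && all(diff(qy) > 0)) {
          bx <- findInterval(rx[idx] - 1e-9, qx[2:4]) + 1L
          by <- findInterval(ry[idx] - 1e-9, qy[2:4]) + 1L
          c16 <- tabulate(bx + 4L * (by - 1L), 16L)
          a16 <- as.vector(outer(diff(qx), diff(qy)))
          e16 <- n * a16 / sum(a16)
          accept <- sum((c16 - e16)^2 / e16) > chi2_2
        }
      }
      if (accept && max(counts) < n &&
          all(counts[counts > 0L] >= min_cell)) {
        quads <- list(idx[left & low], idx[!left & low],
                      idx[left & !low], idx[!left & !low])
        bounds <- list(c(cell$xlo, mx, cell$ylo, my),
                       c(mx, cell$xhi, cell$ylo, my),
                       c(cell$xlo, mx, my, cell$yhi),
                       c(mx, cell$xhi, my, cell$yhi))
        for (k in 1:4) {
          b <- bounds[[k]]
          stack[[length(stack) + 1L]] <-
            list(idx = quads[[k]], xlo = b[1], xhi = b[2],
                 ylo = b[3], yhi = b[4])
        }
        terminal <- FALSE
      }
    }
    if (terminal && n > 0L)
      cells[[length(cells) + 1L]] <-
        list(n = n, xlo = cell$xlo, xhi = cell$xhi,
             ylo = cell$ylo, yhi = cell$yhi)
  }
  cells
}

apmi_from_cells <- function(cells, rx, ry) {
  M <- length(rx)
  mi <- 0
  for (cell in cells) {
    p <- cell$n / M
    p1 <- sum(rx > cell$xlo & rx <= cell$xhi) / M
    p2 <- sum(ry > cell$ylo & ry <= cell$yhi) / M
    mi <- mi + p * log(p / (p1 * p2))
  }
  max(mi, 0)
}

apmi_ranked <- function(rx, ry, chi2_threshold, min_cell) {
  cells <- apmi_partition(rx, ry, chi2_threshold, min_cell)
  apmi_from_cells(cells, rx, ry)
}

#' Adaptive-partitioning mutual information between two samples
#'
#' Estimates the mutual information (in nats) between two continuous
#' variables by recursively refining a rectangular partition of the
#' rank-transformed sample: each cell is split at its marginally
#' equiprobable midpoints into four sub-cells, the split being accepted
#' when a chi-square test on the sub-cell counts (or a second-order test
#' on the next refinement level, which catches weak local dependence)
#' rejects uniformity. Because only ranks are used, the estimate is
#' invariant under strictly monotone transforms of either variable.
#'
#' @param x,y Numeric vectors of equal length (>= 8 observations).
#' @param chi2_threshold Chi-square acceptance threshold for a 4-way split;
#'   default 7.81 (3 df, alpha = 0.05).
#' @param min_cell Minimum points per occupied sub-cell for a split.
#' @return Nonnegative MI estimate in nats.
#' @export
apmi_pair <- function(x, y, chi2_threshold = 7.81, min_cell = 1L) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (length(x) < 8L) stop("need at least 8 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  apmi_ranked(rx, ry, chi2_threshold, min_cell)
}

#' APMI relevance score matrix between TFAs and genes
#'
#' Entry (j, i) is [apmi_pair()] between TF j's activity profile and gene
#' i's expression profile. Deterministic given its inputs.
#'
#' @inheritParams pearson_score_matrix
#' @param chi2_threshold,min_cell Passed to [apmi_pair()].
#' @return Nonnegative score matrix (TFs x genes), in nats.
#' @export
apmi_score_matrix <- function(tfa, er, chi2_threshold = 7.81, min_cell = 1L) {
  stopifnot(identical(colnames(tfa), colnames(er)))
  L <- nrow(tfa); N <- nrow(er)
  tfa_ranks <- t(apply(tfa, 1L, rank, ties.method = "average"))
  er_ranks <- t(apply(er, 1L, rank, ties.method = "average"))
  scores <- matrix(0, L, N, dimnames = list(rownames(tfa), rownames(er)))
  for (j in seq_len(L))
    for (i in seq_len(N))
      scores[j, i] <- apmi_ranked(tfa_ranks[j, ], er_ranks[i, ],
                                  chi2_threshold, min_cell)
  scores
}
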