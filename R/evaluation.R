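## Knockout-based benchmarking: hide a fraction of the known links, rebuild
## the network from the rest, and score how well the hidden links are
## recovered by precision, recall, and area under the PR curve.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly knock out a fraction of topology links
#'
#' Partitions the known links into a visible training topology and a hidden
#' testing set by uniform sampling without replacement; deterministic given
#' the seed. TFs or genes left with no link are dropped from the training
#' matrix (an exported link list would simply not mention them).
#'
#' @param c0 Binary topology matrix (genes x TFs).
#' @param fraction Fraction of links to hide, in [0, 1).
#' @param seed Integer RNG seed.
#' @return List: \code{training} (topology matrix), \code{testing}
#'   (data.frame tf, gene), \code{fraction}, \code{seed}.
#' @export
knockout_links <- function(c0, fraction, seed) {
  stopifnot(fraction >= 0, fraction < 1)
  links <- topology_links(c0)
  n <- nrow(links)
  n_test <- round(fraction * n)
  if (n_test >= n && n_test > 0L)
    stop("knockout would remove every link (", n, " present)")
  test_idx <- if (n_test == 0L) integer(0)
              else with_seed(seed, sample.int(n, n_test))
  testing <- links[test_idx, , drop = FALSE]
  rownames(testing) <- NULL
  training <- c0
  if (n_test > 0L)
    training[cbind(testing$gene, testing$tf)] <- 0
  training <- training[rowSums(training != 0) > 0,
                       colSums(training != 0) > 0, drop = FALSE]
  list(training = training, testing = testing,
       fraction = fraction, seed = seed)
}

link_keys <- function(tf, gene) paste(tf, gene, sep = "\r")

#' Precision and recall of predicted links against a knockout split
#'
#' New predictions are the predicted edges whose (tf, gene) pair is not in
#' the training topology (this also discounts operon-derived duplicates of
#' training links). Precision is the fraction of new predictions found in
#' the hidden testing set; recall is the fraction of the testing set
#' recovered. With no new predictions, precision is defined as 0.
#'
#' @param predicted A \code{regulatory_network}.
#' @param split A knockout split from [knockout_links()].
#' @return List: \code{precision}, \code{recall}, \code{n_new}, \code{n_tp}.
#' @export
precision_recall <- function(predicted, split) {
  if (nrow(split$testing) == 0L)
    stop("empty testing set: recall undefined")
  tl <- topology_links(split$training)
  train_keys <- link_keys(tl$tf, tl$gene)
  pred_keys <- link_keys(predicted$tf, predicted$gene)
  new_keys <- setdiff(pred_keys, train_keys)
  test_keys <- link_keys(split$testing$tf, split$testing$gene)
  tp <- length(intersect(new_keys, test_keys))
  precision <- if (length(new_keys) == 0L) 0 else tp / length(new_keys)
  list(precision = precision, recall = tp / length(test_keys),
       n_new = length(new_keys), n_tp = tp)
}

#' Precision-recall curve over a range of network sizes
#'
#' TFA estimation and relevance scoring are performed once on the training
#' topology; the z-score matrix is then re-thresholded at every requested
#' size, so the networks are nested and recall is non-decreasing in size.
#'
#' @param er Expression matrix (genes x conditions).
#' @param split Knockout split from [knockout_links()].
#' @param sizes Strictly increasing integer vector of network sizes.
#' @param variant Variant code (see [parse_variant()]).
#' @param operons Optional operon map applied to each thresholded network.
#' @param ... Further arguments to [pipeline_zscores()] (e.g.
#'   \code{tf_gene_map}, APMI and ALS controls).
#' @return data.frame with columns size, precision, recall, n_new, n_tp.
#' @export
pr_curve <- function(er, split, sizes, variant = "E-A-C", operons = NULL,
                     ...) {
  stopifnot(length(sizes) >= 1L, !is.unsorted(sizes, strictly = TRUE))
  z <- pipeline_zscores(er, split$training, variant = variant, ...)
  rows <- lapply(sizes, function(s) {
    t <- threshold_for_size(z, s)
    net <- extract_edges(z, t, s, training = split$training)
    if (!is.null(operons) && length(operons) > 0L)
      net <- expand_operons(net, operons, training = split$training)
    pr <- precision_recall(net, split)
    data.frame(size = s, precision = pr$precision, recall = pr$recall,
               n_new = pr$n_new, n_tp = pr$n_tp)
  })
  do.call(rbind, rows)
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration over the points sorted by recall, anchored at
#' (recall 0, precision of the lowest-recall point) and not extrapolated
#' beyond the largest achieved recall.
#'
#' @param points data.frame with columns \code{recall} and \code{precision}
#'   (at least 2 rows).
#' @return Area in [0, 1].
#' @export
auprc <- function(points) {
  if (nrow(points) < 2L) stop("need at least 2 PR points")
  ord <- order(points$recall, points$precision)
  r <- c(0, points$recall[ord])
  p <- c(points$precision[ord][1L], points$precision[ord])
  sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

#' Benchmark algorithm variants over knockout fractions and replicates
#'
#' Full factorial over variants x knockout fractions x replicates: each
#' cell draws its own knockout split (seed derived deterministically from
#' the base seed), computes a PR curve over the requested sizes, and scores
#' it by AUPRC. Failed cells are recorded with NA rather than aborting the
#' sweep.
#'
#' @param er Expression matrix (genes x conditions).
#' @param topology Full binary topology (before knockout).
#' @param variants Character vector of variant codes.
#' @param fractions Numeric vector of knockout fractions.
#' @param sizes Integer vector of network sizes for the PR curve.
#' @param n_replicates Replicates per cell (default 5).
#' @param seed Base seed; replicate r of fraction f uses
#'   \code{seed + 1000*f_index + r}.
#' @param operons,... Passed through to [pr_curve()].
#' @return data.frame: variant, fraction, replicate, size, precision,
#'   recall, auprc (the cell's AUPRC, repeated on its size rows).
#' @export
benchmark_variants <- function(er, topology, variants, fractions, sizes,
                               n_replicates = 5L, seed = 1L,
                               operons = NULL, ...) {
  out <- list()
  for (fi in seq_along(fractions)) {
    for (r in seq_len(n_replicates)) {
      cell_seed <- seed + 1000L * fi + r
      split <- knockout_links(topology, fractions[fi], cell_seed)
      for (v in variants) {
        res <- tryCatch({
          curve <- pr_curve(er, split, sizes, variant = v,
                            operons = operons, ...)
          curve$auprc <- auprc(curve)
          curve
        }, error = function(e) {
          warning("cell failed (", v, ", fraction ", fractions[fi],
                  ", replicate ", r, "): ", conditionMessage(e))
          data.frame(size = NA_integer_, precision = NA_real_,
                     recall = NA_real_, n_new = NA_integer_,
                     n_tp = NA_integer_, auprc = NA_real_)
        })
        res$variant <- v
        res$fraction <- fractions[fi]
        res$replicate <- r
        out[[length(out) + 1L]] <- res
      }
    }
  }
  df <- do.call(rbind, out)
  df[c("variant", "fraction", "replicate", "size",
       "precision", "recall", "n_new", "n_tp", "auprc")]
}
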