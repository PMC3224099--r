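## Pipeline assembly: variant codes, size thresholding, operon expansion,
## and the end-to-end reconstruction driver.

#' Parse a three-letter algorithm variant code
#'
#' Codes are \code{<tfa>-<score>-<background>} with tfa one of E (alternating
#' least squares / EM), S (SVD projection), P (SIMPLS partial least squares),
#' N (TF expression used directly, no TFA layer); score A (adaptive
#' partitioning mutual information) or C (Pearson correlation); background
#' C (CLR correction) or N (none). 16 combinations in total.
#'
#' @param code Character scalar such as \code{"E-A-C"}.
#' @return List with \code{tfa_method}, \code{score}, \code{background}.
#' @export
parse_variant <- function(code) {
  parts <- strsplit(toupper(code), "-", fixed = TRUE)[[1L]]
  if (length(parts) != 3L ||
      !(parts[1L] %in% c("E", "S", "P", "N")) ||
      !(parts[2L] %in% c("A", "C")) ||
      !(parts[3L] %in% c("C", "N")))
    stop("invalid variant code '", code,
         "'; expected <E|S|P|N>-<A|C>-<C|N>, e.g. 'E-A-C'")
  list(tfa_method = parts[1L], score = parts[2L], background = parts[3L])
}

#' All 16 algorithm variant codes
#' @return Character vector of the valid variant codes.
#' @export
variant_codes <- function() {
  as.vector(outer(c("E", "S", "P", "N"),
                  outer(c("A", "C"), c("C", "N"),
                        function(a, b) paste(a, b, sep = "-")),
                  paste, sep = "-"))
}

#' Threshold a z-score matrix to a requested network size
#'
#' Returns the threshold T such that exactly \code{s} entries of \code{z}
#' exceed T when the boundary value is unique — the (s+1)-th largest entry.
#' With ties at the boundary, T is the boundary value itself and the
#' strictly-greater set is completed to exactly \code{s} edges in
#' [extract_edges()] by (tf, gene) lexicographic order.
#'
#' @param z Matrix of pseudo-z-scores (TFs x genes).
#' @param s Requested network size, 1 <= s <= length(z).
#' @return Threshold value T.
#' @export
threshold_for_size <- function(z, s) {
  total <- length(z)
  if (s < 1L || s > total)
    stop("requested size ", s, " outside 1..", total)
  v <- sort(as.vector(z), decreasing = TRUE)
  if (s == total) return(-Inf)
  v[s + 1L]
}

#' Extract the supra-threshold edges as a regulatory network
#'
#' Takes every entry strictly above the threshold, then — if ties at the
#' threshold leave fewer than \code{s} edges — completes to exactly
#' \code{s} by (tf, gene) lexicographic order among the tied entries.
#' Edges present in the input topology are flagged \code{in_training}.
#'
#' @param z Pseudo-z-score matrix (TFs x genes).
#' @param t Threshold from [threshold_for_size()].
#' @param s Requested network size.
#' @param training Optional binary topology (genes x TFs) used to flag
#'   edges already known.
#' @return A \code{regulatory_network} of exactly \code{s}
#'   \code{from_threshold} edges.
#' @export
extract_edges <- function(z, t, s, training = NULL) {
  idx <- which(z > t, arr.ind = TRUE)
  sel <- data.frame(tf = rownames(z)[idx[, 1L]],
                    gene = colnames(z)[idx[, 2L]],
                    score = z[idx], stringsAsFactors = FALSE)
  if (nrow(sel) > s)  # defensive; cannot occur with t from threshold_for_size
    sel <- sel[order(-sel$score, sel$tf, sel$gene), ][seq_len(s), ]
  need <- s - nrow(sel)
  if (need > 0L) {
    tidx <- which(z == t, arr.ind = TRUE)
    tie <- data.frame(tf = rownames(z)[tidx[, 1L]],
                      gene = colnames(z)[tidx[, 2L]],
                      score = z[tidx], stringsAsFactors = FALSE)
    tie <- tie[order(tie$tf, tie$gene), , drop = FALSE]
    sel <- rbind(sel, tie[seq_len(need), , drop = FALSE])
  }
  in_training <- rep(FALSE, nrow(sel))
  if (!is.null(training)) {
    g_ok <- sel$gene %in% rownames(training) & sel$tf %in% colnames(training)
    in_training[g_ok] <- training[cbind(sel$gene[g_ok], sel$tf[g_ok])] != 0
  }
  regulatory_network(sel$tf, sel$gene, sel$score,
                     rep("from_threshold", nrow(sel)), in_training,
                     threshold = t, requested_size = s)
}

#' Expand a network by operon membership
#'
#' Genes co-transcribed in one operon share regulators: for every predicted
#' edge (tf, g) and every other gene g' in g's operon, an edge (tf, g') is
#' added with provenance \code{from_operon}, inheriting the maximum score
#' among its triggering edges. Existing edges are untouched; the operation
#' is idempotent. Operon-added edges do not count toward the requested
#' network size.
#'
#' @param net A \code{regulatory_network}.
#' @param operons Named list: operon id -> character vector of gene ids.
#' @param training Optional binary topology to flag known links.
#' @return The expanded \code{regulatory_network}.
#' @export
expand_operons <- function(net, operons, training = NULL) {
  if (length(operons) == 0L || nrow(net) == 0L) return(net)
  gene2op <- stats::setNames(rep(names(operons), lengths(operons)),
                             unlist(operons, use.names = FALSE))
  op <- gene2op[net$gene]
  trig <- which(!is.na(op))
  if (length(trig) == 0L) return(net)
  add <- do.call(rbind, lapply(trig, function(k) {
    mates <- setdiff(operons[[op[k]]], net$gene[k])
    if (length(mates) == 0L) return(NULL)
    data.frame(tf = net$tf[k], gene = mates, score = net$score[k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(add)) return(net)
  # max score over multiple triggers, drop pairs already present
  add <- stats::aggregate(score ~ tf + gene, data = add, FUN = max)
  key <- paste(add$tf, add$gene, sep = "\r")
  have <- paste(net$tf, net$gene, sep = "\r")
  add <- add[!(key %in% have), , drop = FALSE]
  if (nrow(add) == 0L) return(net)
  in_training <- rep(FALSE, nrow(add))
  if (!is.null(training)) {
    g_ok <- add$gene %in% rownames(training) & add$tf %in% colnames(training)
    in_training[g_ok] <- training[cbind(add$gene[g_ok], add$tf[g_ok])] != 0
  }
  regulatory_network(c(net$tf, add$tf), c(net$gene, add$gene),
                     c(net$score, add$score),
                     c(net$provenance, rep("from_operon", nrow(add))),
                     c(net$in_training, in_training),
                     threshold = attr(net, "threshold"),
                     requested_size = attr(net, "requested_size"))
}

#' Compute the background-corrected z-score matrix for a variant
#'
#' Runs the pipeline up to and including the background-correction stage:
#' alignment, criteria reduction (NCA estimators), TFA estimation,
#' relevance scoring against every gene of the full expression matrix, and
#' CLR or passthrough correction. Thresholding the returned matrix at
#' several sizes reuses this computation (as the PR-curve evaluation does).
#'
#' @inheritParams run_gtrnetwork
#' @return Nonnegative z-score matrix (TFs x genes).
#' @export
pipeline_zscores <- function(er, topology, variant = "E-A-C",
                             tf_gene_map = NULL, n_components = NULL,
                             tol = 1e-6, max_iter = 1000L,
                             chi2_threshold = 7.81, min_cell = 1L,
                             verbose = FALSE) {
  v <- parse_variant(variant)
  say <- function(...) if (verbose) message(sprintf(...))

  al <- align_expression_topology(er, topology)
  say("align: %d genes shared, %d TFs kept (%d dropped)",
      nrow(al$er), ncol(al$topology), length(al$dropped_tfs))

  er0 <- al$er; c0 <- al$topology
  if (v$tfa_method %in% c("E", "S")) {
    red <- reduce_to_compliance(er0, c0)
    say("criteria reduction: removed %d TFs, %d genes",
        length(red$removed_tfs), length(red$removed_genes))
    er_r <- red$er; c_r <- red$topology
  } else {
    er_r <- er0; c_r <- c0
  }

  tfa <- switch(v$tfa_method,
    E = estimate_tfa_em(er_r, c_r, tol = tol, max_iter = max_iter)$tfa,
    S = estimate_tfa_svd(er_r, c_r)$tfa,
    P = estimate_tfa_pls(er_r, c_r, n_components = n_components)$tfa,
    N = {
      if (is.null(tf_gene_map))
        stop("variant 'N' (no TFA layer) requires tf_gene_map")
      tfa_passthrough(er, tf_gene_map[colnames(topology)])$tfa
    })
  say("TFA (%s): %d TFs x %d conditions", v$tfa_method, nrow(tfa), ncol(tfa))

  m <- switch(v$score,
    C = pearson_score_matrix(tfa, er),
    A = apmi_score_matrix(tfa, er, chi2_threshold = chi2_threshold,
                          min_cell = min_cell))
  z <- switch(v$background, C = joint_zscores(m), N = passthrough_scores(m))
  say("scores: %d x %d (%s, background %s)", nrow(z), ncol(z),
      v$score, v$background)
  z
}

#' Run the full network reconstruction pipeline
#'
#' Executes: gene alignment between expression and topology; NCA criteria
#' reduction (EM and SVD estimators only); TFA estimation per the variant's
#' first letter; relevance scoring of every TFA against the expression of
#' every gene in the full expression matrix (so TF self-regulation can be
#' recovered); CLR or no background correction; thresholding to the
#' requested size; and optional operon expansion. The pipeline is fully
#' deterministic: identical inputs yield identical edge lists.
#'
#' @param er Expression matrix (genes x conditions), log2 ratios.
#' @param topology Binary topology matrix (genes x TFs).
#' @param size Requested number of threshold edges S (>= 1).
#' @param variant Variant code, see [parse_variant()]. Default "E-A-C".
#' @param operons Optional operon map (named list); NULL or empty skips the
#'   operon step.
#' @param tf_gene_map Named character vector TF -> encoding gene; required
#'   for the no-TFA variants (first letter N).
#' @param n_components SIMPLS component count (P variants); default
#'   \code{min(L, M - 1)}.
#' @param tol,max_iter ALS stopping controls (E variants).
#' @param chi2_threshold,min_cell APMI controls (score letter A).
#' @param verbose Log per-stage dimensions to stderr.
#' @return A \code{regulatory_network} with at least \code{size} edges
#'   (operon expansion may add more).
#' @export
run_gtrnetwork <- function(er, topology, size, variant = "E-A-C",
                           operons = NULL, tf_gene_map = NULL,
                           n_components = NULL, tol = 1e-6,
                           max_iter = 1000L, chi2_threshold = 7.81,
                           min_cell = 1L, verbose = FALSE) {
  stopifnot(size >= 1L)
  say <- function(...) if (verbose) message(sprintf(...))
  z <- pipeline_zscores(er, topology, variant = variant,
                        tf_gene_map = tf_gene_map,
                        n_components = n_components, tol = tol,
                        max_iter = max_iter,
                        chi2_threshold = chi2_threshold,
                        min_cell = min_cell, verbose = verbose)
  t <- threshold_for_size(z, size)
  net <- extract_edges(z, t, size, training = topology)
  if (!is.null(operons) && length(operons) > 0L)
    net <- expand_operons(net, operons, training = topology)
  say("network: %d edges (threshold %.4g)", nrow(net), t)
  net
}
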