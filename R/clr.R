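## CLR-style background correction: each raw relevance score is z-scored
## against the score distribution of its TF (row) and of its gene (column),
## and the two marginal z-scores are combined into a joint pseudo-z-score.

#' Marginal z-scores of a relevance matrix
#'
#' For entry (j, i): the TF-marginal z-score standardises it against the
#' mean and sample standard deviation of TF j's row (its scores to all
#' genes); the gene-marginal z-score against gene i's column (its scores
#' from all TFs). Zero-variance rows or columns yield z = 0.
#'
#' @param m Relevance score matrix (TFs x genes), L >= 2 and N >= 2.
#' @return List with matrices \code{tf_z} and \code{gene_z}, both L x N.
#' @export
marginal_zscores <- function(m) {
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L)
  row_mu <- rowMeans(m)
  row_sd <- apply(m, 1L, stats::sd)
  col_mu <- colMeans(m)
  col_sd <- apply(m, 2L, stats::sd)
  tf_z <- (m - row_mu) / ifelse(row_sd > 0, row_sd, 1)
  tf_z[row_sd == 0, ] <- 0
  gene_z <- sweep(sweep(m, 2L, col_mu), 2L, ifelse(col_sd > 0, col_sd, 1), "/")
  gene_z[, col_sd == 0] <- 0
  list(tf_z = tf_z, gene_z = gene_z)
}

#' Joint CLR pseudo-z-scores
#'
#' Combines the two marginal z-scores of every entry as
#' \code{sqrt(max(0, tf_z)^2 + max(0, gene_z)^2)} — the CLR default —
#' so only scores elevated above their row/column background contribute.
#'
#' @inheritParams marginal_zscores
#' @return Nonnegative matrix (TFs x genes) of joint pseudo-z-scores.
#' @export
joint_zscores <- function(m) {
  z <- marginal_zscores(m)
  sqrt(pmax(z$tf_z, 0)^2 + pmax(z$gene_z, 0)^2)
}

#' Raw scores as pseudo-z-scores (no background correction)
#'
#' Shifts the relevance matrix by its global minimum so all entries are
#' nonnegative; the ranking of entries is preserved exactly, so thresholding
#' by network size is unaffected. Idempotent.
#'
#' @param m Relevance score matrix (TFs x genes).
#' @return Nonnegative matrix with the same entry ranking as \code{m}.
#' @export
passthrough_scores <- function(m) {
  lo <- min(m)
  if (lo < 0) m - lo else m
}
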