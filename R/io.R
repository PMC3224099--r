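#' Read a log2-ratio expression matrix from TSV
#'
#' The file must have a header row of condition identifiers, gene identifiers
#' in the first column, and a fully numeric body of log2 expression ratios
#' (gene x condition). Missing or non-numeric cells are rejected: the
#' downstream least-squares decomposition requires complete rows, and no
#' imputation is attempted.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x conditions) with gene identifiers as
#'   row names and condition identifiers as column names, in file order.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file needs a gene-id column plus >= 1 condition column")
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stop("duplicate gene id(s) in expression matrix: ",
         paste(unique(dup), collapse = ", "))
  condition_ids <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s' (row %d), condition '%s' (column %d)",
      gene_ids[bad[1L, 1L]], bad[1L, 1L],
      condition_ids[bad[1L, 2L]], bad[1L, 2L]))
  dimnames(values) <- list(gene_ids, condition_ids)
  values
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; full double precision is kept so
#' that a write/read round trip reproduces the matrix.
#'
#' @param er Numeric matrix with gene row names and condition column names.
#' @param path Output path.
#' @export
write_expression_matrix <- function(er, path) {
  df <- data.frame(gene = rownames(er), er, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-gene link list into a binary topology matrix
#'
#' Each line is \code{tf<TAB>gene}; any further columns (e.g. a +/- sign of
#' regulation in RegulonDB exports) are ignored, so database exports load
#' unmodified. Duplicate links collapse to a single entry.
#'
#' @param path Path to the link-list TSV.
#' @return Binary matrix (genes x TFs), entry 1 where a link is listed.
#'   Row/column order follows first appearance in the file.
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("topology file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed topology line %d: '%s' (need tf<TAB>gene)",
                 bad[1L], lines[bad[1L]]))
  tfs <- vapply(parts, `[[`, character(1L), 1L)
  genes <- vapply(parts, `[[`, character(1L), 2L)
  if (any(!nzchar(tfs)) || any(!nzchar(genes)))
    stop("empty tf or gene field at topology line ",
         which(!nzchar(tfs) | !nzchar(genes))[1L])
  make_topology(tfs, genes)
}

#' Build a binary topology matrix from parallel tf/gene vectors
#'
#' @param tfs,genes Character vectors of equal length; each pair is one link.
#' @param gene_order,tf_order Optional identifier orderings; defaults to
#'   first appearance.
#' @return Binary matrix (genes x TFs).
#' @export
make_topology <- function(tfs, genes, gene_order = unique(genes),
                          tf_order = unique(tfs)) {
  stopifnot(length(tfs) == length(genes))
  m <- matrix(0, nrow = length(gene_order), ncol = length(tf_order),
              dimnames = list(gene_order, tf_order))
  m[cbind(match(genes, gene_order), match(tfs, tf_order))] <- 1
  m
}

#' Extract the link list of a topology matrix
#'
#' @param c0 Binary topology matrix (genes x TFs).
#' @return data.frame with columns \code{tf}, \code{gene}, one row per link,
#'   ordered by (tf, gene).
#' @export
topology_links <- function(c0) {
  idx <- which(c0 != 0, arr.ind = TRUE)
  df <- data.frame(tf = colnames(c0)[idx[, 2L]],
                   gene = rownames(c0)[idx[, 1L]],
                   stringsAsFactors = FALSE)
  df[order(df$tf, df$gene), , drop = FALSE]
}

#' Read an operon table
#'
#' Each line is \code{operon_id<TAB>gene1,gene2,...}. A gene may belong to at
#' most one operon; singleton operons are allowed, and an empty file yields
#' an empty map (the operon step is optional).
#'
#' @param path Path to the operon TSV.
#' @return Named list mapping operon id to a character vector of gene ids.
#' @export
read_operons <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L)
    stop("malformed operon line ", bad[1L], ": need operon_id<TAB>genes")
  ids <- vapply(parts, `[[`, character(1L), 1L)
  members <- lapply(parts, function(p) strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  ops <- stats::setNames(members, ids)
  validate_operons(ops)
  ops
}

validate_operons <- function(ops) {
  all_genes <- unlist(ops, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup) > 0L)
    stop("gene(s) assigned to more than one operon: ",
         paste(unique(dup), collapse = ", "))
  if (any(lengths(ops) == 0L)) stop("operon with no member genes")
  invisible(ops)
}

#' Align an expression matrix with a topology matrix
#'
#' Restricts both matrices to the genes they share, in the expression
#' matrix's order, then drops TF columns left without any target. Matching
#' is case-sensitive exact string comparison.
#'
#' @param er Expression matrix (genes x conditions).
#' @param c0 Binary topology matrix (genes x TFs).
#' @return List with elements \code{er} and \code{topology}, row-aligned on
#'   the common gene set, plus \code{dropped_tfs}.
#' @export
align_expression_topology <- function(er, c0) {
  common <- intersect(rownames(er), rownames(c0))
  if (length(common) == 0L)
    stop("no genes shared between expression matrix and topology")
  common <- rownames(er)[rownames(er) %in% common]  # keep expression order
  er0 <- er[common, , drop = FALSE]
  c1 <- c0[common, , drop = FALSE]
  keep_tf <- colSums(c1 != 0) > 0
  list(er = er0,
       topology = c1[, keep_tf, drop = FALSE],
       dropped_tfs = colnames(c1)[!keep_tf])
}

#' Construct a regulatory network edge table
#'
#' @param tf,gene,score,provenance Parallel vectors; provenance values are
#'   \code{"from_threshold"}, \code{"from_operon"}, with \code{in_training}
#'   tracked as a logical column.
#' @param in_training Logical; whether the link is in the input topology.
#' @param threshold,requested_size Network-level metadata.
#' @return A \code{regulatory_network}: data.frame(tf, gene, score,
#'   provenance, in_training) with attributes \code{threshold} and
#'   \code{requested_size}, sorted by descending score then (tf, gene).
#' @export
regulatory_network <- function(tf = character(0), gene = character(0),
                               score = numeric(0),
                               provenance = character(0),
                               in_training = logical(0),
                               threshold = NA_real_,
                               requested_size = NA_integer_) {
  df <- data.frame(tf = as.character(tf), gene = as.character(gene),
                   score = as.numeric(score),
                   provenance = as.character(provenance),
                   in_training = as.logical(in_training),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("tf", "gene")]))
    stop("duplicate (tf, gene) pair in network")
  df <- df[order(-df$score, df$tf, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "threshold") <- threshold
  attr(df, "requested_size") <- requested_size
  class(df) <- c("regulatory_network", "data.frame")
  df
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory network: %d edges (%d from threshold, %d from operons), threshold %.4g, requested size %s\n",
              nrow(x), sum(x$provenance == "from_threshold"),
              sum(x$provenance == "from_operon"),
              attr(x, "threshold"),
              as.character(attr(x, "requested_size"))))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more edges\n")
  invisible(x)
}

#' Write a regulatory network edge list to TSV
#'
#' Columns: tf, gene, score, provenance, in_training; sorted by descending
#' score then (tf, gene) so repeated runs diff cleanly.
#'
#' @param net A \code{regulatory_network}.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  df <- as.data.frame(net)
  df <- df[order(-df$score, df$tf, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulatory network edge list written by [write_edge_list()]
#'
#' @param path Path to the edge-list TSV.
#' @return A \code{regulatory_network}.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  regulatory_network(df$tf, df$gene, df$score, df$provenance, df$in_training)
}
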