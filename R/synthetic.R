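## Ground-truth generator: sparse TF-gene topologies satisfying the NCA
## identifiability criteria, hidden log-TFA profiles, expression ratios from
## the log-linear model with additive Gaussian noise, and operon structures.
## These distributions are this package's own specification of a plausible
## prokaryotic study; real compendia add probe effects, batch structure and
## uneven condition sampling that are deliberately not modelled.

#' Generate a random NCA-compliant TF-gene topology
#'
#' Each TF receives \code{targets_per_tf} targets drawn uniformly from the
#' gene set. The first \code{n_tfs} genes are designated as the TFs'
#' encoding genes (recorded in the \code{"tf_gene_map"} attribute), and
#' each TF targets its own gene with probability \code{autoregulate} —
#' negative autoregulation is a common motif in bacterial regulons, found
#' in roughly half of E. coli TFs, and it is what couples a TF's mRNA to
#' its activity at all (activity is otherwise post-translationally set, so
#' TF expression is only a partial proxy). The draw is repeated until the
#' topology passes the NCA identifiability criteria.
#'
#' @param n_genes,n_tfs,targets_per_tf Topology dimensions; must leave each
#'   TF column at least \code{n_tfs - 1} zeros.
#' @param seed Integer RNG seed; the result is deterministic given it.
#' @param autoregulate Probability that a TF targets its encoding gene
#'   (TRUE/FALSE work as 1/0).
#' @param max_retries Rejection-sampling budget.
#' @return Binary topology matrix (genes x TFs) with attribute
#'   \code{tf_gene_map} (named character vector TF -> gene).
#' @export
generate_topology <- function(n_genes, n_tfs, targets_per_tf, seed,
                              autoregulate = 0.5, max_retries = 50L) {
  if (n_genes - targets_per_tf < n_tfs - 1L)
    stop("infeasible: columns with ", targets_per_tf, " targets in ",
         n_genes, " genes cannot have ", n_tfs - 1L,
         " zeros; use fewer targets per TF or more genes")
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  tf_gene_map <- stats::setNames(gene_ids[seq_len(n_tfs)], tf_ids)
  for (attempt in seq_len(max_retries)) {
    c0 <- with_seed(seed + attempt - 1L, {
      m <- matrix(0, n_genes, n_tfs, dimnames = list(gene_ids, tf_ids))
      for (j in seq_len(n_tfs)) {
        targets <- integer(0)
        if (stats::runif(1) < as.numeric(autoregulate)) targets <- j
        pool <- setdiff(seq_len(n_genes), targets)
        targets <- c(targets,
                     sample(pool, targets_per_tf - length(targets)))
        m[targets, j] <- 1
      }
      m
    })
    if (check_nca_criteria(c0)$compliant) {
      attr(c0, "tf_gene_map") <- tf_gene_map
      return(c0)
    }
  }
  stop("could not draw an NCA-compliant topology in ", max_retries,
       " attempts; try sparser parameters")
}

#' Generate ground-truth activities and a noisy expression matrix
#'
#' Control strengths on the topology support are drawn with magnitude
#' Uniform(0.5, 1.5) x \code{cs_scale} and random sign (activation or
#' repression; magnitudes are bounded away from 0 so every planted link is
#' in principle detectable). Log-TFA rows are i.i.d. standard normal
#' (redrawn in the measure-zero event of row-rank deficiency), and the
#' expression matrix is \code{cs_true . tfa_true} plus i.i.d. Gaussian
#' noise on the log2 scale.
#'
#' @param topology Binary topology matrix (genes x TFs).
#' @param n_conditions Number of conditions M (>= number of TFs).
#' @param noise_sd Standard deviation of the additive log2-scale noise.
#' @param cs_scale Overall control-strength scale.
#' @param seed Integer RNG seed.
#' @return List: \code{er} (genes x conditions log2 ratios),
#'   \code{cs_true}, \code{tfa_true}, \code{topology}, \code{noise_sd},
#'   \code{seed}.
#' @export
generate_truth <- function(topology, n_conditions, noise_sd = 0.1,
                           cs_scale = 1, seed = 1L) {
  L <- ncol(topology); N <- nrow(topology)
  if (n_conditions < L) stop("need n_conditions >= number of TFs")
  with_seed(seed, {
    cs <- topology * 0
    supp <- which(topology != 0)
    cs[supp] <- stats::runif(length(supp), 0.5, 1.5) * cs_scale *
      sample(c(-1, 1), length(supp), replace = TRUE)
    repeat {
      tfa <- matrix(stats::rnorm(L * n_conditions), L, n_conditions,
                    dimnames = list(colnames(topology),
                                    sprintf("c%03d", seq_len(n_conditions))))
      if (matrix_rank(tfa) == L) break
    }
    er <- cs %*% tfa
    if (noise_sd > 0)
      er <- er + matrix(stats::rnorm(N * n_conditions, sd = noise_sd),
                        N, n_conditions)
    dimnames(er) <- list(rownames(topology), colnames(tfa))
    list(er = er, cs_true = cs, tfa_true = tfa, topology = topology,
         noise_sd = noise_sd, seed = seed)
  })
}

#' Partition genes into synthetic operons
#'
#' Consecutive genes are grouped into blocks whose sizes are drawn from a
#' shifted Poisson, 1 + Poisson(mean_size - 1), mimicking the size
#' distribution of bacterial transcription units.
#'
#' @param gene_ids Character vector of gene ids to partition.
#' @param mean_size Mean operon size (>= 1); 1 gives all singletons.
#' @param seed Integer RNG seed.
#' @return Named list: operon id -> character vector of member genes.
#' @export
generate_operons <- function(gene_ids, mean_size, seed) {
  stopifnot(mean_size >= 1)
  n <- length(gene_ids)
  sizes <- with_seed(seed, {
    s <- integer(0)
    while (sum(s) < n)
      s <- c(s, 1L + stats::rpois(n, mean_size - 1))
    s
  })
  ops <- list()
  pos <- 0L
  k <- 0L
  for (sz in sizes) {
    if (pos >= n) break
    k <- k + 1L
    take <- min(sz, n - pos)
    ops[[sprintf("op%03d", k)]] <- gene_ids[(pos + 1L):(pos + take)]
    pos <- pos + take
  }
  ops
}

#' Write a complete synthetic benchmark fixture to disk
#'
#' Generates an NCA-compliant topology, ground-truth activities, a noisy
#' expression matrix and operons, hides a fraction of the links, and writes
#' five TSV files to \code{dir}: \code{expression.tsv},
#' \code{topology.tsv} (the visible training links), \code{operons.tsv},
#' \code{hidden_links.tsv} (the testing set) and \code{tf_genes.tsv}
#' (TF -> encoding gene). All files load with the package readers.
#'
#' @param dir Output directory (created if absent).
#' @param n_genes,n_tfs,n_conditions,targets_per_tf,noise_sd,cs_scale
#'   Generator parameters; defaults describe a small bacterial study.
#' @param hidden_fraction Fraction of links knocked out into the testing
#'   set.
#' @param operon_mean Mean operon size.
#' @param seed Integer RNG seed controlling every draw.
#' @return Invisibly, a list with the file \code{paths}, the ground
#'   \code{truth}, and the knockout \code{split}.
#' @export
make_benchmark_fixture <- function(dir, n_genes = 200L, n_tfs = 10L,
                                   n_conditions = 50L, targets_per_tf = 15L,
                                   noise_sd = 0.1, cs_scale = 1,
                                   hidden_fraction = 0.3, operon_mean = 3,
                                   seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  topo <- generate_topology(n_genes, n_tfs, targets_per_tf, seed)
  truth <- generate_truth(topo, n_conditions, noise_sd = noise_sd,
                          cs_scale = cs_scale, seed = seed + 1L)
  ops <- generate_operons(rownames(topo), operon_mean, seed + 2L)
  split <- knockout_links(topo, hidden_fraction, seed + 3L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    topology = file.path(dir, "topology.tsv"),
    operons = file.path(dir, "operons.tsv"),
    hidden_links = file.path(dir, "hidden_links.tsv"),
    tf_genes = file.path(dir, "tf_genes.tsv"))
  write_expression_matrix(truth$er, paths$expression)
  tl <- topology_links(split$training)
  writeLines(paste(tl$tf, tl$gene, sep = "\t"), paths$topology)
  writeLines(paste(names(ops),
                   vapply(ops, paste, character(1L), collapse = ","),
                   sep = "\t"), paths$operons)
  writeLines(paste(split$testing$tf, split$testing$gene, sep = "\t"),
             paths$hidden_links)
  map <- attr(topo, "tf_gene_map")
  writeLines(paste(names(map), map, sep = "\t"), paths$tf_genes)
  invisible(list(paths = paths, truth = truth, split = split,
                 operons = ops))
}
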