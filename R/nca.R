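## Network component analysis: identifiability checks and TFA estimators.
## Model: log2(Er) = CS %*% log2(TFAr), with CS supported on the known
## topology. The decomposition is unique (up to diagonal scaling) only when
## the topology satisfies the three NCA identifiability criteria.

matrix_rank <- function(m, tol = 1e-9) {
  if (length(m) == 0L) return(0L)
  qr(m, tol = tol)$rank
}

#' Check the NCA identifiability criteria on a topology matrix
#'
#' Criterion (i): the connectivity matrix has full column rank. Criterion
#' (ii): removing any TF together with all genes it targets leaves a matrix
#' of full column rank; a necessary consequence is that every TF column has
#' at least L-1 zeros. Criterion (iii) — full row rank of the latent TFA
#' matrix — depends on the unknown activities and is therefore checked
#' post hoc on an estimate with [check_criterion_iii()].
#'
#' @param c0 Binary topology matrix (genes x TFs).
#' @return List with logical \code{criterion_i}, \code{criterion_ii},
#'   \code{compliant} (i and ii), character \code{failing_tfs}, integer
#'   \code{zero_counts} per TF, and \code{messages}.
#' @export
check_nca_criteria <- function(c0) {
  stopifnot(nrow(c0) > 0L, ncol(c0) > 0L)
  L <- ncol(c0)
  zero_counts <- colSums(c0 == 0)
  crit_i <- matrix_rank(c0) == L
  failing <- character(0)
  for (j in seq_len(L)) {
    if (zero_counts[j] < L - 1L) { failing <- c(failing, colnames(c0)[j]); next }
    keep_rows <- c0[, j] == 0
    sub <- c0[keep_rows, -j, drop = FALSE]
    if (L > 1L && matrix_rank(sub) < L - 1L)
      failing <- c(failing, colnames(c0)[j])
  }
  msgs <- character(0)
  if (!crit_i) msgs <- c(msgs, "topology is column-rank deficient")
  if (length(failing) > 0L)
    msgs <- c(msgs, paste0("TF removal test fails for: ",
                           paste(failing, collapse = ", ")))
  list(criterion_i = crit_i,
       criterion_ii = length(failing) == 0L,
       compliant = crit_i && length(failing) == 0L,
       failing_tfs = failing,
       zero_counts = zero_counts,
       messages = msgs)
}

#' Check criterion (iii) on an estimated TFA matrix
#'
#' @param tfa TFA matrix (TFs x conditions).
#' @return TRUE when the matrix has full row rank.
#' @export
check_criterion_iii <- function(tfa) {
  matrix_rank(tfa) == nrow(tfa)
}

#' Reduce expression and topology matrices to NCA compliance
#'
#' Greedy, deterministic reduction: while the criteria fail, drop the worst
#' offending TF — the failing column with the fewest zeros, ties broken
#' lexicographically by TF id (for pure rank deficiency, the
#' lexicographically first linearly dependent column) — then drop genes left
#' without any regulator, and re-check.
#'
#' @param er Expression matrix aligned to \code{c0} (genes x conditions).
#' @param c0 Binary topology matrix (genes x TFs).
#' @return List: \code{er}, \code{topology} (compliant), \code{removed_tfs},
#'   \code{removed_genes}.
#' @export
reduce_to_compliance <- function(er, c0) {
  stopifnot(identical(rownames(er), rownames(c0)))
  removed_tfs <- character(0)
  removed_genes <- character(0)
  repeat {
    if (ncol(c0) == 0L)
      stop("criteria reduction removed every TF; ",
           "consider the PLS estimator, which needs no NCA criteria")
    rep <- check_nca_criteria(c0)
    if (rep$compliant) break
    if (length(rep$failing_tfs) > 0L) {
      cand <- rep$failing_tfs
      zc <- rep$zero_counts[cand]
      cand <- cand[zc == min(zc)]
      drop_tf <- sort(cand)[1L]
    } else {
      # column-rank deficiency only: drop the first dependent column
      piv <- qr(c0)$pivot
      rk <- matrix_rank(c0)
      dep <- colnames(c0)[piv[(rk + 1L):ncol(c0)]]
      drop_tf <- sort(dep)[1L]
    }
    removed_tfs <- c(removed_tfs, drop_tf)
    c0 <- c0[, setdiff(colnames(c0), drop_tf), drop = FALSE]
    orphan <- rowSums(c0 != 0) == 0
    if (any(orphan)) {
      removed_genes <- c(removed_genes, rownames(c0)[orphan])
      c0 <- c0[!orphan, , drop = FALSE]
      er <- er[rownames(c0), , drop = FALSE]
    }
  }
  list(er = er, topology = c0,
       removed_tfs = removed_tfs, removed_genes = removed_genes)
}

# Fix the diagonal-scaling ambiguity of the factorization: unit Euclidean
# norm per CS column, inverse scale absorbed into the TFA row, and the
# largest-magnitude CS entry of each column made positive.
normalize_decomposition <- function(cs, tfa) {
  for (j in seq_len(ncol(cs))) {
    s <- sqrt(sum(cs[, j]^2))
    if (s == 0) next
    k <- which.max(abs(cs[, j]))
    if (cs[k, j] < 0) s <- -s
    cs[, j] <- cs[, j] / s
    tfa[j, ] <- tfa[j, ] * s
  }
  list(cs = cs, tfa = tfa)
}

frob <- function(m) sqrt(sum(m^2))

#' Estimate TFAs by alternating least squares (EM-style NCA)
#'
#' Minimises \code{||Er - CS . TFA||_F} over the support-constrained control
#' strengths CS and the latent TFA matrix by alternating exact least-squares
#' solves: each condition's TFA column given CS, then each gene's nonzero CS
#' entries given TFA. Initialisation is deterministic (CS = topology entries
#' as reals), so the result does not depend on the RNG. The residual trace
#' is non-increasing by construction.
#'
#' @param er Expression matrix (genes x conditions), log2 ratios.
#' @param c0 Compliant binary topology (genes x TFs).
#' @param tol Relative residual-change stopping tolerance.
#' @param max_iter Maximum number of alternating sweeps.
#' @return List: \code{tfa} (TFs x conditions), \code{cs} (genes x TFs, zero
#'   off-support, unit-norm columns with positive max-entry sign),
#'   \code{residual_trace}, \code{converged}, \code{iterations}.
#' @export
estimate_tfa_em <- function(er, c0, tol = 1e-6, max_iter = 1000L) {
  stopifnot(identical(rownames(er), rownames(c0)))
  L <- ncol(c0); M <- ncol(er)
  if (M < L) stop("need at least as many conditions as TFs (M >= L)")
  support <- lapply(seq_len(L), function(j) which(c0[, j] != 0))
  gene_support <- lapply(seq_len(nrow(c0)), function(i) which(c0[i, ] != 0))
  cs <- matrix(as.numeric(c0 != 0), nrow(c0), ncol(c0),
               dimnames = dimnames(c0))
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  tfa <- NULL
  for (it in seq_len(max_iter)) {
    qr_cs <- qr(cs)
    if (qr_cs$rank < L)
      stop("control-strength matrix became rank deficient (TF '",
           colnames(c0)[qr_cs$pivot[L]], "')")
    tfa <- qr.coef(qr_cs, er)
    for (i in seq_len(nrow(c0))) {
      s <- gene_support[[i]]
      A <- t(tfa[s, , drop = FALSE])          # M x |s|
      fit <- qr(A)
      if (fit$rank < length(s))
        stop("rank-deficient least-squares subproblem for gene '",
             rownames(c0)[i], "'")
      cs[i, s] <- qr.coef(fit, er[i, ])
    }
    res <- frob(er - cs %*% tfa)
    trace <- c(trace, res)
    if (res <= 1e-12 * frob(er) ||
        (is.finite(prev) &&
         abs(prev - res) <= tol * max(prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev <- res
  }
  if (!converged && tol > 0)
    warning("ALS did not converge within ", max_iter,
            " iterations; returning best iterate")
  tfa <- qr.coef(qr(cs), er)
  nm <- normalize_decomposition(cs, tfa)
  dimnames(nm$tfa) <- list(colnames(c0), colnames(er))
  dimnames(nm$cs) <- dimnames(c0)
  list(tfa = nm$tfa, cs = nm$cs, residual_trace = trace,
       converged = converged, iterations = it)
}

#' Estimate TFAs by SVD subspace projection (FastNCA-style)
#'
#' A rank-L truncated SVD of the expression matrix estimates the signal
#' subspace; each TF's control-strength column is the direction of that
#' subspace most nearly vanishing on the column's structural zeros (smallest
#' right singular vector of the zero-row block), and the TFA matrix is then
#' recovered by least squares.
#'
#' @inheritParams estimate_tfa_em
#' @return List: \code{tfa}, \code{cs} (same conventions as
#'   [estimate_tfa_em()]).
#' @export
estimate_tfa_svd <- function(er, c0) {
  stopifnot(identical(rownames(er), rownames(c0)))
  L <- ncol(c0)
  if (L > min(dim(er)))
    stop("number of TFs exceeds min(genes, conditions); rank-L SVD impossible")
  W <- svd(er, nu = L, nv = 0)$u               # N x L signal subspace
  cs <- matrix(0, nrow(c0), ncol(c0), dimnames = dimnames(c0))
  for (j in seq_len(L)) {
    zero_rows <- which(c0[, j] == 0)
    if (length(zero_rows) == 0L) {
      t_j <- c(1, rep(0, L - 1L))
    } else {
      W0 <- W[zero_rows, , drop = FALSE]
      sv <- svd(W0, nu = 0, nv = L)
      t_j <- sv$v[, L]
    }
    col <- as.vector(W %*% t_j)
    cs[c0[, j] != 0, j] <- col[c0[, j] != 0]
  }
  qr_cs <- qr(cs)
  if (qr_cs$rank < L)
    stop("projected control-strength matrix is rank deficient")
  tfa <- qr.coef(qr_cs, er)
  nm <- normalize_decomposition(cs, tfa)
  dimnames(nm$tfa) <- list(colnames(c0), colnames(er))
  dimnames(nm$cs) <- dimnames(c0)
  list(tfa = nm$tfa, cs = nm$cs)
}

#' Estimate TFAs by SIMPLS partial least squares regression
#'
#' Regresses the expression profile of every condition on the binary
#' topology columns with the SIMPLS algorithm; the activity of TF j under
#' condition m is the fitted regression coefficient of predictor j for
#' response m. The regression runs through the origin (no centring): in
#' log-ratio space the reference condition fixes the origin, so zero
#' activity implies zero expression ratio and an intercept has no meaning.
#' Unlike the NCA estimators, no identifiability criteria are required of
#' the topology.
#'
#' @param er Expression matrix (genes x conditions).
#' @param c0 Binary topology (genes x TFs); need not satisfy NCA criteria.
#' @param n_components Number of latent components; default
#'   \code{min(L, M - 1)}.
#' @return List with \code{tfa} (TFs x conditions).
#' @export
estimate_tfa_pls <- function(er, c0, n_components = NULL) {
  stopifnot(identical(rownames(er), rownames(c0)))
  L <- ncol(c0); M <- ncol(er)
  X <- matrix(as.numeric(c0 != 0), nrow(c0), ncol(c0))
  Y <- er
  if (is.null(n_components))
    n_components <- min(L, M - 1L, matrix_rank(X))
  if (n_components < 1L) stop("n_components must be >= 1")
  if (n_components > min(L, M)) stop("n_components exceeds min(L, M)")
  if (n_components > matrix_rank(X))
    stop("n_components exceeds the achievable rank of the topology")
  S <- crossprod(X, Y)                          # L x M
  R <- matrix(0, L, n_components)
  Q <- matrix(0, M, n_components)
  V <- matrix(0, L, n_components)
  for (a in seq_len(n_components)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (sv$d[1L] < 1e-12)
      stop("n_components exceeds the achievable rank of the topology")
    r <- sv$u[, 1L]
    t_scores <- as.vector(X %*% r)
    nt <- sqrt(sum(t_scores^2))
    t_scores <- t_scores / nt
    r <- r / nt
    p <- crossprod(X, t_scores)
    q <- crossprod(Y, t_scores)
    v <- p
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- q; V[, a] <- v
  }
  tfa <- R %*% t(Q)                             # L x M coefficient matrix
  dimnames(tfa) <- list(colnames(c0), colnames(er))
  list(tfa = tfa)
}

#' Use TF gene expression directly as TFA (no-TFA baseline)
#'
#' Copies each TF's own expression row into the TFA matrix, reducing the
#' pipeline to a classic two-layer relevance network.
#'
#' @param er Expression matrix (genes x conditions).
#' @param tf_gene_map Named character vector: TF id -> id of its encoding
#'   gene in \code{er}.
#' @return List with \code{tfa} (TFs x conditions).
#' @export
tfa_passthrough <- function(er, tf_gene_map) {
  missing <- names(tf_gene_map)[!(tf_gene_map %in% rownames(er))]
  if (length(missing) > 0L)
    stop("no expression row for the gene(s) encoding TF(s): ",
         paste(missing, collapse = ", "))
  tfa <- er[tf_gene_map, , drop = FALSE]
  rownames(tfa) <- names(tf_gene_map)
  list(tfa = tfa)
}
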