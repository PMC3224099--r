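test_that("identifiability criteria are checked per the rank and zero-count rules", {
  c_ok <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  rep_ok <- check_nca_criteria(c_ok)
  expect_true(rep_ok$criterion_i)   # rank 2
  expect_true(rep_ok$criterion_ii)  # each column has 1 >= L-1 = 1 zero
  expect_true(rep_ok$compliant)

  c_dup <- matrix(1, 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_false(check_nca_criteria(c_dup)$criterion_i)  # identical columns

  c_bad <- matrix(c(1, 1, 1, 0, 1, 1), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("A", "B")))
  rep_bad <- check_nca_criteria(c_bad)
  expect_false(rep_bad$criterion_ii)
  expect_identical(rep_bad$failing_tfs, "A")  # 0 zeros < L-1 = 1
})

test_that("criteria reduction is greedy, deterministic, and logged", {
  c_ok <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  er <- matrix(rnorm(9), 3, 3, dimnames = list(rownames(c_ok), paste0("c", 1:3)))
  red <- reduce_to_compliance(er, c_ok)
  expect_identical(red$topology, c_ok)
  expect_length(red$removed_tfs, 0L)

  c_bad <- matrix(c(1, 1, 1, 0, 1, 1), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("A", "B")))
  red2 <- reduce_to_compliance(er, c_bad)
  expect_identical(red2$removed_tfs, "A")
  expect_identical(red2$removed_genes, "g1")  # left with no regulator
  expect_true(check_nca_criteria(red2$topology)$compliant)

  # an all-ones topology sheds TFs until a single (trivially compliant)
  # regulator remains: a lone TF needs L - 1 = 0 zeros per column
  c_dense <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), c("A", "B", "C")))
  red3 <- reduce_to_compliance(er, c_dense)
  expect_identical(red3$removed_tfs, c("A", "B"))
  expect_identical(ncol(red3$topology), 1L)
  expect_true(check_nca_criteria(red3$topology)$compliant)
})

test_that("reduction never increases dimensions (monotonicity property)", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    l <- sample(2:4, 1)
    c0 <- matrix(rbinom(n * l, 1, 0.5), n, l,
                 dimnames = list(sprintf("g%02d", 1:n), LETTERS[1:l]))
    c0 <- c0[rowSums(c0) > 0, colSums(c0) > 0, drop = FALSE]
    if (ncol(c0) < 2 || nrow(c0) < 3) next
    er <- matrix(rnorm(nrow(c0) * 5), nrow(c0), 5,
                 dimnames = list(rownames(c0), paste0("c", 1:5)))
    red <- tryCatch(reduce_to_compliance(er, c0), error = function(e) NULL)
    if (is.null(red)) next
    expect_lte(ncol(red$topology), ncol(c0))
    expect_lte(nrow(red$topology), nrow(c0))
    expect_true(check_nca_criteria(red$topology)$compliant)
  }
})

test_that("ALS recovers true activities exactly on noiseless data", {
  tr <- std_truth(noise_sd = 0)
  fit <- estimate_tfa_em(tr$er, tr$topology)
  expect_true(all(per_tf_abs_cor(fit$tfa, tr$tfa_true) >= 0.99))
  rel_res <- frobenius <- sqrt(sum((tr$er - fit$cs %*% fit$tfa)^2)) /
    sqrt(sum(tr$er^2))
  expect_lt(rel_res, 1e-6)
  expect_true(all(diff(fit$residual_trace) <= 1e-8))   # monotone descent
  expect_true(all(fit$cs[tr$topology == 0] == 0))       # structural zeros
  expect_true(check_criterion_iii(fit$tfa))
})

test_that("ALS handles the rank-1 case and a single capped sweep", {
  c1 <- matrix(1, 6, 1, dimnames = list(paste0("g", 1:6), "A"))
  a <- rnorm(10)
  er <- outer(c(2, 1, 3, 0.5, 1.5, 2.5), a)
  dimnames(er) <- list(rownames(c1), paste0("c", 1:10))
  fit <- estimate_tfa_em(er, c1)
  expect_equal(abs(cor(fit$tfa[1, ], a)), 1, tolerance = 1e-10)

  tr <- std_truth(noise_sd = 0.3, seed = 21)
  one <- suppressWarnings(estimate_tfa_em(tr$er, tr$topology, tol = 0,
                                          max_iter = 1L))
  expect_length(one$residual_trace, 1L)
  init_res <- sqrt(sum((tr$er - (tr$topology * 1.0) %*%
                          qr.coef(qr(tr$topology * 1.0), tr$er))^2))
  expect_lte(one$residual_trace[1L], init_res + 1e-8)
})

test_that("SVD projection recovers activities, degrades gracefully with noise", {
  tr0 <- std_truth(noise_sd = 0)
  fit0 <- estimate_tfa_svd(tr0$er, tr0$topology)
  expect_true(all(per_tf_abs_cor(fit0$tfa, tr0$tfa_true) >= 0.99))
  expect_lt(sqrt(sum((tr0$er - fit0$cs %*% fit0$tfa)^2)) / sqrt(sum(tr0$er^2)),
            1e-6)
  expect_true(all(fit0$cs[tr0$topology == 0] == 0))

  tr1 <- std_truth(noise_sd = 0.1, seed = 8)
  fit1 <- estimate_tfa_svd(tr1$er, tr1$topology)
  expect_gte(median(per_tf_abs_cor(fit1$tfa, tr1$tfa_true)), 0.9)

  c1 <- matrix(1, 6, 1, dimnames = list(paste0("g", 1:6), "A"))
  er1 <- outer(c(2, 1, 3, 0.5, 1.5, 2.5), rnorm(8))
  dimnames(er1) <- list(rownames(c1), paste0("c", 1:8))
  f1 <- estimate_tfa_svd(er1, c1)
  expect_lt(sqrt(sum((er1 - f1$cs %*% f1$tfa)^2)), 1e-8)

  big <- matrix(1, 3, 5, dimnames = list(paste0("g", 1:3), LETTERS[1:5]))
  expect_error(estimate_tfa_svd(er1[1:3, ], big), "exceeds")
})

test_that("ALS and SVD agree entrywise on noiseless data (shared convention)", {
  tr <- std_truth(noise_sd = 0, seed = 33)
  em <- estimate_tfa_em(tr$er, tr$topology)
  sv <- estimate_tfa_svd(tr$er, tr$topology)
  expect_equal(em$tfa, sv$tfa, tolerance = 1e-6)
  expect_equal(em$cs, sv$cs, tolerance = 1e-6)
})

test_that("SIMPLS recovers activities for orthogonal designs and tolerates dense columns", {
  topo <- block_topology()
  tr <- generate_truth(topo, 50L, noise_sd = 0, seed = 9)
  fit <- estimate_tfa_pls(tr$er, topo)
  expect_true(all(per_tf_abs_cor(fit$tfa, tr$tfa_true) >= 0.95))

  dense <- topo
  dense[, 1] <- 1  # violates the zero-count criterion
  fit_d <- estimate_tfa_pls(tr$er, dense, n_components = 5L)
  expect_true(all(is.finite(fit_d$tfa)))

  expect_error(estimate_tfa_pls(tr$er, topo, n_components = 0L), ">= 1")
  expect_error(estimate_tfa_pls(tr$er, topo, n_components = 11L), "exceeds")
})

test_that("the no-TFA baseline copies TF gene expression verbatim", {
  er <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  map <- c(A = "g1", B = "g3")
  tfa <- tfa_passthrough(er, map)$tfa
  expect_identical(unname(tfa), unname(er[c("g1", "g3"), ]))
  expect_identical(rownames(tfa), c("A", "B"))
  expect_error(tfa_passthrough(er, c(A = "g1", C = "gX")), "C")
})
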