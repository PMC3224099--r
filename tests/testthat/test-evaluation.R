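test_that("knockout splits partition the links deterministically", {
  c0 <- make_topology(rep(c("A", "B"), each = 5),
                      paste0("g", c(1:5, 4:8)))
  split <- knockout_links(c0, 0.3, seed = 1)
  expect_identical(nrow(split$testing), 3L)
  expect_identical(sum(split$training), 7)
  all_links <- topology_links(c0)
  train_links <- topology_links(split$training)
  got <- rbind(train_links, split$testing)
  expect_setequal(paste(got$tf, got$gene),
                  paste(all_links$tf, all_links$gene))

  split2 <- knockout_links(c0, 0.3, seed = 1)
  expect_identical(split$testing, split2$testing)

  none <- knockout_links(c0, 0, seed = 1)
  expect_identical(nrow(none$testing), 0L)
})

test_that("knockout partition invariant holds over random inputs", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    c0 <- make_topology(sample(LETTERS[1:4], n, replace = TRUE),
                        sample(sprintf("g%02d", 1:15), n, replace = TRUE))
    frac <- runif(1, 0, 0.8)
    total <- sum(c0)
    if (round(frac * total) >= total) next
    sp <- knockout_links(c0, frac, seed = rep)
    expect_equal(nrow(sp$testing), round(frac * total))
    expect_equal(sum(sp$training) + nrow(sp$testing), total)
    # disjointness
    tr_keys <- paste(topology_links(sp$training)$tf,
                     topology_links(sp$training)$gene)
    te_keys <- paste(sp$testing$tf, sp$testing$gene)
    expect_length(intersect(tr_keys, te_keys), 0L)
  }
})

test_that("precision and recall match direct set arithmetic", {
  training <- make_topology(c("A", "A"), c("g1", "g2"))
  split <- list(training = training,
                testing = data.frame(tf = c("A", "A", "B"),
                                     gene = c("g3", "g4", "g1"),
                                     stringsAsFactors = FALSE),
                fraction = 0.5, seed = 1)
  # new predictions {A-g3, A-g4, B-g2, B-g3}; testing {A-g3, A-g4, B-g1}
  net <- regulatory_network(c("A", "A", "A", "B", "B"),
                            c("g1", "g3", "g4", "g2", "g3"),
                            5:1, rep("from_threshold", 5),
                            c(TRUE, FALSE, FALSE, FALSE, FALSE))
  pr <- precision_recall(net, split)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 2 / 3)

  all_known <- regulatory_network(c("A", "A"), c("g1", "g2"), c(2, 1),
                                  rep("from_threshold", 2), c(TRUE, TRUE))
  pr0 <- precision_recall(all_known, split)
  expect_equal(pr0$precision, 0)
  expect_equal(pr0$recall, 0)

  perfect <- regulatory_network(split$testing$tf, split$testing$gene, 3:1,
                                rep("from_threshold", 3), rep(FALSE, 3))
  prp <- precision_recall(perfect, split)
  expect_equal(prp$precision, 1)
  expect_equal(prp$recall, 1)

  empty_split <- list(training = training,
                      testing = data.frame(tf = character(0),
                                           gene = character(0)))
  expect_error(precision_recall(net, empty_split), "empty testing")
})

test_that("precision/recall agree with a brute-force oracle on 1000 random instances", {
  set.seed(42)
  pairs <- as.vector(outer(LETTERS[1:3], sprintf("g%02d", 1:12), paste,
                           sep = "|"))
  for (rep in 1:1000) {
    train <- sample(pairs, sample(1:6, 1))
    test <- sample(setdiff(pairs, train), sample(1:6, 1))
    pred <- sample(pairs, sample(1:10, 1))
    split <- list(
      training = make_topology(sub("\\|.*", "", train), sub(".*\\|", "", train)),
      testing = data.frame(tf = sub("\\|.*", "", test),
                           gene = sub(".*\\|", "", test),
                           stringsAsFactors = FALSE))
    net <- regulatory_network(sub("\\|.*", "", pred), sub(".*\\|", "", pred),
                              seq_along(pred), rep("from_threshold",
                                                   length(pred)),
                              pred %in% train)
    pr <- precision_recall(net, split)
    new_pred <- setdiff(pred, train)          # brute force, set algebra
    tp <- length(intersect(new_pred, test))
    expect_identical(pr$precision,
                     if (length(new_pred) == 0) 0 else tp / length(new_pred))
    expect_identical(pr$recall, tp / length(test))
  }
})

test_that("AUPRC integrates exactly on known curves and ignores point order", {
  square <- data.frame(recall = c(0, 1), precision = c(1, 1))
  expect_equal(auprc(square), 1.0)
  triangle <- data.frame(recall = c(0, 1), precision = c(1, 0))
  expect_equal(auprc(triangle), 0.5)
  pts <- data.frame(recall = c(0.2, 0.8, 0.5), precision = c(0.9, 0.3, 0.6))
  expect_equal(auprc(pts), auprc(pts[c(2, 3, 1), ]))
  expect_error(auprc(square[1, , drop = FALSE]), "at least 2")
  set.seed(43)
  for (rep in 1:10) {
    p <- data.frame(recall = sort(runif(5)), precision = runif(5))
    a <- auprc(p)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("PR curves from nested thresholds have monotone recall and precision", {
  topo <- std_topology()
  tr <- generate_truth(topo, 50L, noise_sd = 0.1, seed = 61)
  split <- knockout_links(topo, 0.3, seed = 62)
  curve <- pr_curve(tr$er, split, sizes = c(25L, 50L, 100L, 200L),
                    variant = "S-C-C")
  expect_identical(nrow(curve), 4L)
  expect_true(all(diff(curve$recall) >= 0))
  expect_true(all(diff(curve$precision) <= 1e-12))

  single <- pr_curve(tr$er, split, sizes = 50L, variant = "S-C-C")
  net <- run_gtrnetwork(tr$er, split$training, size = 50L, variant = "S-C-C")
  pr <- precision_recall(net, split)
  expect_equal(single$precision, pr$precision)
  expect_equal(single$recall, pr$recall)
})

test_that("the variant benchmark enumerates the factorial design", {
  topo <- std_topology()
  tr <- generate_truth(topo, 50L, noise_sd = 0.1, seed = 71)
  res <- benchmark_variants(tr$er, topo, c("S-C-C", "S-C-N"),
                            fractions = 0.5, sizes = c(30L, 60L),
                            n_replicates = 2L, seed = 5)
  expect_identical(nrow(res), 2L * 1L * 2L * 2L)  # variants x frac x reps x sizes
  expect_setequal(unique(res$variant), c("S-C-C", "S-C-N"))
  # different replicates use different splits, so cells differ
  a <- res$auprc[res$variant == "S-C-C" & res$replicate == 1][1]
  b <- res$auprc[res$variant == "S-C-C" & res$replicate == 2][1]
  expect_false(isTRUE(all.equal(a, b)))
})
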