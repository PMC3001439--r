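four_preds <- function() {
  data.frame(node = c("n1", "n2", "n3", "n4"),
             fun = c("1.1.1", "1.1.1", "2.2.2", "1.1.1"),
             confidence = c(3, 2, 1, 0.5), stringsAsFactors = FALSE)
}
four_truth <- function() {
  # correctness pattern T, T, F, T at level 3
  label_table(c("n1", "n2", "n3", "n4"),
              c("1.1.1.1", "1.1.1.9", "3.3.3.3", "1.1.1.2"))
}

test_that("cumulative accuracy/coverage matches hand enumeration", {
  curve <- accuracy_coverage_curve(four_preds(), four_truth(), level = 3,
                                   test_size = 4)
  expect_equal(curve$threshold, c(3, 2, 1, 0.5))
  expect_equal(curve$tp, c(1, 2, 2, 3))
  expect_equal(curve$fp, c(0, 0, 1, 1))
  expect_equal(curve$accuracy, c(1, 1, 2 / 3, 3 / 4))
  expect_equal(curve$coverage, c(1 / 4, 1 / 2, 3 / 4, 1))
  # cumulative bookkeeping: accuracy * (tp + fp) is an integer count
  expect_equal(curve$accuracy * (curve$tp + curve$fp), curve$tp)
  # endpoint: all predictions made
  expect_equal(curve$coverage[nrow(curve)], 1)
})

test_that("sensitivity steps from 0 toward 1 as the threshold is lowered", {
  curve <- sensitivity_precision_curve(four_preds(), four_truth(), level = 3,
                                       test_size = 4)
  # hand enumeration: 3 true predictions in total
  expect_equal(curve$fn, c(2, 1, 1, 0))
  expect_equal(curve$sensitivity, c(1 / 3, 2 / 3, 2 / 3, 1))
  expect_equal(curve$precision, curve$accuracy)
  # below the lowest threshold every true prediction is accepted
  expect_equal(curve$sensitivity[nrow(curve)], 1)
})

test_that("perfect predictions give accuracy 1 at every point and equal
           confidences share a curve point", {
  preds <- data.frame(node = c("n1", "n2", "n3"), fun = "1.1.1",
                      confidence = c(2, 1, 1))
  truth <- label_table(c("n1", "n2", "n3"),
                       c("1.1.1.1", "1.1.1.2", "1.1.1.3"))
  curve <- accuracy_coverage_curve(preds, truth, level = 3, test_size = 5)
  expect_equal(nrow(curve), 2)  # distinct confidences only
  expect_true(all(curve$accuracy == 1))
  expect_equal(curve$coverage[2], 3 / 5)
  expect_error(accuracy_coverage_curve(preds, truth, 3, test_size = 2),
               "test_size")
})

test_that("worked-example arithmetic: counts to percent accuracy and fold
           reduction of false positives", {
  expect_equal(round(accuracy_from_counts(375, 382), 1), 98.2)
  expect_equal(round(accuracy_from_counts(649 - 30, 649), 1), 95.4)
  expect_equal(fold_reduction(48, 12), 4)
  expect_error(accuracy_from_counts(5, 0))
})

test_that("negative-label ablation is a no-op with a single function and
           flips a bridge query between two planted clusters", {
  # single function: no negatives possible, identical curves
  sim <- planted_network(planted_config(n_functions = 1,
                                        nodes_per_function = 10, seed = 12))
  net <- match_network(sim$matches)
  ab <- ablation_negative_labels(net, sim$labels, sim$queries, sim$truth)
  expect_equal(ab$with, ab$without, tolerance = 1e-12)
  expect_true(all(ab$difference$gain == 0))

  # two-cluster fixture where negatives flip the query's prediction
  m <- flip_fixture_matches()
  labs <- flip_fixture_labels()
  netf <- match_network(m)
  qs <- c("qqqqA", "mmm1A", "uuu1A", "uuu2A")
  fw <- ec_diffusion(netf, labs, queries = qs, use_negatives = TRUE)
  fo <- ec_diffusion(netf, labs, queries = qs, use_negatives = FALSE)
  pw <- fw$predictions[fw$predictions$node == "qqqqA", ]
  po <- fo$predictions[fo$predictions$node == "qqqqA", ]
  expect_equal(pw$fun, "2.1.1.1")
  expect_equal(po$fun, "1.1.1.1")

  # dense-oracle verification of the flipped z-scores
  W <- as.matrix(adjacency_matrix(netf, extra_nodes = qs))
  nodes <- rownames(W)
  z_of <- function(fun, use_neg) {
    y <- label_vector(labs, fun, nodes, level = 4, use_negatives = use_neg)
    f <- dense_diffusion(W, as.numeric(y), 1)
    names(f) <- nodes
    prediction_zscores(f, as.numeric(y))[["qqqqA"]]
  }
  expect_gt(z_of("2.1.1.1", TRUE), z_of("1.1.1.1", TRUE))
  expect_gt(z_of("1.1.1.1", FALSE), z_of("2.1.1.1", FALSE))
})

test_that("path-length histograms match an exhaustive BFS oracle", {
  # chain aA - bB - cC with aA, cC sharing a function: distance 2
  net <- weighted_network(c("aA", "bB"), c("bB", "cC"), c(0.5, 0.9))
  truth <- label_table(c("aA", "cC"), c("1.1.1.1", "1.1.1.1"))
  preds <- data.frame(node = "aA", fun = "1.1.1.1", confidence = 1.5)
  h <- path_length_histogram(net, truth, preds, level = 4)
  expect_equal(h$distance, 2)
  expect_true(h$same_function)
  expect_equal(h$count, 1)

  # a fully disconnected pair is excluded
  net2 <- weighted_network(c("aA", "dD"), c("bB", "eE"), c(0.5, 0.6))
  truth2 <- label_table(c("aA", "bB", "dD"),
                        c("1.1.1.1", "1.1.1.1", "1.1.1.1"))
  h2 <- path_length_histogram(net2, truth2,
                              data.frame(node = "aA", fun = "1.1.1.1",
                                         confidence = 0.5), level = 4)
  expect_equal(sum(h2$count), 1)  # only the reachable bB

  # 30-node planted network against the BFS oracle
  sim <- planted_network(planted_config(n_functions = 3,
                                        nodes_per_function = 10,
                                        p_in = 0.5, p_out = 0.05,
                                        seed = 21))
  net3 <- match_network(sim$matches)
  fit <- ec_diffusion(net3, sim$labels, queries = sim$queries)
  h3 <- path_length_histogram(net3, sim$truth, fit$predictions, level = 4)
  D <- bfs_distances(net3$nodes, net3$edges$a, net3$edges$b)
  correct <- prediction_correct(fit$predictions, sim$truth, 4)
  sets <- split(sim$truth$ec, sim$truth$chain_id)
  expected <- 0L
  for (i in which(correct)) {
    node <- fit$predictions$node[i]
    if (!node %in% rownames(D)) next
    to <- setdiff(intersect(names(sets), colnames(D)), node)
    expected <- expected + sum(is.finite(D[node, to]))
  }
  expect_equal(sum(h3$count), expected)
  # same-function pairs sit closer than different-function pairs
  same_mean <- with(h3, sum(distance * count * same_function) /
                      sum(count * same_function))
  diff_mean <- with(h3, sum(distance * count * !same_function) /
                      sum(count * !same_function))
  expect_lte(same_mean, diff_mean)
})
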