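test_that("match statistics are population moments of the record table", {
  m2 <- data.frame(query_id = c("aA", "bB"), target_id = c("bB", "aA"),
                   rmsd = c(1, 3), et_score = c(2, 2))
  s2 <- match_stats(m2)
  expect_equal(s2$mu_rmsd, 2)
  expect_equal(s2$sigma_rmsd, 1)

  # five-record oracle: brute-force population formula
  rmsd <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  et <- c(1, 2, 3, 4, 5)
  m5 <- data.frame(query_id = paste0("q", 1:5, "A"),
                   target_id = paste0("t", 1:5, "A"),
                   rmsd = rmsd, et_score = et)
  s5 <- match_stats(m5)
  expect_equal(s5$mu_rmsd, 1.5)
  expect_equal(s5$sigma_rmsd, sqrt(sum((rmsd - mean(rmsd))^2) / 5))
  expect_equal(s5$mu_et, 3)
  expect_equal(s5$sigma_et, sqrt(sum((et - mean(et))^2) / 5))

  # degenerate single record: zero spread
  s1 <- match_stats(m5[1, ])
  expect_equal(s1$sigma_rmsd, 0)
  expect_equal(s1$sigma_et, 0)

  expect_error(match_stats(m5[0, ]), "no matches")
})

test_that("edge weights are logistic in the standardized match quality", {
  s <- structure(list(mu_rmsd = 2, sigma_rmsd = 1, mu_et = 3, sigma_et = 2),
                 class = "match_stats")
  expect_equal(edge_weight(2, 3, s), 0.5)
  # one sigma better in rmsd, average et: s = 0.5
  expect_equal(edge_weight(1, 3, s), 1 / (1 + exp(-0.5)))
  # strictly decreasing in each argument
  r <- seq(0, 4, 0.5)
  expect_true(all(diff(edge_weight(r, 3, s)) < 0))
  expect_true(all(diff(edge_weight(2, r, s)) < 0))
  # zero-sigma component contributes nothing
  s0 <- structure(list(mu_rmsd = 2, sigma_rmsd = 0, mu_et = 3, sigma_et = 2),
                  class = "match_stats")
  expect_equal(edge_weight(99, 3, s0), 0.5)
})

test_that("weights are invariant to shifting or rescaling the raw scores", {
  set.seed(1)
  n <- 15
  m <- do.call(rbind, lapply(seq_len(n), function(i)
    make_matches(sprintf("a%02dA", i), sprintf("b%02dA", i),
                 runif(1, 0.5, 3), runif(1, 1, 6))))
  w0 <- match_network(m)$edges$weight
  shifted <- transform(m, rmsd = rmsd + 7, et_score = et_score - 2)
  scaled <- transform(m, rmsd = rmsd * 3.5, et_score = et_score * 0.2)
  expect_equal(match_network(shifted)$edges$weight, w0, tolerance = 1e-12)
  expect_equal(match_network(scaled)$edges$weight, w0, tolerance = 1e-12)
})

test_that("reciprocal filtering keeps only mutual matches and averages them", {
  one_way <- data.frame(query_id = "aA", target_id = "bB", rmsd = 1,
                        et_score = 2)
  net <- match_network(one_way, reciprocal = TRUE)
  expect_setequal(net$nodes, c("aA", "bB"))
  expect_equal(nrow(net$edges), 0)
  # without the filter a single directional record creates the edge
  expect_equal(nrow(match_network(one_way, reciprocal = FALSE)$edges), 1)

  both <- data.frame(query_id = c("aA", "bB"), target_id = c("bB", "aA"),
                     rmsd = c(1, 2), et_score = c(3, 5))
  net2 <- match_network(both)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$avg_rmsd, 1.5)
  expect_equal(net2$edges$avg_et, 4)

  expect_equal(nrow(match_network(both[0, ])$edges), 0)
})

test_that("duplicate directional records are averaged with a warning", {
  m <- rbind(make_matches("aA", "bB", 1, 2),
             data.frame(query_id = "aA", target_id = "bB", rmsd = 3,
                        et_score = 4))
  expect_warning(net <- match_network(m), "duplicate")
  # a->b averages to rmsd 2, reciprocal pair then averages (2 + 1)/2
  expect_equal(net$edges$avg_rmsd, 1.5)
})

test_that("adjacency is symmetric with weights strictly inside (0, 1)", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    pairs <- t(combn(sprintf("n%02dA", 1:n), 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) next
    m <- do.call(rbind, lapply(which(keep), function(i)
      make_matches(pairs[i, 1], pairs[i, 2], runif(1, 0.3, 3),
                   runif(1, 1, 8))))
    net <- match_network(m)
    W <- as.matrix(adjacency_matrix(net))
    expect_equal(W, t(W))
    expect_true(all(net$edges$weight > 0 & net$edges$weight < 1))
    # reciprocal edge set is a subset of the unfiltered one
    all_e <- match_network(m, reciprocal = FALSE)$edges
    expect_true(all(paste(net$edges$a, net$edges$b) %in%
                      paste(all_e$a, all_e$b)))
  }
})

test_that("identity filtering removes high-identity edges, keeps nodes,
           and is monotone in the cutoff", {
  m <- rbind(make_matches("aA", "bB", 1.0, 2.0),
             make_matches("bB", "cC", 1.5, 3.0),
             make_matches("aA", "cC", 2.0, 4.0))
  net <- match_network(m)
  ids <- data.frame(id_a = c("aA", "bB", "aA"), id_b = c("bB", "cC", "cC"),
                    identity_pct = c(85, 45, 15))
  f80 <- filter_identity(net, ids, 80)
  expect_equal(nrow(f80$edges), 2)  # the 85% edge is gone
  expect_setequal(f80$nodes, net$nodes)
  # cutoff at the ceiling changes nothing
  f100 <- filter_identity(net, ids, 100)
  expect_equal(f100$edges$weight, net$edges$weight)
  # nestedness over the full cutoff ladder
  cuts <- c(10, 20, 40, 60, 80, 100)
  prev <- character(0)
  for (cut in cuts) {
    e <- filter_identity(net, ids, cut)$edges
    keys <- paste(e$a, e$b)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
  # a pair with no identity entry is retained with a warning
  expect_warning(fmiss <- filter_identity(net, ids[1:2, ], 50),
                 "lack an identity")
  expect_true("aA\rcC" %in% paste(fmiss$edges$a, fmiss$edges$b, sep = "\r"))
})
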