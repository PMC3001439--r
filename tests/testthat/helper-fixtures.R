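# shared fixtures and independent oracles

# independent dense oracle for the diffusion solve: base-R solve() on the
# full matrix, never touching the package's sparse path
dense_diffusion <- function(W, y, alpha) {
  W <- as.matrix(W)
  L <- diag(rowSums(W)) - W
  solve(diag(nrow(W)) + alpha * L, y)
}

# random symmetric weight matrix on n nodes (edge prob p, weights in (0,1))
random_weight_matrix <- function(n, p = 0.3) {
  W <- matrix(0, n, n)
  upper <- which(upper.tri(W))
  on <- upper[stats::runif(length(upper)) < p]
  W[on] <- stats::runif(length(on), 0.05, 0.95)
  W <- W + t(W)
  rownames(W) <- colnames(W) <- sprintf("n%02d", seq_len(n))
  W
}

# reciprocal directional match records for a given undirected edge list
make_matches <- function(a, b, rmsd, et) {
  data.frame(query_id = c(a, b), target_id = c(b, a),
             rmsd = rep(rmsd, 2), et_score = rep(et, 2),
             stringsAsFactors = FALSE)
}

# a network with hand-set edge weights (bypasses the weighting scheme so
# weight-dependent arithmetic can be checked exactly)
weighted_network <- function(a, b, weight) {
  edges <- data.frame(a = a, b = b, weight = weight,
                      avg_rmsd = NA_real_, avg_et = NA_real_,
                      identity = NA_real_, stringsAsFactors = FALSE)
  diffanno:::new_similarity_network(unique(c(a, b)), edges)
}

# two labeled clusters plus a query whose prediction flips when negative
# labels are switched on; frozen from a randomized search over two-cluster
# topologies, verified against the dense oracle in the ablation tests
flip_fixture_matches <- function() {
  e <- data.frame(
    a = c("aaa1A", "aaa1A", "aaa1A", "aaa1A", "bbb1A", "bbb1A", "bbb2A",
          "bbb2A", "uuu1A"),
    b = c("bbb1A", "bbb2A", "mmm1A", "qqqqA", "mmm1A", "qqqqA", "mmm1A",
          "qqqqA", "uuu2A"),
    rmsd = c(1.74, 1.78, 0.68, 1.36, 2.39, 1.46, 0.52, 2.30, 2.50),
    et = c(3.78, 1.35, 2.74, 3.07, 2.56, 4.69, 2.94, 4.10, 5.00))
  do.call(rbind, lapply(seq_len(nrow(e)), function(i)
    make_matches(e$a[i], e$b[i], e$rmsd[i], e$et[i])))
}

flip_fixture_labels <- function() {
  label_table(c("aaa1A", "aaa2A", "bbb1A", "bbb2A"),
              c("1.1.1.1", "1.1.1.1", "2.1.1.1", "2.1.1.1"))
}

# exhaustive all-pairs BFS on an unweighted edge list: the hop-count oracle
bfs_distances <- function(nodes, a, b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  D <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}
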