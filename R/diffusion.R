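#' Per-function label vector
#'
#' Encodes the evidence for one function over the network nodes:
#' `+1` if a node carries an EC number whose truncation at `level` equals
#' `fun`, `-1` if the node carries at least one EC complete at that level,
#' none of which equals `fun` (negative evidence, only when
#' `use_negatives`), and `0` otherwise — no annotation, or only partial
#' codes at that level, which cannot establish either presence or absence.
#' A multifunctional node is `+1` for each of its own functions and never
#' simultaneously `+1` and `-1` for one function.
#'
#' @param labels a [label_table()].
#' @param fun EC string, complete at `level` (e.g. `"3.1.1"` at level 3).
#' @param nodes character vector of network node names, in order.
#' @param level EC depth, 3 or 4 (defaults to the number of components of
#'   `fun`).
#' @param use_negatives logical; emit `-1` for nodes with other functions.
#' @return named numeric vector over `nodes` with entries in
#'   `{-1, 0, +1}`, with attributes `fun`, `p` (labeled count) and `q`
#'   (unlabeled count).
#' @examples
#' lt <- label_table(c("a", "b"), c("3.1.1.1", "2.7.7.7"))
#' label_vector(lt, "3.1.1", nodes = c("a", "b", "c"), level = 3)
#' @export
label_vector <- function(labels, fun, nodes, level = NULL,
                         use_negatives = TRUE) {
  if (is.null(level)) level <- length(parse_ec(fun)[[1]])
  if (!ec_complete_at(fun, level)) {
    stop(sprintf("'%s' is not a complete EC prefix at level %d", fun, level))
  }
  fun <- truncate_ec(fun, level)
  y <- stats::setNames(numeric(length(nodes)), nodes)
  sets <- label_sets(labels)
  sets <- sets[names(sets) %in% nodes]
  for (id in names(sets)) {
    ecs <- sets[[id]]
    complete <- ec_complete_at(ecs, level)
    if (!any(complete)) next
    if (fun %in% truncate_ec(ecs[complete], level)) {
      y[id] <- 1
    } else if (use_negatives) {
      y[id] <- -1
    }
  }
  attr(y, "fun") <- fun
  attr(y, "p") <- sum(y != 0)
  attr(y, "q") <- sum(y == 0)
  y
}

#' Graph Laplacian of a similarity network
#'
#' @param W symmetric (sparse) weight matrix.
#' @param type `"combinatorial"` for `L = D - W` with `D` the diagonal of
#'   row sums (the default used throughout), or `"normalized"` for the
#'   symmetric normalized form `I - D^{-1/2} W D^{-1/2}` (rows of isolated
#'   nodes are zero).
#' @return a sparse symmetric matrix of the same dimension as `W`.
#' @export
graph_laplacian <- function(W, type = c("combinatorial", "normalized")) {
  type <- match.arg(type)
  d <- Matrix::rowSums(W)
  if (type == "combinatorial") {
    Matrix::Diagonal(x = d) - W
  } else {
    s <- ifelse(d > 0, 1 / sqrt(d), 0)
    Matrix::Diagonal(x = as.numeric(d > 0)) -
      Matrix::Diagonal(x = s) %*% W %*% Matrix::Diagonal(x = s)
  }
}

#' Solve the label-diffusion linear system
#'
#' Computes the vector `f` minimizing the quadratic cost
#' `sum_i (f_i - y_i)^2 + alpha * sum_{i<j} w_ij (f_i - f_j)^2`,
#' i.e. the unique solution of the sparse symmetric positive-definite
#' system `(I + alpha L) f = y` with `L` the graph Laplacian. The first
#' term anchors nodes to their prior labels; the second smooths labels
#' along strong edges; `alpha > 0` balances the two like a diffusion
#' coefficient. For label vectors in `{-1, 0, +1}` the solution obeys the
#' maximum principle `-1 <= f_i <= 1`; `alpha = 0` returns `y` itself, and
#' as `alpha -> Inf` on a connected graph every `f_i` approaches the mean
#' of `y`.
#'
#' @param network a `similarity_network`, or a symmetric weight matrix.
#' @param y numeric label vector over the network nodes (see
#'   [label_vector()]); if named, names must match the node order.
#' @param alpha non-negative coupling parameter (default 1).
#' @param laplacian `"combinatorial"` (default) or `"normalized"`.
#' @param tol maximum allowed relative residual of the solve.
#' @return an object of class `diffusion_solution`: list with the named
#'   solution vector `f`, `alpha`, and the achieved relative `residual`.
#' @examples
#' m <- data.frame(query_id = c("a", "b"), target_id = c("b", "a"),
#'                 rmsd = c(1, 2), et_score = c(1, 2))
#' net <- match_network(m)
#' solve_diffusion(net, c(a = 1, b = 0), alpha = 1)
#' @export
solve_diffusion <- function(network, y, alpha = 1,
                            laplacian = c("combinatorial", "normalized"),
                            tol = 1e-8) {
  laplacian <- match.arg(laplacian)
  W <- if (inherits(network, "similarity_network")) {
    adjacency_matrix(network, extra_nodes = names(y))
  } else {
    methods::as(network, "CsparseMatrix")
  }
  n <- nrow(W)
  stopifnot(length(y) == n, alpha >= 0)
  if (any(!is.finite(W@x))) stop("non-finite edge weights")
  if (any(!is.finite(y))) stop("non-finite label vector")
  if (!is.null(names(y)) && !is.null(rownames(W))) {
    y <- y[rownames(W)]
  }
  if (alpha == 0) {
    return(structure(list(f = y, alpha = 0, residual = 0),
                     class = "diffusion_solution"))
  }
  L <- graph_laplacian(W, laplacian)
  A <- Matrix::Diagonal(n) + alpha * L
  f <- as.numeric(Matrix::solve(A, y))
  res <- sqrt(sum((as.numeric(A %*% f) - y)^2)) / max(sqrt(sum(y^2)), 1)
  if (res > tol) {  # one step of iterative refinement, then enforce
    f <- f + as.numeric(Matrix::solve(A, y - as.numeric(A %*% f)))
    res <- sqrt(sum((as.numeric(A %*% f) - y)^2)) / max(sqrt(sum(y^2)), 1)
    if (res > tol) stop(sprintf("diffusion solve residual %.3g > tol %.3g",
                                res, tol))
  }
  structure(list(f = stats::setNames(f, rownames(W)), alpha = alpha,
                 residual = res),
            class = "diffusion_solution")
}

#' @export
print.diffusion_solution <- function(x, ...) {
  cat(sprintf("Diffusion solution over %d nodes (alpha = %g, residual %.2g)\n",
              length(x$f), x$alpha, x$residual))
  cat(sprintf("  f in [%.4f, %.4f]\n", min(x$f), max(x$f)))
  invisible(x)
}

#' Confidence z-scores of a diffusion solution
#'
#' Normalizes the diffused values at the unlabeled nodes against their own
#' population: `z_i = (f_i - mean) / sd`, with mean and population
#' (divide-by-n) standard deviation taken over all unlabeled nodes
#' (`y == 0`). The z-score measures positive deviation from the expected
#' random mean in standard-deviation units, removing the bias that label
#' frequency imprints on the raw `f`, so functions of very different
#' prevalence become comparable at one node. A near-zero spread
#' (`sd < 1e-12`) carries no ranking information and yields all-zero z.
#'
#' @param solution a [solve_diffusion()] result (or a bare numeric `f`).
#' @param y the label vector the system was solved with.
#' @return named numeric vector of z-scores over the unlabeled nodes, with
#'   attributes `mu_f` and `sigma_f`.
#' @export
prediction_zscores <- function(solution, y) {
  f <- if (inherits(solution, "diffusion_solution")) solution$f else solution
  stopifnot(length(f) == length(y))
  unlabeled <- which(y == 0)
  if (length(unlabeled) == 0) stop("nothing to predict: no unlabeled nodes")
  fu <- f[unlabeled]
  mu <- mean(fu)
  sigma <- sqrt(mean((fu - mu)^2))
  z <- if (sigma < 1e-12) 0 * fu else (fu - mu) / sigma
  attr(z, "mu_f") <- mu
  attr(z, "sigma_f") <- sigma
  z
}
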