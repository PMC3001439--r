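#' Fit a competitive network-diffusion annotator
#'
#' The central fitting function. For every enzymatic function present
#' among the labeled chains (EC numbers truncated to `level`), it builds
#' the `{-1, 0, +1}` evidence vector, solves the diffusion system
#' `(I + alpha L) f = y` over the similarity network, and converts the
#' diffused values at unlabeled nodes into confidence z-scores. Functions
#' then compete: each query chain is annotated with the function of the
#' highest z-score at that node, and the z-score magnitude is its
#' confidence.
#'
#' Query chains are treated as unlabeled — any labels they carry are
#' withheld, which is the leave-out mechanism used for benchmarking. With
#' `holdout = "batch"` (default) all queries are withheld simultaneously,
#' emulating the annotation of a batch of unannotated structures against
#' a reference set; `holdout = "loo"` withholds one query at a time, so
#' the remaining queries' labels stay in play (classical leave-one-out).
#'
#' Queries lying in connected components without any labeled chain still
#' receive the argmax-z function — their diffused value is exactly zero
#' and the z-score comes from the unlabeled population — but are flagged
#' `isolated = TRUE` so downstream consumers can treat them with caution.
#' Ties in z are broken toward the lexicographically smallest EC string.
#'
#' @param network a [match_network()] object.
#' @param labels reference annotations, a [label_table()].
#' @param queries chains to annotate; default: all network nodes without a
#'   label entry. Queries absent from the network are scored as isolated
#'   zero-degree nodes rather than dropped.
#' @param level EC depth to annotate at, 3 or 4.
#' @param alpha diffusion coupling parameter, > 0 (default 1).
#' @param use_negatives logical; include `-1` labels for chains known to
#'   carry a different function (default `TRUE`).
#' @param laplacian Laplacian variant, see [graph_laplacian()].
#' @param holdout `"batch"` or `"loo"`, see Details.
#' @param tol linear-solve relative residual bound.
#' @return an object of class `ec_diffusion` with components
#'   `predictions` (data frame: `node`, `fun`, `confidence`, `method`,
#'   `isolated`), `z` (query-by-function z-score matrix, batch holdout
#'   only), `functions`, and the fitting settings. Methods: `print`,
#'   `summary`, `coef` (the z matrix), `predict`, `plot`.
#' @examples
#' sim <- planted_network(planted_config(n_functions = 2,
#'                                       nodes_per_function = 8, seed = 7))
#' net <- match_network(sim$matches)
#' fit <- ec_diffusion(net, sim$labels, queries = sim$queries, level = 4)
#' head(predict(fit))
#' @seealso [nn_annotate()] for the local baseline,
#'   [accuracy_coverage_curve()] for evaluation.
#' @export
ec_diffusion <- function(network, labels, queries = NULL, level = 4,
                         alpha = 1, use_negatives = TRUE,
                         laplacian = c("combinatorial", "normalized"),
                         holdout = c("batch", "loo"), tol = 1e-8) {
  laplacian <- match.arg(laplacian)
  holdout <- match.arg(holdout)
  stopifnot(inherits(network, "similarity_network"), alpha > 0,
            level %in% c(3, 4))
  if (!inherits(labels, "label_table")) labels <- label_table(labels$chain_id,
                                                              labels$ec)
  if (is.null(queries)) {
    queries <- setdiff(network$nodes, unique(labels$chain_id))
  }
  queries <- as.character(queries)
  if (length(queries) == 0) stop("no query chains to annotate")

  if (holdout == "batch") {
    res <- diffuse_competitively(network, labels, queries, withheld = queries,
                                 level = level, alpha = alpha,
                                 use_negatives = use_negatives,
                                 laplacian = laplacian, tol = tol)
    predictions <- res$predictions
    zmat <- res$z
  } else {
    rows <- lapply(queries, function(q) {
      diffuse_competitively(network, labels, q, withheld = q, level = level,
                            alpha = alpha, use_negatives = use_negatives,
                            laplacian = laplacian, tol = tol)$predictions
    })
    predictions <- do.call(rbind, rows)
    zmat <- NULL
  }
  rownames(predictions) <- NULL
  structure(list(predictions = predictions, z = zmat,
                 functions = sort(unique(predictions$fun)),
                 level = level, alpha = alpha,
                 use_negatives = use_negatives, laplacian = laplacian,
                 holdout = holdout, network = network, labels = labels,
                 queries = queries, call = match.call()),
            class = "ec_diffusion")
}

# one competitive diffusion pass: labels of `withheld` chains removed,
# z-scores computed for `queries` (a subset of the unlabeled nodes)
diffuse_competitively <- function(network, labels, queries, withheld,
                                  level, alpha, use_negatives, laplacian,
                                  tol) {
  eff <- labels[!labels$chain_id %in% withheld, , drop = FALSE]
  funs <- label_functions(eff, level)
  if (length(funs) == 0) stop("no labeled functions in network")
  W <- adjacency_matrix(network, extra_nodes = queries)
  nodes <- rownames(W)
  n <- length(nodes)
  L <- graph_laplacian(W, laplacian)
  A <- Matrix::Diagonal(n) + alpha * L

  Y <- vapply(funs, function(fun) {
    as.numeric(label_vector(eff, fun, nodes, level = level,
                            use_negatives = use_negatives))
  }, numeric(n))
  Fmat <- as.matrix(Matrix::solve(A, Y))
  res <- vapply(seq_along(funs), function(k) {
    r <- as.numeric(A %*% Fmat[, k]) - Y[, k]
    sqrt(sum(r^2)) / max(sqrt(sum(Y[, k]^2)), 1)
  }, numeric(1))
  if (any(res > tol)) {
    stop(sprintf("diffusion solve residual %.3g > tol %.3g", max(res), tol))
  }
  Z <- matrix(NA_real_, nrow = length(queries), ncol = length(funs),
              dimnames = list(queries, funs))
  for (k in seq_along(funs)) {
    z <- prediction_zscores(stats::setNames(Fmat[, k], nodes), Y[, k])
    Z[, k] <- z[queries]
  }
  iso <- isolated_queries(network, queries, eff, level)
  # argmax over lexicographically sorted functions: ties go to the smaller EC
  best <- apply(Z, 1, which.max)
  predictions <- data.frame(node = queries, fun = funs[best],
                            confidence = Z[cbind(seq_along(queries), best)],
                            method = "diffusion", isolated = iso[queries],
                            stringsAsFactors = FALSE)
  list(predictions = predictions, z = Z, residual = max(res))
}

# TRUE for queries whose connected component holds no labeled chain
isolated_queries <- function(network, queries, eff_labels, level) {
  g <- network_igraph(network)
  missing <- setdiff(queries, network$nodes)
  if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing),
                                                     name = missing)
  comp <- igraph::components(g)$membership
  labeled <- unique(eff_labels$chain_id[ec_complete_at(eff_labels$ec, level)])
  labeled <- intersect(labeled, names(comp))
  live <- unique(comp[labeled])
  stats::setNames(!(comp[queries] %in% live), queries)
}

#' @export
print.ec_diffusion <- function(x, ...) {
  cat(sprintf("Competitive diffusion annotation (EC level %d, alpha = %g)\n",
              x$level, x$alpha))
  cat(sprintf("  %d queries, %d candidate functions, holdout = %s, %s\n",
              length(x$queries), length(x$functions), x$holdout,
              if (x$use_negatives) "with negative labels"
              else "positive labels only"))
  cat(sprintf("  confidence z in [%.3f, %.3f]; %d isolated quer%s\n",
              min(x$predictions$confidence), max(x$predictions$confidence),
              sum(x$predictions$isolated),
              if (sum(x$predictions$isolated) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
summary.ec_diffusion <- function(object, ...) {
  p <- object$predictions
  cat(sprintf("Predictions for %d queries at EC level %d:\n", nrow(p),
              object$level))
  tab <- sort(table(p$fun), decreasing = TRUE)
  print(tab)
  cat("Confidence z-score quartiles:\n")
  print(stats::quantile(p$confidence))
  invisible(object)
}

#' @describeIn ec_diffusion the query-by-function z-score matrix (batch
#'   holdout; `NULL` under leave-one-out).
#' @param object,x an `ec_diffusion` fit.
#' @param ... unused.
#' @export
coef.ec_diffusion <- function(object, ...) object$z

#' @describeIn ec_diffusion the prediction table; with `newqueries`,
#'   refits for those chains under the same settings.
#' @param newqueries optional character vector of chains to annotate.
#' @export
predict.ec_diffusion <- function(object, newqueries = NULL, ...) {
  if (is.null(newqueries)) return(object$predictions)
  refit <- ec_diffusion(object$network, object$labels, queries = newqueries,
                        level = object$level, alpha = object$alpha,
                        use_negatives = object$use_negatives,
                        laplacian = object$laplacian,
                        holdout = object$holdout)
  refit$predictions
}

#' @describeIn ec_diffusion confidence profile: winning z-scores in
#'   descending order, the shape that confidence-stratified accuracy
#'   curves are cut from.
#' @export
plot.ec_diffusion <- function(x, ...) {
  z <- sort(x$predictions$confidence, decreasing = TRUE)
  graphics::plot(seq_along(z) / length(z), z, type = "s",
                 xlab = "coverage (fraction of queries)",
                 ylab = "confidence z-score",
                 main = "Confidence profile", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Nearest-neighbor annotation baseline
#'
#' The purely local baseline on the same network: for each query, edge
#' weights to its directly connected labeled neighbors are summed per
#' candidate function, the function with the largest cumulative weight
#' wins, and the mean edge weight of the winning function is the
#' confidence. Queries with no labeled neighbor yield no prediction —
#' the contrast with [ec_diffusion()], which can annotate through
#' intermediate unlabeled nodes, is the point of the comparison. Ties go
#' to the lexicographically smallest EC string.
#'
#' @inheritParams ec_diffusion
#' @return data frame of class `nn_annotation` with columns `node`,
#'   `fun`, `confidence`, `method`, `isolated` (always `FALSE`: uncovered
#'   queries are absent, not flagged).
#' @export
nn_annotate <- function(network, labels, queries = NULL, level = 4,
                        holdout = c("batch", "loo")) {
  holdout <- match.arg(holdout)
  stopifnot(inherits(network, "similarity_network"), level %in% c(3, 4))
  if (!inherits(labels, "label_table")) labels <- label_table(labels$chain_id,
                                                              labels$ec)
  if (is.null(queries)) {
    queries <- setdiff(network$nodes, unique(labels$chain_id))
  }
  queries <- as.character(queries)
  e <- network$edges
  sets <- label_sets(labels)
  rows <- lapply(queries, function(q) {
    withheld <- if (holdout == "batch") queries else q
    nb <- rbind(data.frame(id = e$b[e$a == q], w = e$weight[e$a == q]),
                data.frame(id = e$a[e$b == q], w = e$weight[e$b == q]))
    if (nrow(nb) == 0) return(NULL)
    nb <- nb[!(nb$id %in% withheld), , drop = FALSE]
    cum <- list(); wts <- list()
    for (i in seq_len(nrow(nb))) {
      ecs <- sets[[nb$id[i]]]
      if (is.null(ecs)) next
      complete <- ec_complete_at(ecs, level)
      if (!any(complete)) next
      for (fun in unique(truncate_ec(ecs[complete], level))) {
        cum[[fun]] <- (cum[[fun]] %||% 0) + nb$w[i]
        wts[[fun]] <- c(wts[[fun]], nb$w[i])
      }
    }
    if (length(cum) == 0) return(NULL)
    funs <- sort(names(cum))
    best <- funs[which.max(unlist(cum[funs]))]
    data.frame(node = q, fun = best, confidence = mean(wts[[best]]),
               method = "nearest_neighbor", isolated = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(node = character(0), fun = character(0),
                                      confidence = numeric(0),
                                      method = character(0),
                                      isolated = logical(0),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("nn_annotation", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep the diffusion coupling parameter
#'
#' Refits [ec_diffusion()] over a grid of `alpha` values and reports
#' full-coverage accuracy against a truth table, for choosing the
#' coupling strength on benchmark data.
#'
#' @inheritParams ec_diffusion
#' @param alphas numeric vector of coupling values to try.
#' @param truth a [label_table()] with the queries' true annotations.
#' @return data frame `alpha`, `accuracy` (fraction of queries whose
#'   predicted function matches any truth EC at `level`).
#' @export
sweep_alpha <- function(network, labels, queries, truth,
                        alphas = c(0.1, 0.5, 1, 2, 5, 10), level = 4,
                        use_negatives = TRUE) {
  acc <- vapply(alphas, function(a) {
    fit <- ec_diffusion(network, labels, queries = queries, level = level,
                        alpha = a, use_negatives = use_negatives)
    mean(prediction_correct(fit$predictions, truth, level))
  }, numeric(1))
  data.frame(alpha = alphas, accuracy = acc)
}
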