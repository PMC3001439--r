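#' Is each prediction correct against a truth table?
#'
#' A prediction is correct when its function matches *any* of the node's
#' true EC numbers truncated to `level` (promiscuous enzymes carry
#' several ECs, so exact-set matching would be unfair).
#'
#' @param predictions data frame with `node` and `fun` columns.
#' @param truth a [label_table()] of reference annotations.
#' @param level EC depth of the evaluation.
#' @return logical vector, one entry per prediction row.
#' @export
prediction_correct <- function(predictions, truth, level) {
  sets <- label_sets(truth)
  vapply(seq_len(nrow(predictions)), function(i) {
    ecs <- sets[[predictions$node[i]]]
    if (is.null(ecs)) stop("no truth entry for node '",
                           predictions$node[i], "'")
    complete <- ec_complete_at(ecs, level)
    any(truncate_ec(ecs[complete], level) ==
          truncate_ec(predictions$fun[i], level))
  }, logical(1))
}

# shared engine: cumulative counts stepping down through distinct
# confidence values; equal-confidence predictions enter together
confidence_curve <- function(predictions, truth, level, test_size) {
  if (nrow(predictions) == 0) stop("no predictions to evaluate")
  if (test_size < nrow(predictions)) {
    stop(sprintf("test_size (%d) smaller than number of predictions (%d)",
                 test_size, nrow(predictions)))
  }
  correct <- prediction_correct(predictions, truth, level)
  ord <- order(-predictions$confidence)
  conf <- predictions$confidence[ord]
  correct <- correct[ord]
  thresholds <- unique(conf)
  total_true <- sum(correct)
  cum_tp <- cumsum(correct)
  cum_n <- seq_along(conf)
  # index of the last prediction at-or-above each distinct threshold
  last <- vapply(thresholds, function(t) max(which(conf >= t)), integer(1))
  tp <- cum_tp[last]
  n_at <- cum_n[last]
  fp <- n_at - tp
  fn <- total_true - tp
  out <- data.frame(threshold = thresholds, tp = tp, fp = fp, fn = fn,
                    accuracy = tp / (tp + fp),
                    coverage = n_at / test_size,
                    sensitivity = if (total_true > 0) tp / total_true
                                  else rep(NA_real_, length(tp)),
                    precision = tp / (tp + fp))
  rownames(out) <- NULL
  class(out) <- c("annotation_curve", "data.frame")
  out
}

#' Confidence-stratified evaluation curves
#'
#' Predictions are sorted in descending order of confidence; stepping
#' down through each distinct confidence value, cumulative counts are
#' tallied: predictions at-or-above the threshold are true (tp) or false
#' (fp) positives according to the truth table, and correct predictions
#' falling below the threshold are false negatives (fn). Each threshold
#' yields one curve point with
#' accuracy `tp / (tp + fp)` (equal to precision),
#' coverage `(tp + fp) / test_size`, and
#' sensitivity `tp / (tp + fn)`.
#' `accuracy_coverage_curve()` and `sensitivity_precision_curve()` are
#' two views of the same table.
#'
#' @inheritParams prediction_correct
#' @param predictions data frame with `node`, `fun`, `confidence`.
#' @param test_size number of chains in the test set (predictions may
#'   cover fewer; never more).
#' @return a data frame of class `annotation_curve` with columns
#'   `threshold`, `tp`, `fp`, `fn`, `accuracy`, `coverage`,
#'   `sensitivity`, `precision`, one row per distinct confidence.
#' @examples
#' preds <- data.frame(node = c("a", "b", "c", "d"),
#'                     fun = c("1.1.1", "1.1.1", "2.1.1", "1.1.1"),
#'                     confidence = c(3, 2, 1, 0.5))
#' tru <- label_table(c("a", "b", "c", "d"),
#'                    c("1.1.1.1", "1.1.1.2", "3.1.1.1", "1.1.1.1"))
#' accuracy_coverage_curve(preds, tru, level = 3, test_size = 4)
#' @export
accuracy_coverage_curve <- function(predictions, truth, level, test_size) {
  confidence_curve(predictions, truth, level, test_size)
}

#' @rdname accuracy_coverage_curve
#' @export
sensitivity_precision_curve <- function(predictions, truth, level,
                                        test_size) {
  confidence_curve(predictions, truth, level, test_size)
}

#' @export
plot.annotation_curve <- function(x, what = c("accuracy", "sensitivity"),
                                  ...) {
  what <- match.arg(what)
  if (what == "accuracy") {
    graphics::plot(x$coverage, x$accuracy, type = "b", ylim = c(0, 1),
                   xlab = "coverage", ylab = "accuracy", ...)
  } else {
    graphics::plot(x$sensitivity, x$precision, type = "b", ylim = c(0, 1),
                   xlab = "sensitivity", ylab = "precision", ...)
  }
  invisible(x)
}

#' Accuracy of a curve at a coverage cut
#'
#' Steps along the cumulative curve and returns the accuracy of the first
#' point whose coverage reaches `coverage`; if the curve never reaches it
#' (fewer predictions than requested coverage), the accuracy of the last
#' point — all predictions accepted — is returned.
#'
#' @param curve an `annotation_curve`.
#' @param coverage target coverage in (0, 1].
#' @return accuracy at the cut.
#' @export
accuracy_at_coverage <- function(curve, coverage) {
  i <- which(curve$coverage >= coverage)
  if (length(i) == 0) i <- nrow(curve)
  curve$accuracy[min(i)]
}

#' Accuracy and false-positive fold change from printed counts
#'
#' Small arithmetic helpers for confidence-stratified counts:
#' `accuracy_from_counts()` gives the percent accuracy of `correct`
#' predictions out of `total` made; `fold_reduction()` the factor by
#' which false positives drop from a baseline method to a comparison
#' method at a matched coverage.
#'
#' @param correct,total counts of correct predictions and predictions
#'   made.
#' @param fp_baseline,fp_method false-positive counts of the baseline and
#'   the compared method.
#' @return a percentage, or a dimensionless fold factor.
#' @examples
#' accuracy_from_counts(375, 382)   # 98.17...
#' fold_reduction(48, 12)           # 4
#' @export
accuracy_from_counts <- function(correct, total) {
  stopifnot(total > 0, correct >= 0, correct <= total)
  100 * correct / total
}

#' @rdname accuracy_from_counts
#' @export
fold_reduction <- function(fp_baseline, fp_method) {
  stopifnot(fp_method > 0, fp_baseline >= 0)
  fp_baseline / fp_method
}

#' Negative-label ablation
#'
#' Runs the competitive diffusion annotator twice — with and without the
#' `-1` labels that mark chains known to carry a different function — and
#' returns both accuracy/coverage curves together with the accuracy
#' difference on a common coverage grid. Negative labels let functional
#' boundaries repel a competing function's diffusion front, which is
#' where much of the method's accuracy margin comes from.
#'
#' @inheritParams ec_diffusion
#' @param truth a [label_table()] with the queries' true annotations.
#' @param test_size size of the test set; defaults to the number of
#'   queries.
#' @return an object of class `negative_label_ablation`: list with
#'   curves `with` and `without`, and `difference` (data frame
#'   `coverage`, `accuracy_with`, `accuracy_without`, `gain`).
#' @export
ablation_negative_labels <- function(network, labels, queries, truth,
                                     alpha = 1, level = 4,
                                     test_size = length(queries)) {
  fit_with <- ec_diffusion(network, labels, queries = queries, level = level,
                           alpha = alpha, use_negatives = TRUE)
  fit_without <- ec_diffusion(network, labels, queries = queries,
                              level = level, alpha = alpha,
                              use_negatives = FALSE)
  cw <- accuracy_coverage_curve(fit_with$predictions, truth, level, test_size)
  co <- accuracy_coverage_curve(fit_without$predictions, truth, level,
                                test_size)
  grid <- sort(unique(c(cw$coverage, co$coverage)))
  diff <- data.frame(coverage = grid,
                     accuracy_with = vapply(grid, accuracy_at_coverage,
                                            numeric(1), curve = cw),
                     accuracy_without = vapply(grid, accuracy_at_coverage,
                                               numeric(1), curve = co))
  diff$gain <- diff$accuracy_with - diff$accuracy_without
  structure(list(with = cw, without = co, difference = diff),
            class = "negative_label_ablation")
}

#' @export
print.negative_label_ablation <- function(x, ...) {
  cat("Negative-label ablation\n")
  mid <- x$difference[which.min(abs(x$difference$coverage - 0.5)), ]
  cat(sprintf("  accuracy near 50%% coverage: %.3f with, %.3f without (gain %+.3f)\n",
              mid$accuracy_with, mid$accuracy_without, mid$gain))
  invisible(x)
}

#' Shortest-path distances to same- and different-function chains
#'
#' For every correctly predicted chain, hop-count (unweighted)
#' shortest-path distances to every truth-labeled chain are collected and
#' partitioned by whether the labeled chain shares the predicted node's
#' function at `level`. Unreachable pairs (infinite distance) are
#' dropped. Counts are binned by the prediction's confidence z-score,
#' default bin edges `(-Inf, 0, 1, 2, 3, Inf)`. On networks where
#' functions cluster, same-function distances are stochastically shorter;
#' the long tail shows how far diffusion must reach beyond the immediate
#' neighborhood.
#'
#' @inheritParams prediction_correct
#' @param network the `similarity_network` the predictions were made on.
#' @param z_breaks bin edges for the confidence z-score.
#' @return data frame `z_bin`, `distance`, `same_function`, `count`.
#' @export
path_length_histogram <- function(network, truth, predictions, level,
                                  z_breaks = c(-Inf, 0, 1, 2, 3, Inf)) {
  correct <- prediction_correct(predictions, truth, level)
  preds <- predictions[correct, , drop = FALSE]
  if (nrow(preds) == 0) {
    return(data.frame(z_bin = character(0), distance = integer(0),
                      same_function = logical(0), count = integer(0)))
  }
  sets <- label_sets(truth)
  labeled <- intersect(names(sets), network$nodes)
  g <- network_igraph(network)
  from <- intersect(preds$node, network$nodes)
  D <- igraph::distances(g, v = from, to = labeled, weights = NA)
  truth_funs <- lapply(sets, function(ecs) {
    complete <- ec_complete_at(ecs, level)
    unique(truncate_ec(ecs[complete], level))
  })
  rows <- list()
  for (i in seq_len(nrow(preds))) {
    node <- preds$node[i]
    if (!node %in% rownames(D)) next
    zbin <- as.character(cut(preds$confidence[i], z_breaks))
    d <- D[node, ]
    d <- d[names(d) != node]
    d <- d[is.finite(d)]
    if (length(d) == 0) next
    fun <- truncate_ec(preds$fun[i], level)
    same <- vapply(names(d), function(m) fun %in% truth_funs[[m]],
                   logical(1))
    rows[[length(rows) + 1]] <- data.frame(z_bin = zbin,
                                           distance = as.integer(d),
                                           same_function = same,
                                           stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("z_bin", "distance", "same_function")],
                          FUN = sum)
  agg <- agg[order(agg$z_bin, agg$distance, agg$same_function), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
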