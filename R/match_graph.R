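#' Summary statistics of a directional match table
#'
#' Means and population standard deviations (divide-by-n) of the RMSD and
#' evolutionary-similarity (ET) score over all directional match records.
#' These statistics standardize both quantities when edges are weighted,
#' so weights are invariant to shifting or positively rescaling either
#' score across the whole table. Statistics are deliberately computed on
#' the directional records, before reciprocal pairs are collapsed.
#'
#' @param matches data frame of directional records with columns
#'   `query_id`, `target_id`, `rmsd`, `et_score`.
#' @return an object of class `match_stats`: a list with `mu_rmsd`,
#'   `sigma_rmsd`, `mu_et`, `sigma_et` and the record count `n`.
#' @examples
#' m <- data.frame(query_id = c("a", "b"), target_id = c("b", "a"),
#'                 rmsd = c(1, 3), et_score = c(2, 4))
#' match_stats(m)
#' @export
match_stats <- function(matches) {
  validate_matches(matches)
  if (nrow(matches) == 0) stop("no matches")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(mu_rmsd = mean(matches$rmsd),
                 sigma_rmsd = pop_sd(matches$rmsd),
                 mu_et = mean(matches$et_score),
                 sigma_et = pop_sd(matches$et_score),
                 n = nrow(matches)),
            class = "match_stats")
}

#' @export
print.match_stats <- function(x, ...) {
  cat(sprintf("Match statistics over %d directional records\n", x$n))
  cat(sprintf("  rmsd:     mean %.4g, pop. sd %.4g\n", x$mu_rmsd, x$sigma_rmsd))
  cat(sprintf("  et_score: mean %.4g, pop. sd %.4g\n", x$mu_et, x$sigma_et))
  invisible(x)
}

#' Edge weight from an averaged match
#'
#' Maps a match's averaged RMSD and ET score to a similarity weight in
#' (0, 1). Both quantities are standardized against the full record set as
#' `(mu - x) / sigma` — smaller RMSD and smaller ET score both indicate a
#' better match, so better-than-average matches score positive — the two
#' standardized terms are averaged, and the result passes through the
#' logistic function, guaranteeing a strictly positive weight for every
#' retained edge. A zero standard deviation carries no discriminating
#' information, so its term contributes 0.
#'
#' @param avg_rmsd averaged RMSD of the match pair (angstroms).
#' @param avg_et averaged ET score of the match pair.
#' @param stats a [match_stats()] object for the full record set.
#' @return numeric weight(s) in (0, 1); 0.5 for an exactly average match.
#' @examples
#' s <- structure(list(mu_rmsd = 2, sigma_rmsd = 1, mu_et = 3, sigma_et = 1),
#'                class = "match_stats")
#' edge_weight(2, 3, s)   # 0.5
#' edge_weight(1, 3, s)   # logistic(0.5) > 0.5
#' @export
edge_weight <- function(avg_rmsd, avg_et, stats) {
  stopifnot(inherits(stats, "match_stats"))
  t_rmsd <- if (stats$sigma_rmsd > 0)
    (stats$mu_rmsd - avg_rmsd) / stats$sigma_rmsd else 0 * avg_rmsd
  t_et <- if (stats$sigma_et > 0)
    (stats$mu_et - avg_et) / stats$sigma_et else 0 * avg_et
  stats::plogis((t_rmsd + t_et) / 2)
}

new_similarity_network <- function(nodes, edges, stats = NULL,
                                   reciprocal = NA) {
  # canonical order: a < b within a row, rows by (a, b)
  if (nrow(edges) > 0) {
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(unique(nodes)), edges = edges, stats = stats,
                 reciprocal = reciprocal),
            class = "similarity_network")
}

#' Build a similarity network from directional match records
#'
#' Collapses directional template-match records into an undirected,
#' weighted network of protein chains. By default only reciprocal matches
#' — A matched B *and* B matched A — become edges; one-directional matches
#' contribute their nodes but no edge. The edge's RMSD and ET score are
#' the means of the directional records' values, converted to a weight in
#' (0, 1) by `weight_fun` (default [edge_weight()]). Absent pairs mean
#' weight zero.
#'
#' @param matches directional match records (see [read_matches()]).
#' @param reciprocal logical; if `TRUE` (default) keep only reciprocal
#'   pairs.
#' @param stats match statistics; defaults to [match_stats()] over
#'   `matches`. Supply explicitly to weight a subnetwork against the
#'   statistics of a larger record set.
#' @param weight_fun function `(avg_rmsd, avg_et, stats) -> weight`;
#'   alternate weighting strategies can be plugged in.
#' @return an object of class `similarity_network`: node vector, edge data
#'   frame (`a`, `b`, `weight`, `avg_rmsd`, `avg_et`, `identity`), and the
#'   statistics used.
#' @examples
#' m <- data.frame(query_id = c("a", "b", "a"), target_id = c("b", "a", "c"),
#'                 rmsd = c(1, 2, 3), et_score = c(1, 2, 5))
#' net <- match_network(m)       # one reciprocal edge a-b; c is isolated
#' net$edges
#' @seealso [filter_identity()], [adjacency_matrix()], [write_network()]
#' @export
match_network <- function(matches, reciprocal = TRUE, stats = NULL,
                          weight_fun = edge_weight) {
  validate_matches(matches)
  if (is.null(stats) && nrow(matches) > 0) stats <- match_stats(matches)
  nodes <- sort(unique(c(matches$query_id, matches$target_id)))
  if (nrow(matches) == 0) {
    return(new_similarity_network(character(0), empty_edges(), stats,
                                  reciprocal))
  }
  # duplicate directional pairs: average their values, with a warning
  key <- paste(matches$query_id, matches$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate directional record(s); values averaged",
                    sum(duplicated(key))))
    agg <- stats::aggregate(matches[c("rmsd", "et_score")],
                            by = list(key = key), FUN = mean)
    ids <- strsplit(agg$key, "\r", fixed = TRUE)
    matches <- data.frame(query_id = vapply(ids, `[`, "", 1),
                          target_id = vapply(ids, `[`, "", 2),
                          rmsd = agg$rmsd, et_score = agg$et_score,
                          stringsAsFactors = FALSE)
  }
  pa <- pmin(matches$query_id, matches$target_id)
  pb <- pmax(matches$query_id, matches$target_id)
  pkey <- paste(pa, pb, sep = "\r")
  n_dir <- tapply(rep(1L, nrow(matches)), pkey, sum)
  keep <- if (reciprocal) names(n_dir)[n_dir == 2L] else names(n_dir)
  if (length(keep) == 0) {
    return(new_similarity_network(nodes, empty_edges(), stats, reciprocal))
  }
  sel <- pkey %in% keep
  avg_rmsd <- tapply(matches$rmsd[sel], pkey[sel], mean)
  avg_et <- tapply(matches$et_score[sel], pkey[sel], mean)
  ids <- strsplit(names(avg_rmsd), "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(ids, `[`, "", 1),
                      b = vapply(ids, `[`, "", 2),
                      weight = as.numeric(weight_fun(as.numeric(avg_rmsd),
                                                     as.numeric(avg_et),
                                                     stats)),
                      avg_rmsd = as.numeric(avg_rmsd),
                      avg_et = as.numeric(avg_et),
                      identity = NA_real_,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("edge weights must be finite and strictly positive")
  }
  new_similarity_network(nodes, edges, stats, reciprocal)
}

empty_edges <- function() {
  data.frame(a = character(0), b = character(0), weight = numeric(0),
             avg_rmsd = numeric(0), avg_et = numeric(0),
             identity = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("Similarity network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (isTRUE(x$reciprocal)) " (reciprocal matches only)" else ""))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  weights in [%.3f, %.3f]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' @export
summary.similarity_network <- function(object, ...) {
  deg <- degree_counts(object)
  cat(sprintf("Similarity network: %d nodes, %d edges\n",
              length(object$nodes), nrow(object$edges)))
  cat(sprintf("  isolated nodes: %d\n", sum(deg == 0)))
  if (nrow(object$edges) > 0) {
    cat("  weight quartiles:\n")
    print(stats::quantile(object$edges$weight))
  }
  invisible(object)
}

#' @export
plot.similarity_network <- function(x, ...) {
  g <- network_igraph(x)
  igraph::plot.igraph(g, edge.width = 2 * igraph::E(g)$weight,
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}

degree_counts <- function(network) {
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0) {
    tab <- table(c(network$edges$a, network$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

network_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = network$nodes)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(network$edges$a, network$edges$b),
                           weight = network$edges$weight)
  }
  g
}

#' Sparse adjacency matrix of a similarity network
#'
#' @param network a `similarity_network`.
#' @param extra_nodes additional node names to include as zero-degree rows
#'   (used when query chains absent from the match table must be scored).
#' @return a symmetric sparse `Matrix::dsCMatrix` with node-name dimnames.
#' @export
adjacency_matrix <- function(network, extra_nodes = character(0)) {
  nodes <- sort(unique(c(network$nodes, extra_nodes)))
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  e <- network$edges
  W <- Matrix::sparseMatrix(i = idx[e$a], j = idx[e$b], x = e$weight,
                            dims = c(n, n), symmetric = TRUE,
                            dimnames = list(nodes, nodes))
  W
}

#' Remove edges above a sequence-identity cutoff
#'
#' Removes every edge whose pairwise sequence identity exceeds
#' `max_identity` percent; all nodes are retained. Used to probe how much
#' annotation transfer relies on detectable homology by stripping the
#' network down in identity increments. Edges whose pair has no identity
#' entry are retained with a warning: absence of homology evidence does
#' not erase the observed structural similarity.
#'
#' @param network a `similarity_network`.
#' @param identities data frame `id_a`, `id_b`, `identity_pct` over
#'   unordered pairs (see [read_identities()]).
#' @param max_identity maximum allowed identity, percent in (0, 100].
#' @return a new `similarity_network`; surviving edges carry their
#'   identity in the `identity` column.
#' @export
filter_identity <- function(network, identities, max_identity) {
  stopifnot(inherits(network, "similarity_network"),
            max_identity > 0, max_identity <= 100)
  e <- network$edges
  if (nrow(e) == 0) return(network)
  ia <- pmin(identities$id_a, identities$id_b)
  ib <- pmax(identities$id_a, identities$id_b)
  ident <- stats::setNames(identities$identity_pct, paste(ia, ib, sep = "\r"))
  key <- paste(e$a, e$b, sep = "\r")
  e$identity <- as.numeric(ident[key])
  missing <- is.na(e$identity)
  if (any(missing)) {
    warning(sprintf("%d edge(s) lack an identity entry; retained",
                    sum(missing)))
  }
  drop <- !missing & e$identity > max_identity
  new_similarity_network(network$nodes, e[!drop, , drop = FALSE],
                         network$stats, network$reciprocal)
}
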