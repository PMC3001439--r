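#' Configuration of the planted-partition benchmark generator
#'
#' The generator emulates the one property of template-match networks
#' that the annotation method exploits: chains sharing an enzymatic
#' function are densely interconnected by good (low-RMSD, low-ET-score)
#' matches, while cross-function matches are rare and poor. Each of
#' `n_functions` classes gets `nodes_per_function` chains; node pairs are
#' joined independently with probability `p_in` within a class and
#' `p_out` between classes, and every realized edge is emitted as two
#' directional match records so reciprocal filtering keeps it. RMSD and
#' ET score of each directional record are drawn from truncated-normal
#' distributions (RMSD >= 0), better for within-class edges.
#'
#' @param n_functions number of planted functional classes.
#' @param nodes_per_function chains per class.
#' @param p_in,p_out within-/between-class edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param frac_labeled fraction of each class given reference labels; the
#'   rest form the query/truth set.
#' @param rmsd_in,rmsd_out,et_in,et_out length-2 numeric `c(mean, sd)`
#'   of the match-quality distributions (RMSD in angstroms).
#' @param seed RNG seed; identical config and seed give byte-identical
#'   output files.
#' @return a validated list of class `planted_config`.
#' @export
planted_config <- function(n_functions = 5, nodes_per_function = 30,
                           p_in = 0.3, p_out = 0.01, frac_labeled = 0.5,
                           rmsd_in = c(1.0, 0.3), rmsd_out = c(2.5, 0.5),
                           et_in = c(2.0, 0.5), et_out = c(5.0, 1.0),
                           seed = 1) {
  cfg <- list(n_functions = n_functions,
              nodes_per_function = nodes_per_function,
              p_in = p_in, p_out = p_out, frac_labeled = frac_labeled,
              rmsd_in = rmsd_in, rmsd_out = rmsd_out,
              et_in = et_in, et_out = et_out, seed = seed)
  stopifnot(n_functions >= 1, nodes_per_function >= 1,
            p_out >= 0, p_out <= p_in, p_in <= 1,
            frac_labeled > 0, frac_labeled <= 1,
            length(rmsd_in) == 2, length(rmsd_out) == 2,
              length(et_in) == 2, length(et_out) == 2)
  if (nodes_per_function < 2 && p_in > 0) {
    warning("classes of size < 2 cannot realize within-class edges")
  }
  class(cfg) <- "planted_config"
  cfg
}

# normal draw truncated below at `lower` by rejection
rtnorm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a planted-function benchmark
#'
#' Draws one realization of the planted-partition model described in
#' [planted_config()]. Class `k` carries the synthetic EC number
#' `"k.1.1.1"` (valid four-component strings, so level-truncation logic
#' is exercised end to end). A `frac_labeled` subset of each class forms
#' the reference label table; the remaining chains are the queries, whose
#' planted functions go into the truth table.
#'
#' @param config a [planted_config()].
#' @return an object of class `planted_benchmark`: list with `matches`
#'   (directional record data frame), `labels` and `truth`
#'   ([label_table()]s), `queries`, `classes` (named class index per
#'   node), and `config`.
#' @examples
#' sim <- planted_network(planted_config(n_functions = 2,
#'                                       nodes_per_function = 6, seed = 3))
#' table(sim$truth$ec)
#' @export
planted_network <- function(config = planted_config()) {
  stopifnot(inherits(config, "planted_config"))
  with_preserved_rng(config$seed, {
    m <- config$nodes_per_function
    k <- config$n_functions
    n <- m * k
    nodes <- sprintf("c%03dA", seq_len(n))
    cls <- rep(seq_len(k), each = m)
    pairs <- utils::combn(n, 2)
    within <- cls[pairs[1, ]] == cls[pairs[2, ]]
    prob <- ifelse(within, config$p_in, config$p_out)
    realized <- stats::runif(ncol(pairs)) < prob
    idx <- which(realized)
    w_in <- within[idx]
    n_e <- length(idx)
    draw <- function(par_in, par_out, trunc) {
      mean <- ifelse(w_in, par_in[1], par_out[1])
      sd <- ifelse(w_in, par_in[2], par_out[2])
      if (trunc) rtnorm(n_e, mean, sd) else stats::rnorm(n_e, mean, sd)
    }
    # two directional records per realized edge, values drawn per direction
    mk_records <- function() {
      data.frame(rmsd = draw(config$rmsd_in, config$rmsd_out, TRUE),
                 et_score = draw(config$et_in, config$et_out, FALSE))
    }
    fwd <- mk_records()
    rev <- mk_records()
    matches <- data.frame(
      query_id = c(nodes[pairs[1, idx]], nodes[pairs[2, idx]]),
      target_id = c(nodes[pairs[2, idx]], nodes[pairs[1, idx]]),
      rmsd = c(fwd$rmsd, rev$rmsd),
      et_score = c(fwd$et_score, rev$et_score),
      stringsAsFactors = FALSE)
    ec_of <- sprintf("%d.1.1.1", cls)
    labeled <- unlist(lapply(seq_len(k), function(g) {
      members <- which(cls == g)
      sample(members, round(config$frac_labeled * m))
    }))
    queries <- setdiff(seq_len(n), labeled)
    structure(list(matches = matches,
                   labels = label_table(nodes[labeled], ec_of[labeled]),
                   truth = label_table(nodes[queries], ec_of[queries]),
                   queries = nodes[queries],
                   classes = stats::setNames(cls, nodes),
                   config = config),
              class = "planted_benchmark")
  })
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat(sprintf("Planted benchmark: %d functions x %d chains, p_in %.3g / p_out %.3g\n",
              x$config$n_functions, x$config$nodes_per_function,
              x$config$p_in, x$config$p_out))
  cat(sprintf("  %d directional records, %d labeled chains, %d queries\n",
              nrow(x$matches), length(unique(x$labels$chain_id)),
              length(x$queries)))
  invisible(x)
}

#' Write a benchmark's three tables
#'
#' Emits `<prefix>.matches.tsv`, `<prefix>.labels.tsv` and
#' `<prefix>.truth.tsv`, readable by [read_matches()] / [read_labels()].
#'
#' @param benchmark a [planted_network()] or [bridge_fixture()] result.
#' @param prefix path prefix.
#' @return `prefix`, invisibly.
#' @export
write_benchmark <- function(benchmark, prefix) {
  write_matches(benchmark$matches, paste0(prefix, ".matches.tsv"))
  write_labels(benchmark$labels, paste0(prefix, ".labels.tsv"))
  write_labels(benchmark$truth, paste0(prefix, ".truth.tsv"))
  invisible(prefix)
}

#' Bridge-cluster fixture
#'
#' A fixed small network reproducing the topology where global diffusion
#' pays off: the query chain's direct neighbors are all unlabeled, but
#' two hops away sits a well-connected cluster of chains sharing one
#' function. A nearest-neighbor annotator, seeing no labeled neighbor,
#' makes no prediction; diffusion reaches the cluster through the bridge
#' and annotates the query with positive confidence. Detached pairs of
#' unlabeled chains are included as background, mimicking the large
#' no-signal fraction of real match networks, so the z-score population
#' is non-trivial and the query's diffused signal stands above its mean.
#'
#' @return a `planted_benchmark`-shaped list: `matches`, `labels`,
#'   `truth` (the query's planted function, `"3.1.1.1"`), `queries`.
#' @export
bridge_fixture <- function() {
  edge <- function(a, b, rmsd, et) {
    data.frame(query_id = c(a, b), target_id = c(b, a),
               rmsd = rmsd + c(0, 0.05), et_score = et + c(0, 0.1),
               stringsAsFactors = FALSE)
  }
  cluster <- c("k001A", "k002A", "k003A", "k004A")
  rows <- list(edge("q001A", "u001A", 1.6, 3.2),
               edge("q001A", "u002A", 1.5, 3.0),
               edge("u001A", "k001A", 1.2, 2.4),
               edge("u002A", "k002A", 1.1, 2.2),
               # detached unlabeled pairs: background for the z population
               edge("x001A", "x002A", 2.5, 5.0),
               edge("x003A", "x004A", 2.4, 4.8),
               edge("x005A", "x006A", 2.6, 5.2))
  cp <- utils::combn(cluster, 2)
  for (i in seq_len(ncol(cp))) {
    rows[[length(rows) + 1]] <- edge(cp[1, i], cp[2, i], 0.8 + 0.02 * i,
                                     1.5 + 0.05 * i)
  }
  matches <- do.call(rbind, rows)
  list(matches = matches,
       labels = label_table(cluster, rep("3.1.1.1", length(cluster))),
       truth = label_table("q001A", "3.1.1.1"),
       queries = c("q001A", "u001A", "u002A",
                   paste0("x00", 1:6, "A")))
}
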