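#' Tabular readers and writers
#'
#' All input tables are tab-separated with a header line; `#`-prefixed
#' comment lines are allowed and ignored. Curves are written as CSV.
#' Every reader validates its columns and fails with the file name and the
#' offending values; every write/read pair round-trips.
#'
#' * match table: `query_id  target_id  rmsd  et_score`, one directional
#'   template-match record per line (RMSD in angstroms, >= 0; self-matches
#'   are invalid).
#' * label table: `chain_id  ec_number`; repeated chain rows accumulate
#'   into a set.
#' * identity table: `id_a  id_b  identity_pct` over unordered pairs.
#' * predictions: `node  function  confidence  method  isolated`.
#' * curves: CSV `threshold,tp,fp,fn,accuracy,coverage,sensitivity,precision`.
#'
#' @param path file path.
#' @param x object to write.
#' @return readers return validated data frames (`read_labels()` a
#'   [label_table()]); writers return `path` invisibly.
#' @name io_tables
NULL

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d: '%s'",
                   path, col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_matches <- function(path) {
  df <- read_tsv_checked(path, c("query_id", "target_id", "rmsd", "et_score"),
                         c("rmsd", "et_score"))
  df <- df[c("query_id", "target_id", "rmsd", "et_score")]
  df$query_id <- as.character(df$query_id)
  df$target_id <- as.character(df$target_id)
  validate_matches(df, context = path)
  df
}

# shared invariants for match records (used by the reader and the builder)
validate_matches <- function(matches, context = "match records") {
  stopifnot(is.data.frame(matches))
  need <- c("query_id", "target_id", "rmsd", "et_score")
  if (!all(need %in% names(matches))) {
    stop(context, ": expected columns ", paste(need, collapse = ", "))
  }
  if (nrow(matches) == 0) return(invisible(matches))
  bad_rmsd <- which(!is.finite(matches$rmsd) | matches$rmsd < 0)
  if (length(bad_rmsd) > 0) {
    stop(sprintf("%s: invalid rmsd (< 0 or non-finite) at data row %d",
                 context, bad_rmsd[1]))
  }
  if (any(!is.finite(matches$et_score))) {
    stop(context, ": non-finite et_score")
  }
  selfm <- which(matches$query_id == matches$target_id)
  if (length(selfm) > 0) {
    stop(sprintf("%s: self-match at data row %d ('%s')", context, selfm[1],
                 matches$query_id[selfm[1]]))
  }
  invisible(matches)
}

#' @rdname io_tables
#' @export
write_matches <- function(x, path) {
  write_tsv(x[c("query_id", "target_id", "rmsd", "et_score")], path)
}

#' @rdname io_tables
#' @export
read_labels <- function(path) {
  df <- read_tsv_checked(path, c("chain_id", "ec_number"))
  label_table(df$chain_id, df$ec_number)
}

#' @rdname io_tables
#' @export
write_labels <- function(x, path) {
  write_tsv(data.frame(chain_id = x$chain_id, ec_number = x$ec), path)
}

#' @rdname io_tables
#' @export
read_identities <- function(path) {
  df <- read_tsv_checked(path, c("id_a", "id_b", "identity_pct"),
                         "identity_pct")
  df <- df[c("id_a", "id_b", "identity_pct")]
  df$id_a <- as.character(df$id_a)
  df$id_b <- as.character(df$id_b)
  if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
    stop(path, ": identity_pct outside [0, 100]")
  }
  df
}

#' @rdname io_tables
#' @export
write_identities <- function(x, path) {
  write_tsv(x[c("id_a", "id_b", "identity_pct")], path)
}

#' @rdname io_tables
#' @export
read_predictions <- function(path) {
  df <- read_tsv_checked(path, c("node", "function", "confidence"),
                         "confidence")
  names(df)[names(df) == "function"] <- "fun"
  if (!"method" %in% names(df)) df$method <- NA_character_
  if (!"isolated" %in% names(df)) df$isolated <- FALSE
  df$isolated <- as.logical(df$isolated)
  df[c("node", "fun", "confidence", "method", "isolated")]
}

#' @rdname io_tables
#' @export
write_predictions <- function(x, path) {
  out <- data.frame(node = x$node, `function` = x$fun,
                    confidence = x$confidence, method = x$method,
                    isolated = x$isolated, check.names = FALSE)
  out <- out[order(-out$confidence, out$node), , drop = FALSE]
  write_tsv(out, path)
}

#' @rdname io_tables
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("threshold", "tp", "fp", "fn", "accuracy", "coverage",
            "sensitivity", "precision")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  class(df) <- c("annotation_curve", "data.frame")
  df
}

#' @rdname io_tables
#' @export
write_curve <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write similarity networks
#'
#' A network is serialized as two TSV files sharing a prefix: an edge list
#' `<prefix>.edges.tsv` (`id_a  id_b  weight  avg_rmsd  avg_et_score`
#' plus `identity_pct` when identities were attached) and a node list
#' `<prefix>.nodes.tsv`, so that nodes without edges survive the round trip.
#'
#' @param network a [match_network()] object.
#' @param prefix path prefix for the two files.
#' @return `write_network()` returns `prefix` invisibly; `read_network()`
#'   a `similarity_network` object (match statistics are not serialized).
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "similarity_network"))
  e <- network$edges
  out <- data.frame(id_a = e$a, id_b = e$b, weight = e$weight,
                    avg_rmsd = e$avg_rmsd, avg_et_score = e$avg_et)
  if (!all(is.na(e$identity))) out$identity_pct <- e$identity
  write_tsv(out, paste0(prefix, ".edges.tsv"))
  write_tsv(data.frame(node = network$nodes), paste0(prefix, ".nodes.tsv"))
  invisible(prefix)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  nodes <- read_tsv_checked(paste0(prefix, ".nodes.tsv"), "node")$node
  e <- read_tsv_checked(paste0(prefix, ".edges.tsv"),
                        c("id_a", "id_b", "weight", "avg_rmsd",
                          "avg_et_score"),
                        c("weight", "avg_rmsd", "avg_et_score"))
  edges <- data.frame(a = as.character(e$id_a), b = as.character(e$id_b),
                      weight = e$weight, avg_rmsd = e$avg_rmsd,
                      avg_et = e$avg_et_score,
                      identity = if ("identity_pct" %in% names(e))
                        as.numeric(e$identity_pct) else NA_real_,
                      stringsAsFactors = FALSE)
  new_similarity_network(as.character(nodes), edges, stats = NULL)
}
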