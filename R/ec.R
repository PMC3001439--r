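#' Enzyme Commission (EC) string utilities
#'
#' EC numbers are hierarchical codes of up to four dot-separated components,
#' each a positive integer or `"-"` for an unassigned level (e.g. `"3.1.1.1"`,
#' `"3.1.-.-"`). Level 3 identifies the reaction class; level 4 is typically
#' substrate-specific.
#'
#' @param ec character vector of EC strings.
#' @param level integer, hierarchy depth (3 or 4 for annotation work; any
#'   value in 1..4 is accepted by the utilities).
#'
#' @return `parse_ec()` returns a list of character component vectors;
#'   `truncate_ec()` a character vector of the first `level` components;
#'   `ec_complete_at()` a logical vector, `TRUE` where the first `level`
#'   components are all integers (so the code is fully specified at that
#'   depth).
#'
#' @examples
#' truncate_ec("6.3.4.15", 3)        # "6.3.4"
#' ec_complete_at("3.1.-.-", 3)      # FALSE: third component unassigned
#' @name ec_utils
NULL

ec_pattern <- "^([0-9]+|-)(\\.([0-9]+|-)){0,3}$"

#' @rdname ec_utils
#' @export
parse_ec <- function(ec) {
  ec <- as.character(ec)
  bad <- !grepl(ec_pattern, ec) | is.na(ec)
  if (any(bad)) {
    stop("malformed EC string(s): ", paste(unique(ec[bad]), collapse = ", "))
  }
  strsplit(ec, ".", fixed = TRUE)
}

#' @rdname ec_utils
#' @export
truncate_ec <- function(ec, level) {
  stopifnot(length(level) == 1, level >= 1, level <= 4)
  parts <- parse_ec(ec)
  vapply(parts, function(p) {
    paste(p[seq_len(min(level, length(p)))], collapse = ".")
  }, character(1))
}

#' @rdname ec_utils
#' @export
ec_complete_at <- function(ec, level) {
  stopifnot(length(level) == 1, level >= 1, level <= 4)
  parts <- parse_ec(ec)
  vapply(parts, function(p) {
    length(p) >= level && all(grepl("^[0-9]+$", p[seq_len(level)]))
  }, logical(1))
}

#' Construct a label table
#'
#' A label table maps protein chain identifiers to sets of EC numbers.
#' Chain identifiers are opaque, case-sensitive strings (conventionally a
#' PDB ID plus chain letter, e.g. `"2dz9A"`); no structural parsing is done.
#' Duplicate (chain, EC) rows collapse to a single entry (set semantics).
#'
#' @param chain_id character vector of chain identifiers.
#' @param ec character vector of EC strings, same length as `chain_id`.
#' @return a `data.frame` of class `label_table` with columns `chain_id`
#'   and `ec`, one row per distinct pair, ordered by chain then EC.
#' @examples
#' label_table(c("1abcA", "1abcA", "2defB"), c("3.1.1.1", "3.1.1.1", "2.7.7.7"))
#' @export
label_table <- function(chain_id, ec) {
  stopifnot(length(chain_id) == length(ec))
  parse_ec(ec)  # validates
  df <- unique(data.frame(chain_id = as.character(chain_id),
                          ec = as.character(ec),
                          stringsAsFactors = FALSE))
  df <- df[order(df$chain_id, df$ec), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("label_table", "data.frame")
  df
}

# chain -> character vector of ECs
label_sets <- function(labels) {
  split(labels$ec, labels$chain_id)
}

# distinct complete-at-level truncated functions present in a label table
label_functions <- function(labels, level) {
  ok <- ec_complete_at(labels$ec, level)
  sort(unique(truncate_ec(labels$ec[ok], level)))
}
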