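#' Count substitutions, insertions and deletions in an alignment
#'
#' Columns where both rows carry differing residues are substitutions;
#' query residues opposite a germline gap are insertions; germline residues
#' opposite a query gap are deletions. The germline is the concatenated V+J
#' reference, so non-templated junction residues are counted as
#' substitutions (a documented overestimate of true somatic mutation).
#'
#' @param aln A `pairwise_alignment` from [align_to_germline()].
#' @return Tibble with `substitutions`, `insertions`, `deletions` and
#'   `germline_length` (residues).
#' @export
count_differences <- function(aln) {
  q <- strsplit(aln$query_aligned, "")[[1]]
  g <- strsplit(aln$germline_aligned, "")[[1]]
  stopifnot(length(q) == length(g))
  tibble::tibble(
    substitutions = sum(q != "-" & g != "-" & q != g),
    insertions = sum(g == "-"),
    deletions = sum(q == "-"),
    germline_length = sum(g != "-"))
}

#' Fraction of mutated residues
#'
#' The mutation load of a V-domain relative to its germline of length L,
#' with S substitutions, I insertions and D deletions, is
#' \deqn{S/L + I/(L+I) + D/(L+D).}
#' It is zero exactly when all three counts are zero, and strictly
#' increasing in each count.
#'
#' @param substitutions,insertions,deletions Non-negative counts
#'   (vectorised).
#' @param germline_length Germline length in residues; must be positive.
#' @return Numeric vector of mutation fractions.
#' @export
#' @examples
#' fraction_mutated(2, 0, 0, 100)            # 0.02
#' fraction_mutated(1, 1, 1, 100)            # 0.01 + 1/101 + 1/101
fraction_mutated <- function(substitutions, insertions, deletions,
                             germline_length) {
  if (any(germline_length <= 0)) {
    stop("germline_length must be positive", call. = FALSE)
  }
  if (any(substitutions < 0 | insertions < 0 | deletions < 0)) {
    stop("mutation counts must be non-negative", call. = FALSE)
  }
  substitutions / germline_length +
    insertions / (germline_length + insertions) +
    deletions / (germline_length + deletions)
}

#' Mutation load for a set of sequences
#'
#' Aligns each query to its assigned V+J germline and reports mutation
#' counts, the mutation fraction, and the fraction as a percentage of
#' germline length (the scale used for group comparisons).
#'
#' @param queries Character vector of amino-acid sequences.
#' @param v_calls V gene name per sequence.
#' @param set A `germline_set`.
#' @param sequence_ids Identifiers (defaults to names of `queries` or an
#'   index).
#' @param ... Passed to [align_to_germline()].
#' @return Tibble with one row per sequence.
#' @export
mutation_load <- function(queries, v_calls, set, sequence_ids = NULL, ...) {
  n <- length(queries)
  stopifnot(length(v_calls) == n)
  ids <- sequence_ids %||% names(queries) %||% paste0("seq", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    v <- get_germline(set, v_calls[i])
    ref <- concat_germline(v, default_j_gene(set, v$locus))
    aln <- align_to_germline(queries[i], ref, sequence_id = ids[i], ...)
    mc <- count_differences(aln)
    mc$sequence_id <- ids[i]
    mc$v_call <- v$gene
    mc
  })
  out <- dplyr::bind_rows(rows)
  out$fraction <- fraction_mutated(out$substitutions, out$insertions,
                                   out$deletions, out$germline_length)
  out$percent <- 100 * out$fraction
  out[, c("sequence_id", "v_call", "substitutions", "insertions",
          "deletions", "germline_length", "fraction", "percent")]
}
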