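#' Region and strand maps for the IMGT V-domain scaffold
#'
#' The scaffold has 127 canonical positions. Region boundaries follow the
#' IMGT unique numbering convention (FR1 1-26, CDR1 27-38, FR2 39-55, CDR2
#' 56-65, FR3 66-104, CDR3 105-117, FR4 118-127); IMGT "strand" spans are
#' shipped as an editable table because they do not correspond exactly to
#' secondary-structure elements. Both maps can be replaced by the user.
#'
#' @param path Path to a TSV with columns `region` (or `strand`), `start`,
#'   `end`.
#' @return A tibble with one row per region/strand.
#' @export
read_region_map <- function(path = system.file("extdata", "region_map.tsv",
                                               package = "lcsequon")) {
  m <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                                           stringsAsFactors = FALSE))
  validate_interval_map(m, names(m)[1])
  m
}

#' @rdname read_region_map
#' @export
read_strand_map <- function(path = system.file("extdata", "strand_map.tsv",
                                               package = "lcsequon")) {
  m <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                                           stringsAsFactors = FALSE))
  validate_interval_map(m, names(m)[1])
  m
}

#' @rdname read_region_map
#' @export
default_region_map <- function() read_region_map()

#' @rdname read_region_map
#' @export
default_strand_map <- function() read_strand_map()

validate_interval_map <- function(m, label_col) {
  stopifnot(all(c("start", "end") %in% names(m)))
  if (any(m$start > m$end)) stop("interval map has start > end", call. = FALSE)
  o <- order(m$start)
  if (any(m$end[o][-nrow(m)] >= m$start[o][-1])) {
    stop(label_col, " intervals overlap", call. = FALSE)
  }
  invisible(m)
}

#' Label an IMGT position with its region or strand
#'
#' @param position Integer vector of canonical IMGT positions.
#' @param map A region or strand map tibble (see [read_region_map()]).
#' @return Character vector of labels; `NA` where no interval covers the
#'   position.
#' @export
position_label <- function(position, map) {
  lab_col <- setdiff(names(map), c("start", "end"))[1]
  out <- rep(NA_character_, length(position))
  for (r in seq_len(nrow(map))) {
    hit <- !is.na(position) & position >= map$start[r] & position <= map$end[r]
    out[hit] <- map[[lab_col]][r]
  }
  out
}

#' Number of scaffold positions where a motif can be observed
#'
#' A motif of span `k` cannot start within the final `k - 1` scaffold
#' positions, so for the 127-position V-domain scaffold and the 3-residue
#' sequon, 125 positions are available for analysis.
#'
#' @param scaffold_size Number of canonical positions (default 127).
#' @param motif_span Length of the motif in residues (default 3).
#' @return `scaffold_size - (motif_span - 1)`.
#' @export
#' @examples
#' count_detectable_positions(127, 3)  # 125
count_detectable_positions <- function(scaffold_size = 127L, motif_span = 3L) {
  if (!is.numeric(scaffold_size) || !is.numeric(motif_span) ||
      length(scaffold_size) != 1 || length(motif_span) != 1 ||
      motif_span < 1 || scaffold_size < motif_span) {
    stop("require scaffold_size >= motif_span >= 1", call. = FALSE)
  }
  as.integer(scaffold_size) - (as.integer(motif_span) - 1L)
}

#' Globally align a query V-domain to its germline
#'
#' Needleman-Wunsch global alignment with affine gap costs (BLOSUM62,
#' gap open 10, gap extend 1 by default), via [Biostrings::pairwiseAlignment].
#' Sequences containing non-standard residue letters are rejected;
#' alignments whose identity falls below `min_identity` are flagged as
#' having a dubious germline assignment.
#'
#' @param query Amino-acid string.
#' @param germline A `germline_record` (possibly V+J concatenated, see
#'   [concat_germline()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution_matrix Name of a substitution matrix bundled with
#'   Biostrings.
#' @param min_identity Identity floor below which the alignment is flagged
#'   `dubious` (default 0.5).
#' @param sequence_id Identifier used in error messages and downstream
#'   tables.
#' @return A `pairwise_alignment`: list with gapped `query_aligned` and
#'   `germline_aligned` strings, `score`, `identity`, `dubious` flag and
#'   `sequence_id`.
#' @export
align_to_germline <- function(query, germline, gap_open = 10, gap_extend = 1,
                              substitution_matrix = "BLOSUM62",
                              min_identity = 0.5,
                              sequence_id = "query") {
  if (!nzchar(query)) stop("empty query sequence: ", sequence_id, call. = FALSE)
  letters_q <- strsplit(query, "")[[1]]
  bad <- setdiff(unique(letters_q), AA_STANDARD)
  if (length(bad) > 0) {
    stop("sequence '", sequence_id, "' contains non-standard residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(germline$sequence),
    type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  identity <- Biostrings::pid(pa, type = "PID1") / 100
  dubious <- identity < min_identity
  if (dubious) {
    warning("sequence '", sequence_id, "': identity to germline '",
            germline$gene, "' is ", round(identity * 100, 1),
            "% -- dubious germline assignment")
  }
  structure(
    list(query_aligned = as.character(Biostrings::alignedPattern(pa)),
         germline_aligned = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa),
         identity = identity, dubious = dubious,
         sequence_id = sequence_id, germline_gene = germline$gene),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$sequence_id, " vs ", x$germline_gene,
      ": score ", round(x$score, 1), ", identity ",
      round(x$identity * 100, 1), "%\n", sep = "")
  cat(" query:    ", x$query_aligned, "\n", sep = "")
  cat(" germline: ", x$germline_aligned, "\n", sep = "")
  invisible(x)
}

#' Transfer IMGT numbering from a germline onto an aligned query
#'
#' Query residues aligned to germline residues inherit that residue's IMGT
#' position; query residues in insertion columns receive an insertion marker
#' (`"<anchor>.<k>"`) anchored to the preceding canonical position; germline
#' residues aligned to gaps leave their IMGT position unoccupied. The CDR3
#' stretch (query residues falling between the last position <= 104 and the
#' first position >= 118) is then renumbered inward from both ends over the
#' canonical CDR3 positions 105-117, following the IMGT junction
#' convention; residues beyond 13 become insertions anchored at 111.
#'
#' @param aln A `pairwise_alignment` from [align_to_germline()].
#' @param germline The `germline_record` used for the alignment.
#' @param region_map,strand_map Interval maps (see [read_region_map()]).
#' @return A `numbered_sequence`: tibble with columns `idx` (linear,
#'   1-based), `aa`, `imgt` (label, e.g. `"86"` or `"111.1"`), `insertion`,
#'   `region`, `strand`; attributes carry `sequence_id`, `locus`,
#'   `germline_gene`, `scaffold_size` and the `dubious` flag.
#' @export
transfer_numbering <- function(aln, germline,
                               region_map = default_region_map(),
                               strand_map = default_strand_map()) {
  g_al <- strsplit(aln$germline_aligned, "")[[1]]
  q_al <- strsplit(aln$query_aligned, "")[[1]]
  if (paste(g_al[g_al != "-"], collapse = "") != germline$sequence) {
    stop("alignment germline row does not match the germline record",
         call. = FALSE)
  }
  n_col <- length(g_al)
  q_i <- 0L
  g_i <- 0L
  idx <- integer(0); aa <- character(0); pos <- integer(0)
  anchor <- 0L; ins_k <- 0L
  ins_label <- character(0)
  for (col in seq_len(n_col)) {
    gq <- g_al[col] != "-"
    qq <- q_al[col] != "-"
    if (gq) g_i <- g_i + 1L
    if (qq) {
      q_i <- q_i + 1L
      idx <- c(idx, q_i)
      aa <- c(aa, q_al[col])
      if (gq) {
        p <- germline$imgt_positions[g_i]
        pos <- c(pos, p)
        ins_label <- c(ins_label, NA_character_)
        anchor <- p; ins_k <- 0L
      } else {
        ins_k <- ins_k + 1L
        pos <- c(pos, NA_integer_)
        ins_label <- c(ins_label, paste0(anchor, ".", ins_k))
      }
    }
  }
  ns <- tibble::tibble(idx = idx, aa = aa, imgt_num = pos, imgt = ins_label)
  ns$imgt[!is.na(ns$imgt_num)] <- as.character(ns$imgt_num[!is.na(ns$imgt_num)])
  ns$insertion <- is.na(ns$imgt_num)
  ns <- renumber_cdr3(ns)
  ns$region <- position_label(ns$imgt_num, region_map)
  ns$strand <- position_label(ns$imgt_num, strand_map)
  # insertions take the region of their anchor
  if (any(ns$insertion)) {
    anchor_num <- as.integer(sub("\\..*$", "", ns$imgt[ns$insertion]))
    ns$region[ns$insertion] <- position_label(anchor_num, region_map)
  }
  structure(ns[, c("idx", "aa", "imgt", "imgt_num", "insertion",
                   "region", "strand")],
            sequence_id = aln$sequence_id, locus = germline$locus,
            germline_gene = germline$gene, scaffold_size = 127L,
            dubious = aln$dubious,
            class = c("numbered_sequence", class(ns)))
}

# Renumber the CDR3 stretch inward from both ends (IMGT junction
# convention): k residues between FR3 (<=104) and FR4 (>=118) take
# 105..(104+ceil(k/2)) from the left and (118-floor(k/2))..117 from the
# right; with k > 13 the middle residues become insertions at 111.
renumber_cdr3 <- function(ns) {
  left_end <- max(c(0L, which(!is.na(ns$imgt_num) & ns$imgt_num <= 104L)))
  fr4_rows <- which(!is.na(ns$imgt_num) & ns$imgt_num >= 118L)
  right_start <- if (length(fr4_rows) > 0) min(fr4_rows) else nrow(ns) + 1L
  rows <- seq_len(nrow(ns))
  rows <- rows[rows > left_end & rows < right_start]
  k <- length(rows)
  if (k == 0) return(ns)
  n_left <- min(ceiling(k / 2), 7L)
  n_right <- min(floor(k / 2), 6L)
  labels_num <- rep(NA_integer_, k)
  labels_chr <- rep(NA_character_, k)
  labels_num[seq_len(n_left)] <- 104L + seq_len(n_left)
  if (n_right > 0) {
    labels_num[k - n_right + seq_len(n_right)] <- 117L - rev(seq_len(n_right)) + 1L
  }
  mid <- which(is.na(labels_num))
  if (length(mid) > 0) labels_chr[mid] <- paste0("111.", seq_along(mid))
  ns$imgt_num[rows] <- labels_num
  ns$imgt[rows] <- ifelse(is.na(labels_num), labels_chr,
                          as.character(labels_num))
  ns$insertion[rows] <- is.na(labels_num)
  ns
}

#' @export
print.numbered_sequence <- function(x, ...) {
  cat("<numbered_sequence> ", attr(x, "sequence_id"), " (",
      attr(x, "locus"), ", germline ", attr(x, "germline_gene"), "), ",
      nrow(x), " residues\n", sep = "")
  NextMethod()
}

#' Refresh region and strand labels on a numbered sequence
#'
#' @param ns A `numbered_sequence`.
#' @param region_map,strand_map Interval maps.
#' @return The `numbered_sequence` with `region`/`strand` recomputed.
#' @export
assign_regions <- function(ns, region_map = default_region_map(),
                           strand_map = default_strand_map()) {
  ns$region <- position_label(ns$imgt_num, region_map)
  ns$strand <- position_label(ns$imgt_num, strand_map)
  if (any(ns$insertion)) {
    anchor_num <- as.integer(sub("\\..*$", "", ns$imgt[ns$insertion]))
    ns$region[ns$insertion] <- position_label(anchor_num, region_map)
  }
  ns
}

#' Number a query sequence against its assigned germline genes
#'
#' Convenience wrapper: concatenates the V and J germline records, aligns
#' the query and transfers IMGT numbering.
#'
#' @param query Amino-acid string.
#' @param v_gene V gene name (aliases and alleles resolved).
#' @param set A `germline_set`.
#' @param j_gene J gene name; defaults to the locus's bundled J gene.
#' @param sequence_id Identifier for the query.
#' @param ... Passed to [align_to_germline()].
#' @return A `numbered_sequence`.
#' @export
number_sequence <- function(query, v_gene, set, j_gene = NULL,
                            sequence_id = "query", ...) {
  v <- get_germline(set, v_gene)
  j <- if (is.null(j_gene)) default_j_gene(set, v$locus)
       else get_germline(set, j_gene)
  ref <- concat_germline(v, j)
  aln <- align_to_germline(query, ref, sequence_id = sequence_id, ...)
  transfer_numbering(aln, ref)
}
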