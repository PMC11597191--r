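#' Scan sequences for sequon motifs
#'
#' Vectorised motif scan: returns, for each sequence, the 1-based linear
#' indices of every motif asparagine, including overlapping matches
#' (lookahead regular expression `N(?=[^P][ST])`, or `N(?=[^P]C)` for the
#' cysteine variant), left to right.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param kind `"NxST"` (default) or `"NxC"`.
#' @return List of integer vectors, one per sequence.
#' @export
#' @examples
#' scan_sequons(c("NNSS", "NPS"))
scan_sequons <- function(sequences, kind = c("NxST", "NxC")) {
  kind <- match.arg(kind)
  pattern <- if (kind == "NxST") "N(?=[^P][ST])" else "N(?=[^P]C)"
  lapply(gregexpr(pattern, sequences, perl = TRUE), function(m) {
    if (m[1] == -1) integer(0) else as.integer(m)
  })
}

# single-sequence core used by detect_sequons
scan_motif_indices <- function(sequence, kind = c("NxST", "NxC")) {
  scan_sequons(sequence, kind)[[1]]
}

#' Detect N-glycosylation sequons in a numbered sequence
#'
#' Scans for the NxS/T sequon (asparagine, any residue except proline, then
#' serine or threonine) or its cysteine variant NxC. All occurrences are
#' reported, including overlapping ones. Each hit is annotated with its IMGT
#' position (or insertion marker), region, strand, +2 residue, a context
#' window centred on the asparagine, and -- when the germline record is
#' supplied -- whether the position is a progenitor site or carries a
#' germline-encoded sequon.
#'
#' @param x A `numbered_sequence`, or a plain amino-acid string (in which
#'   case position annotations are `NA`).
#' @param kind `"NxST"` (default) or `"NxC"`. The two motif kinds are never
#'   merged: call once per kind.
#' @param germline Optional `germline_record` (with progenitor annotations)
#'   for the progenitor / germline-encoded flags.
#' @param context_window Half-width of the context window (default 5, i.e.
#'   offsets -5..+5); termini are padded with `"-"`.
#' @return A tibble of hits: `sequence_id`, `motif_kind`, `n_index` (linear,
#'   1-based), `imgt_position`, `imgt_num`, `insertion`, `region`, `strand`,
#'   `plus2`, `context`, `at_progenitor`, `germline_encoded`,
#'   `germline_motif_retained`. Zero rows when nothing matches.
#' @export
#' @examples
#' detect_sequons("AANGSA")
detect_sequons <- function(x, kind = c("NxST", "NxC"), germline = NULL,
                           context_window = 5L) {
  kind <- match.arg(kind)
  if (inherits(x, "numbered_sequence")) {
    seq_chr <- paste(x$aa, collapse = "")
    seq_id <- attr(x, "sequence_id")
  } else {
    stopifnot(is.character(x), length(x) == 1)
    seq_chr <- x
    seq_id <- "seq"
  }
  idx <- scan_motif_indices(seq_chr, kind)
  res <- strsplit(seq_chr, "")[[1]]
  hits <- tibble::tibble(
    sequence_id = rep(seq_id, length(idx)),
    motif_kind = rep(kind, length(idx)),
    n_index = idx,
    imgt_position = NA_character_,
    imgt_num = NA_integer_,
    insertion = NA,
    region = NA_character_,
    strand = NA_character_,
    plus2 = res[idx + 2L],
    context = context_windows(res, idx, context_window),
    at_progenitor = NA,
    germline_encoded = NA,
    germline_motif_retained = NA)
  if (inherits(x, "numbered_sequence") && length(idx) > 0) {
    hits$imgt_position <- x$imgt[idx]
    hits$imgt_num <- x$imgt_num[idx]
    hits$insertion <- x$insertion[idx]
    hits$region <- x$region[idx]
    hits$strand <- x$strand[idx]
    if (!is.null(germline)) {
      hits$at_progenitor <- hits$imgt_num %in% germline$progenitor_sites
      hits$germline_encoded <- hits$imgt_num %in% germline$encoded_sequons
      gres <- strsplit(germline$sequence, "")[[1]]
      hits$germline_motif_retained <- vapply(seq_along(idx), function(k) {
        p <- hits$imgt_num[k]
        if (is.na(p)) return(NA)
        gi <- match(p, germline$imgt_positions)
        if (is.na(gi) || gi + 2L > length(gres)) return(NA)
        identical(res[idx[k] + 0:2], gres[gi + 0:2])
      }, logical(1))
    }
  }
  hits
}

# context windows centred on each index, padded with "-" at termini
context_windows <- function(residues, idx, w) {
  if (length(idx) == 0) return(character(0))
  padded <- c(rep("-", w), residues, rep("-", w))
  vapply(idx, function(i) {
    paste(padded[i:(i + 2L * w)], collapse = "")
  }, character(1))
}

#' Most N-terminal sequon per sequence
#'
#' When a sequence harbours more than one sequon, position analyses use
#' only the first (most N-terminal) one.
#'
#' @param hits A hit tibble from [detect_sequons()] (possibly several
#'   sequences bound together).
#' @return One row per `sequence_id`, the hit with minimal `n_index`; zero
#'   rows for empty input.
#' @export
first_sequon <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::slice_min(.data$n_index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Sequon counts per detectable IMGT position
#'
#' @param hits A hit tibble. Hits at insertion markers (no canonical IMGT
#'   position) are excluded with a message.
#' @param n_positions Length of the detectable-position scaffold (default
#'   125, see [count_detectable_positions()]).
#' @return Named integer vector of counts, one per position `1..n_positions`;
#'   its sum equals the number of included hits.
#' @export
position_histogram <- function(hits, n_positions = count_detectable_positions()) {
  counts <- stats::setNames(integer(n_positions), as.character(seq_len(n_positions)))
  if (nrow(hits) == 0) return(counts)
  excluded <- is.na(hits$imgt_num)
  if (any(excluded)) {
    message(sum(excluded), " hit(s) at insertion markers excluded from the ",
            "position histogram")
  }
  keep <- hits$imgt_num[!excluded]
  keep <- keep[keep >= 1 & keep <= n_positions]
  tab <- table(factor(keep, levels = seq_len(n_positions)))
  counts[] <- as.integer(tab)
  counts
}

#' Fraction of NxS/T sequons with threonine at +2
#'
#' Threonine in the +2 position is associated with a higher frequency of
#' N-glycosylation than serine.
#'
#' @param hits A hit tibble containing NxS/T hits only.
#' @return List with `n_thr`, `n_total` and `fraction` (`NA` when there are
#'   no hits).
#' @export
plus2_threonine_fraction <- function(hits) {
  if (nrow(hits) > 0 && any(hits$motif_kind != "NxST")) {
    stop("plus2_threonine_fraction expects NxS/T hits only", call. = FALSE)
  }
  n_total <- nrow(hits)
  n_thr <- sum(hits$plus2 == "T")
  list(n_thr = n_thr, n_total = n_total,
       fraction = if (n_total == 0) NA_real_ else n_thr / n_total)
}

#' Fraction of sequons per region or strand
#'
#' @param hits A hit tibble with region/strand labels assigned.
#' @param by `"region"` or `"strand"`.
#' @return Tibble with `n` and `fraction` per label; fractions sum to 1
#'   over hits carrying a label.
#' @export
region_fractions <- function(hits, by = c("region", "strand")) {
  by <- match.arg(by)
  lab <- hits[[by]]
  keep <- !is.na(lab)
  tab <- table(lab[keep])
  tibble::tibble(!!by := names(tab),
                 n = as.integer(tab),
                 fraction = as.integer(tab) / sum(tab))
}
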