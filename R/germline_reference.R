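#' Canonical germline gene name
#'
#' Strips the allele suffix (e.g. `*01`) and maps distal-locus paralogues
#' (`IGKV1D-16`) to their proximal counterpart (`IGKV1-16`), which are
#' treated as identical genes.
#'
#' @param gene Character vector of gene names, with or without allele suffix.
#' @return Character vector of canonical gene symbols.
#' @export
#' @examples
#' canonical_gene_name(c("IGKV1D-16*02", "IGLV2-14"))
canonical_gene_name <- function(gene) {
  g <- sub("\\*.*$", "", gene)
  sub("^(IGKV[0-9]+)D-", "\\1-", g)
}

new_germline_record <- function(gene, locus, sequence, imgt_positions,
                                progenitor_sites = integer(0)) {
  stopifnot(nchar(sequence) == length(imgt_positions))
  if (is.unsorted(imgt_positions, strictly = TRUE)) {
    stop("IMGT positions of germline '", gene, "' are not strictly increasing",
         call. = FALSE)
  }
  res <- strsplit(sequence, "")[[1]]
  idx <- scan_motif_indices(sequence, kind = "NxST")
  structure(
    list(gene = gene, locus = locus, sequence = sequence,
         imgt_positions = as.integer(imgt_positions),
         encoded_sequons = as.integer(imgt_positions[idx]),
         progenitor_sites = as.integer(progenitor_sites)),
    class = "germline_record")
}

#' @export
print.germline_record <- function(x, ...) {
  cat("<germline_record> ", x$gene, " (", x$locus, "), ",
      nchar(x$sequence), " aa, IMGT ", min(x$imgt_positions), "-",
      max(x$imgt_positions), "\n", sep = "")
  if (length(x$encoded_sequons) > 0)
    cat("  germline-encoded sequons at:",
        paste(x$encoded_sequons, collapse = ", "), "\n")
  if (length(x$progenitor_sites) > 0)
    cat("  progenitor sites at:",
        paste(x$progenitor_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Read a germline V/J reference bundle
#'
#' Reads an IMGT-numbered germline reference set from a FASTA file whose
#' headers carry three pipe-delimited fields: `gene|locus|imgt_positions`,
#' where `imgt_positions` is a comma-separated list of the IMGT position of
#' each residue. Alleles of a gene (suffix `*01`, `*02`, ...) are collapsed
#' to the first listed allele; paralogous distal-locus genes with identical
#' sequences are registered as aliases of their proximal counterpart.
#'
#' The bundled reference set shipped with the package
#' (`germline_vj_synthetic.fasta`) is a constructed, synthetic stand-in for
#' the IMGT germline database: the sequences follow the canonical V-domain
#' architecture (conserved Cys23, Trp41, Cys104 and the IMGT region layout)
#' but are not the deposited human germline sequences. Replace it with a
#' real reference bundle for production analyses.
#'
#' @param path Path to the FASTA bundle. Defaults to the bundled synthetic
#'   reference set.
#' @return A `germline_set`: a list with `records` (named list of
#'   `germline_record`, keyed by canonical gene) and `aliases` (named
#'   character vector mapping alias to canonical gene).
#' @export
read_germline_set <- function(path = system.file("extdata",
                                                 "germline_vj_synthetic.fasta",
                                                 package = "lcsequon")) {
  if (!file.exists(path)) stop("germline bundle not found: ", path, call. = FALSE)
  fa <- Biostrings::readAAStringSet(path)
  if (length(fa) == 0) {
    warning("empty germline bundle: ", path)
    return(structure(list(records = list(), aliases = character(0)),
                     class = "germline_set"))
  }
  records <- list()
  aliases <- character(0)
  first_name <- character(0)  # full name (gene*allele) kept per canonical
  for (i in seq_along(fa)) {
    hdr <- names(fa)[i]
    fields <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(fields) != 3) {
      stop("malformed header (expected gene|locus|imgt_positions): '",
           hdr, "'", call. = FALSE)
    }
    full_gene <- fields[1]
    locus <- fields[2]
    if (!locus %in% c("IGK", "IGL")) {
      stop("record '", full_gene, "': locus must be IGK or IGL, got '",
           locus, "'", call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(strsplit(fields[3], ",")[[1]]))
    if (anyNA(pos)) {
      stop("record '", full_gene, "': IMGT position string does not parse",
           call. = FALSE)
    }
    seq <- as.character(fa[[i]])
    if (nchar(seq) != length(pos)) {
      stop("record '", full_gene, "': sequence length (", nchar(seq),
           ") != number of IMGT positions (", length(pos), ")", call. = FALSE)
    }
    bare <- sub("\\*.*$", "", full_gene)
    canon <- canonical_gene_name(full_gene)
    if (!canon %in% names(records)) {
      records[[canon]] <- new_germline_record(canon, locus, seq, pos)
      first_name[canon] <- full_gene
      if (bare != canon) aliases[bare] <- canon
    } else {
      existing <- records[[canon]]
      if (identical(full_gene, unname(first_name[canon])) &&
          !identical(seq, existing$sequence)) {
        stop("duplicate record '", full_gene,
             "' with conflicting sequence", call. = FALSE)
      }
      if (bare != canon && identical(seq, existing$sequence)) {
        aliases[bare] <- canon
      }
      # otherwise: a further allele; first listed allele is kept
    }
  }
  structure(list(records = records, aliases = aliases),
            class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  cat("<germline_set> ", length(x$records), " genes, ",
      length(x$aliases), " aliases\n", sep = "")
  invisible(x)
}

#' Look up a germline record, resolving aliases
#'
#' @param set A `germline_set`.
#' @param gene Gene name; allele suffixes are stripped and paralogue aliases
#'   resolved.
#' @return A `germline_record`.
#' @export
get_germline <- function(set, gene) {
  canon <- canonical_gene_name(gene)
  if (canon %in% names(set$aliases)) canon <- unname(set$aliases[canon])
  rec <- set$records[[canon]]
  if (is.null(rec)) stop("unknown germline gene: '", gene, "'", call. = FALSE)
  rec
}

#' @rdname get_germline
#' @export
germline_genes <- function(set) names(set$records)

#' Annotate progenitor N-glycosylation sites
#'
#' A progenitor site is a germline position where a single nucleotide change
#' suffices to create an NxS/T sequon in the translated protein. Because the
#' analysis is protein-only, sites are supplied as a gene-to-positions table
#' rather than computed from codons. The bundled table
#' (`progenitor_sites_synthetic.tsv`) is a reconstructed fixture and is
#' intended to be replaced by the user.
#'
#' @param set A `germline_set`.
#' @param table Data frame with columns `gene` and `position`, or a path to
#'   a two-column TSV. Defaults to the bundled synthetic table.
#' @return The `germline_set` with `progenitor_sites` populated.
#' @export
annotate_progenitor_sites <- function(set,
    table = system.file("extdata", "progenitor_sites_synthetic.tsv",
                        package = "lcsequon")) {
  if (is.character(table)) {
    table <- utils::read.table(table, header = TRUE, sep = "\t", quote = "",
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "position") %in% names(table)))
  canon <- canonical_gene_name(table$gene)
  canon <- ifelse(canon %in% names(set$aliases),
                  unname(set$aliases[canon])[match(canon, names(set$aliases))],
                  canon)
  unknown <- setdiff(unique(canon), names(set$records))
  if (length(unknown) > 0) {
    warning("progenitor table lists genes absent from the reference set, ",
            "skipped: ", paste(unknown, collapse = ", "))
  }
  for (g in intersect(unique(canon), names(set$records))) {
    pos <- sort(unique(as.integer(table$position[canon == g])))
    occupied <- set$records[[g]]$imgt_positions
    bad <- setdiff(pos, occupied)
    if (length(bad) > 0) {
      stop("progenitor position(s) ", paste(bad, collapse = ", "),
           " not occupied in germline '", g, "'", call. = FALSE)
    }
    set$records[[g]]$progenitor_sites <- pos
  }
  set
}

#' Write a germline set back to FASTA
#'
#' Serialises records (and alias entries, so that aliases survive a
#' round-trip) in the same `gene|locus|imgt_positions` header format read by
#' [read_germline_set()]. Progenitor annotations are not serialised; they
#' live in the separate progenitor table.
#'
#' @param set A `germline_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_germline_set <- function(set, path) {
  lines <- character(0)
  for (rec in set$records) {
    lines <- c(lines,
               sprintf(">%s|%s|%s", rec$gene, rec$locus,
                       paste(rec$imgt_positions, collapse = ",")),
               rec$sequence)
  }
  for (al in names(set$aliases)) {
    rec <- set$records[[set$aliases[[al]]]]
    lines <- c(lines,
               sprintf(">%s|%s|%s", al, rec$locus,
                       paste(rec$imgt_positions, collapse = ",")),
               rec$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate a V and a J germline record
#'
#' Builds the combined V+J reference used for numbering transfer and
#' mutation counting. The J record's IMGT positions must all lie after the
#' V record's.
#'
#' @param v,j `germline_record`s for the V and J gene.
#' @return A `germline_record` for the concatenated reference, named after
#'   the V gene.
#' @export
concat_germline <- function(v, j) {
  if (v$locus != j$locus) stop("V and J records are from different loci",
                               call. = FALSE)
  if (max(v$imgt_positions) >= min(j$imgt_positions)) {
    stop("J positions must follow V positions", call. = FALSE)
  }
  rec <- new_germline_record(
    gene = v$gene, locus = v$locus,
    sequence = paste0(v$sequence, j$sequence),
    imgt_positions = c(v$imgt_positions, j$imgt_positions),
    progenitor_sites = v$progenitor_sites)
  rec$j_gene <- j$gene
  rec
}

#' Default J gene for a locus
#'
#' @param set A `germline_set`.
#' @param locus `"IGK"` or `"IGL"`.
#' @return The first J-gene `germline_record` for that locus.
#' @export
default_j_gene <- function(set, locus) {
  jn <- names(set$records)[vapply(set$records, function(r) {
    r$locus == locus && grepl("J", r$gene)
  }, logical(1))]
  if (length(jn) == 0) stop("no J gene for locus ", locus, call. = FALSE)
  set$records[[jn[1]]]
}
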