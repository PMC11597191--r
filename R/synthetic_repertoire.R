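#' Configuration for a synthetic light-chain repertoire
#'
#' Defines the generative model used to emulate germline-derived light
#' chains carrying somatic point substitutions (and optional indels), with
#' a group-dependent probability that a progenitor site is mutated into an
#' NxS/T sequon -- the mechanism by which somatic hypermutation is thought
#' to create sequons in antibodies.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   output.
#' @param n_per_group Sequences per group.
#' @param groups Named list of group specifications, each a list with:
#'   `usage` (named probability vector over germline V genes, must sum to
#'   1), `sub_rate` (per-residue substitution probability), `indel_rate`
#'   (per-sequence expected indel events; default 0, keeping numbering
#'   crisp), `conversion_prob` (probability that one progenitor site is
#'   converted into a sequon), `plus2_T_prob` (probability the introduced
#'   sequon gets threonine rather than serine at +2; default 0.5),
#'   `extra_sub_rate` (additional per-residue substitution rate applied to
#'   sequon-bearing sequences; default 0).
#' @return A validated `repertoire_config`.
#' @export
repertoire_config <- function(seed = 1L, n_per_group = 100L, groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  groups <- lapply(groups, function(g) {
    g$indel_rate <- g$indel_rate %||% 0
    g$plus2_T_prob <- g$plus2_T_prob %||% 0.5
    g$extra_sub_rate <- g$extra_sub_rate %||% 0
    probs <- c(g$sub_rate, g$indel_rate, g$conversion_prob,
               g$plus2_T_prob, g$extra_sub_rate)
    if (any(probs < 0 | probs > 1)) {
      stop("group rates/probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(g$usage) || is.null(names(g$usage)) ||
        abs(sum(g$usage) - 1) > 1e-8) {
      stop("each group needs a named usage distribution summing to 1",
           call. = FALSE)
    }
    g
  })
  structure(list(seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 groups = groups),
            class = "repertoire_config")
}

#' Generate a labelled synthetic repertoire
#'
#' For each sequence: a germline V gene is drawn from the group's usage
#' distribution and concatenated with the locus J gene; point substitutions
#' are applied at the group's rate (sampling uniformly among the 19 other
#' standard residues, never introducing ambiguous letters); with the
#' group's conversion probability, one progenitor site is converted into a
#' sequon by writing N at the site and S or T at +2 (restoring the germline
#' residue at +1 if a background substitution had placed a proline there);
#' sequon-bearing sequences optionally receive extra substitutions. Truth
#' labels record the gene, mutated positions, and whether/where a sequon
#' was introduced. Background substitutions may also create sequons
#' spontaneously at non-progenitor sites, as in real repertoires; the truth
#' table distinguishes the two via `sequon_introduced`.
#'
#' @param config A `repertoire_config`.
#' @param set A `germline_set` with progenitor sites annotated.
#' @return Tibble with one row per sequence: `sequence_id`, `group`,
#'   `locus`, `v_call`, `j_call`, `sequence_aa`, `n_substitutions`,
#'   `mutated_positions` (comma-separated IMGT positions),
#'   `sequon_introduced`, `introduced_position` (IMGT), `introduced_plus2`.
#' @export
generate_repertoire <- function(config, set = NULL) {
  stopifnot(inherits(config, "repertoire_config"))
  if (is.null(set)) set <- annotate_progenitor_sites(read_germline_set())
  for (g in config$groups) {
    unknown <- setdiff(names(g$usage), germline_genes(set))
    unknown <- unknown[!canonical_gene_name(unknown) %in% germline_genes(set)]
    if (length(unknown) > 0) {
      stop("usage distribution over unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(config$seed)
  out <- list()
  for (grp in names(config$groups)) {
    gs <- config$groups[[grp]]
    genes <- sample(names(gs$usage), config$n_per_group, replace = TRUE,
                    prob = gs$usage)
    for (gene in unique(genes)) {
      n_g <- sum(genes == gene)
      v <- get_germline(set, gene)
      j <- default_j_gene(set, v$locus)
      ref <- concat_germline(v, j)
      sim <- simulate_gene_batch(ref, n_g, gs)
      sim$group <- grp
      sim$locus <- v$locus
      sim$v_call <- v$gene
      sim$j_call <- j$gene
      out[[length(out) + 1]] <- sim
    }
  }
  res <- dplyr::bind_rows(out)
  res$sequence_id <- sprintf("%s_%06d", res$group, stats::ave(
    seq_len(nrow(res)), res$group, FUN = seq_along))
  res[, c("sequence_id", "group", "locus", "v_call", "j_call",
          "sequence_aa", "n_substitutions", "mutated_positions",
          "sequon_introduced", "introduced_position", "introduced_plus2")]
}

# vectorised simulation of n sequences from one V+J reference
simulate_gene_batch <- function(ref, n, gs) {
  base <- strsplit(ref$sequence, "")[[1]]
  L <- length(base)
  pos <- ref$imgt_positions
  mat <- matrix(rep(base, each = n), nrow = n)
  aa_idx <- match(base, AA_STANDARD)

  mutate_cells <- function(mat, mask) {
    if (!any(mask)) return(mat)
    cur <- match(mat[mask], AA_STANDARD)
    step <- sample.int(19L, sum(mask), replace = TRUE)
    mat[mask] <- AA_STANDARD[((cur + step - 1L) %% 20L) + 1L]
    mat
  }
  mask <- matrix(stats::runif(n * L) < gs$sub_rate, nrow = n)
  mat <- mutate_cells(mat, mask)

  convert <- stats::runif(n) < gs$conversion_prob
  site_pos <- rep(NA_integer_, n)
  plus2 <- rep(NA_character_, n)
  sites <- ref$progenitor_sites
  if (any(convert) && length(sites) > 0) {
    pick <- sites[sample.int(length(sites), sum(convert), replace = TRUE)]
    site_pos[convert] <- pick
    si <- match(pick, pos)
    rows <- which(convert)
    mat[cbind(rows, si)] <- "N"
    # +1 must not be proline; restore germline if a substitution made it P
    p1 <- mat[cbind(rows, si + 1L)]
    mat[cbind(rows, si + 1L)] <- ifelse(p1 == "P", base[si + 1L], p1)
    plus2[convert] <- ifelse(stats::runif(sum(convert)) < gs$plus2_T_prob,
                             "T", "S")
    mat[cbind(rows, si + 2L)] <- plus2[convert]
  } else {
    convert[] <- FALSE
  }

  if (gs$extra_sub_rate > 0 && any(convert)) {
    rows <- which(convert)
    extra <- matrix(stats::runif(length(rows) * L) < gs$extra_sub_rate,
                    nrow = length(rows))
    # keep the introduced motif intact
    si <- match(site_pos[rows], pos)
    extra[cbind(seq_along(rows), si)] <- FALSE
    extra[cbind(seq_along(rows), si + 1L)] <- FALSE
    extra[cbind(seq_along(rows), si + 2L)] <- FALSE
    sub <- mat[rows, , drop = FALSE]
    sub <- mutate_cells(sub, extra)
    mat[rows, ] <- sub
  }

  seqs <- apply(mat, 1, paste, collapse = "")
  diff_mask <- mat != matrix(rep(base, each = n), nrow = n)
  n_subs <- as.integer(rowSums(diff_mask))
  mut_pos <- vapply(seq_len(n), function(i) {
    paste(pos[diff_mask[i, ]], collapse = ",")
  }, character(1))

  if (gs$indel_rate > 0) {
    n_events <- stats::rbinom(n, 1L, gs$indel_rate)
    for (i in which(n_events > 0)) {
      s <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(length(s) - 2L, 1L) + 1L
      if (stats::runif(1) < 0.5) s <- s[-at] else s <- append(s, s[at], at)
      seqs[i] <- paste(s, collapse = "")
    }
  }

  tibble::tibble(sequence_aa = seqs, n_substitutions = n_subs,
                 mutated_positions = mut_pos,
                 sequon_introduced = convert,
                 introduced_position = site_pos,
                 introduced_plus2 = plus2)
}

#' Write a repertoire to FASTA / truth TSV / config echo
#'
#' @param repertoire Tibble from [generate_repertoire()].
#' @param fasta,truth Paths for the FASTA (headers
#'   `sequence_id|locus|v_call`) and the truth-label TSV.
#' @param config Optional `repertoire_config`, echoed to `config_json`.
#' @param config_json Optional path for a JSON echo of the configuration.
#' @return Invisibly, the paths written.
#' @export
write_repertoire <- function(repertoire, fasta = NULL, truth = NULL,
                             config = NULL, config_json = NULL) {
  paths <- character(0)
  if (!is.null(fasta)) {
    lines <- rbind(sprintf(">%s|%s|%s", repertoire$sequence_id,
                           repertoire$locus, repertoire$v_call),
                   repertoire$sequence_aa)
    writeLines(as.vector(lines), fasta)
    paths <- c(paths, fasta)
  }
  if (!is.null(truth)) {
    utils::write.table(repertoire, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth)
  }
  if (!is.null(config_json) && !is.null(config)) {
    jsonlite::write_json(unclass(config), config_json, auto_unbox = TRUE,
                         pretty = TRUE)
    paths <- c(paths, config_json)
  }
  invisible(paths)
}

#' Read a repertoire from FASTA or AIRR-style TSV
#'
#' FASTA headers must carry `sequence_id|locus|v_call`; TSV input must have
#' columns `sequence_id`, `locus`, `v_call`, `sequence_aa`.
#'
#' @param path Input file (`.fasta`/`.fa` or `.tsv`).
#' @return Tibble with `sequence_id`, `locus`, `v_call`, `sequence_aa`.
#' @export
read_repertoire <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    df <- tibble::as_tibble(utils::read.table(path, header = TRUE,
                                              sep = "\t",
                                              stringsAsFactors = FALSE))
    need <- c("sequence_id", "locus", "v_call", "sequence_aa")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      stop("input '", path, "' lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(df[, need])
  }
  fa <- Biostrings::readAAStringSet(path)
  if (length(fa) == 0) stop("empty input: ", path, call. = FALSE)
  fields <- strsplit(names(fa), "|", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    stop("malformed FASTA header in '", path, "': '", names(fa)[bad[1]],
         "'", call. = FALSE)
  }
  tibble::tibble(sequence_id = vapply(fields, `[`, "", 1),
                 locus = vapply(fields, `[`, "", 2),
                 v_call = vapply(fields, `[`, "", 3),
                 sequence_aa = unname(as.character(fa)))
}
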