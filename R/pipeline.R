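#' Sequon prevalence statistics from grouped counts
#'
#' Counts-only entry point: the headline prevalence odds ratios are
#' reproducible from published summary counts without any sequence data.
#' Takes a table of with/without-sequon counts per cohort and locus and
#' computes cross-product and GLM odds ratios for each requested
#' comparison, overall and per locus, with BH-FDR across the family.
#'
#' @param counts Data frame with columns `origin`, `locus`, `with_sequon`,
#'   `without_sequon`. Defaults to the bundled cohort count table
#'   (AL/MM/OAS by kappa/lambda).
#' @param comparisons List of 2-vectors `c(group_a, group_b)`.
#' @param adjust Adjustment policy passed to [odds_ratio_manual()].
#' @return Tibble with one row per comparison x scope (`all`, `IGK`,
#'   `IGL`) x estimator, with `fdr` filled across the manual rows.
#' @export
#' @examples
#' sequon_prevalence_stats()
sequon_prevalence_stats <- function(counts = NULL,
                                    comparisons = list(c("AL", "MM"),
                                                       c("AL", "OAS")),
                                    adjust = "zero") {
  if (is.null(counts)) {
    counts <- tibble::as_tibble(utils::read.table(
      system.file("extdata", "cohort_sequon_counts.tsv",
                  package = "lcsequon"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  }
  need <- c("origin", "locus", "with_sequon", "without_sequon")
  stopifnot(all(need %in% names(counts)))
  scope_counts <- function(origin, scope) {
    sub <- counts[counts$origin == origin, ]
    if (scope != "all") sub <- sub[sub$locus == scope, ]
    if (nrow(sub) == 0) stop("no counts for origin '", origin, "', scope '",
                             scope, "'", call. = FALSE)
    c(with_sequon = sum(sub$with_sequon), without = sum(sub$without_sequon))
  }
  rows <- list()
  for (cmp in comparisons) {
    for (scope in c("all", unique(counts$locus))) {
      a <- scope_counts(cmp[1], scope)
      b <- scope_counts(cmp[2], scope)
      man <- odds_ratio_manual(a[1], a[2], b[1], b[2], adjust = adjust)
      glm_ <- odds_ratio_glm(a[1], a[2], b[1], b[2])
      man$comparison <- glm_$comparison <- paste(cmp[1], "vs", cmp[2])
      man$scope <- glm_$scope <- scope
      rows[[length(rows) + 1]] <- man
      rows[[length(rows) + 1]] <- glm_
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("comparison", "scope", "method",
                 setdiff(names(out), c("comparison", "scope", "method")))]
  manual <- out$method == "manual_adjusted" & !is.na(out$p_value)
  out$fdr[manual] <- bh_adjust(out$p_value[manual])
  out
}

#' Per-gene sequon enrichment
#'
#' Compares the fraction of sequon-bearing sequences between two groups
#' within each germline gene, reporting only genes with at least
#' `min_group_n` sequences in the first group, with BH-FDR across the
#' reported genes.
#'
#' @param data Tibble with columns `group`, `v_call` and logical
#'   `has_sequon`.
#' @param group_a,group_b Group labels to compare (A vs B).
#' @param min_group_n Minimum group-A sequences per gene (default 10).
#' @return Tibble of per-gene contingency results, `fdr`-adjusted.
#' @export
per_gene_enrichment <- function(data, group_a, group_b, min_group_n = 10L) {
  stopifnot(all(c("group", "v_call", "has_sequon") %in% names(data)))
  data <- data[data$group %in% c(group_a, group_b), ]
  genes <- unique(data$v_call[data$group == group_a])
  rows <- list()
  for (g in genes) {
    sub <- data[data$v_call == g, ]
    n_a <- sum(sub$group == group_a)
    if (n_a < min_group_n) next
    a <- sum(sub$group == group_a & sub$has_sequon)
    b <- n_a - a
    c_ <- sum(sub$group == group_b & sub$has_sequon)
    d <- sum(sub$group == group_b & !sub$has_sequon)
    r <- odds_ratio_manual(a, b, c_, d)
    r$v_call <- g
    rows[[length(rows) + 1]] <- r
  }
  if (length(rows) == 0) {
    return(tibble::tibble())
  }
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  out[, c("v_call", setdiff(names(out), "v_call"))]
}

#' Run the full sequon analysis pipeline
#'
#' Orchestrates: numbering of each sequence against its assigned germline,
#' NxS/T and NxC sequon detection, mutation-load computation, and group
#' statistics (prevalence odds ratios, per-gene enrichment, +2 threonine
#' fractions, positional histograms and their Pearson correlations, region
#' fractions, logo matrices, Wilcoxon mutation comparisons). Sequences
#' with ambiguous residues or failed numbering are excluded and accounted
#' for in the result's `exclusions` element.
#'
#' @param repertoire Tibble with `sequence_id`, `group`, `locus`, `v_call`,
#'   `sequence_aa` (e.g. from [generate_repertoire()] or
#'   [read_repertoire()]).
#' @param set A `germline_set` (progenitor-annotated); defaults to the
#'   bundled reference.
#' @param fdr_threshold Significance threshold on BH-FDR (default 0.05).
#' @param min_gene_n Minimum group-A sequences per gene for per-gene
#'   comparisons.
#' @param compute_mutations Set `FALSE` to skip the (alignment-heavy)
#'   mutation stage.
#' @param output_dir Optional directory; when given, per-stage TSVs and a
#'   JSON summary are written.
#' @return List with `sequences` (per-sequence annotations), `hits`,
#'   `nxc_hits`, `prevalence`, `per_gene`, `histograms`, `correlations`,
#'   `plus2`, `region_fractions`, `logos`, `mutations`,
#'   `mutation_tests`, `exclusions`, `fdr_threshold`.
#' @export
run_pipeline <- function(repertoire, set = NULL, fdr_threshold = 0.05,
                         min_gene_n = 10L, compute_mutations = TRUE,
                         output_dir = NULL) {
  stopifnot(is.data.frame(repertoire))
  if (nrow(repertoire) == 0) stop("empty repertoire input", call. = FALSE)
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) {
    stop("fdr_threshold must lie in (0, 1)", call. = FALSE)
  }
  need <- c("sequence_id", "group", "locus", "v_call", "sequence_aa")
  miss <- setdiff(need, names(repertoire))
  if (length(miss) > 0) stop("repertoire lacks column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(set)) set <- annotate_progenitor_sites(read_germline_set())

  ambiguous <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"),
                     repertoire$sequence_aa)
  excl <- list(ambiguous_residues = repertoire$sequence_id[ambiguous])
  rep_ok <- repertoire[!ambiguous, ]

  hits_l <- list(); nxc_l <- list(); failed <- character(0)
  has_sequon <- logical(nrow(rep_ok))
  for (i in seq_len(nrow(rep_ok))) {
    ns <- tryCatch(
      number_sequence(rep_ok$sequence_aa[i], rep_ok$v_call[i], set,
                      sequence_id = rep_ok$sequence_id[i]),
      error = function(e) NULL)
    if (is.null(ns)) {
      failed <- c(failed, rep_ok$sequence_id[i])
      next
    }
    germ <- get_germline(set, rep_ok$v_call[i])
    h <- detect_sequons(ns, "NxST", germline = germ)
    x <- detect_sequons(ns, "NxC", germline = germ)
    has_sequon[i] <- nrow(h) > 0
    if (nrow(h) > 0) {
      h$group <- rep_ok$group[i]; h$locus <- rep_ok$locus[i]
      h$v_call <- rep_ok$v_call[i]
      hits_l[[length(hits_l) + 1]] <- h
    }
    if (nrow(x) > 0) {
      x$group <- rep_ok$group[i]; x$locus <- rep_ok$locus[i]
      x$v_call <- rep_ok$v_call[i]
      nxc_l[[length(nxc_l) + 1]] <- x
    }
  }
  excl$numbering_failed <- failed
  rep_ok$has_sequon <- has_sequon
  rep_ok <- rep_ok[!rep_ok$sequence_id %in% failed, ]
  hits <- dplyr::bind_rows(hits_l)
  nxc <- dplyr::bind_rows(nxc_l)
  firsts <- first_sequon(hits)
  if (nrow(firsts) > 0) {
    excl$insertion_position_sequons <-
      firsts$sequence_id[is.na(firsts$imgt_num)]
  } else {
    excl$insertion_position_sequons <- character(0)
  }

  groups <- sort(unique(rep_ok$group))
  counts <- rep_ok |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(with_sequon = sum(.data$has_sequon),
                     without_sequon = sum(!.data$has_sequon),
                     .groups = "drop") |>
    dplyr::rename(origin = "group")
  prevalence <- if (length(groups) >= 2) {
    sequon_prevalence_stats(counts,
      comparisons = utils::combn(groups, 2, simplify = FALSE))
  } else NULL

  per_gene <- if (length(groups) >= 2) {
    per_gene_enrichment(rep_ok, groups[1], groups[2],
                        min_group_n = min_gene_n)
  } else NULL

  histograms <- list(); plus2 <- list(); regf <- list(); logos <- list()
  key <- function(g, l) paste(g, l, sep = ".")
  if (nrow(firsts) > 0) {
    for (g in groups) for (l in unique(rep_ok$locus)) {
      sel <- firsts$group == g & firsts$locus == l
      sub <- firsts[sel, ]
      histograms[[key(g, l)]] <- suppressMessages(position_histogram(sub))
      plus2[[key(g, l)]] <- plus2_threonine_fraction(sub)
      regf[[key(g, l)]] <- region_fractions(sub)
      if (nrow(sub) > 0) logos[[key(g, l)]] <- logo_matrix(sub$context)
    }
  }
  correlations <- list()
  hn <- names(histograms)
  if (length(hn) >= 2) {
    for (i in seq_along(hn)) for (j in seq_along(hn)) {
      if (i < j) {
        correlations[[paste(hn[i], "vs", hn[j])]] <-
          suppressWarnings(
            pearson_position_correlation(histograms[[hn[i]]],
                                         histograms[[hn[j]]]))
      }
    }
  }

  mutations <- NULL; mutation_tests <- NULL
  if (compute_mutations) {
    mutations <- mutation_load(rep_ok$sequence_aa, rep_ok$v_call, set,
                               sequence_ids = rep_ok$sequence_id)
    mutations$group <- rep_ok$group
    mutations$locus <- rep_ok$locus
    mutations$has_sequon <- rep_ok$has_sequon
    mt <- list()
    for (g in groups) for (l in unique(rep_ok$locus)) {
      sub <- mutations[mutations$group == g & mutations$locus == l, ]
      if (sum(sub$has_sequon) > 0 && sum(!sub$has_sequon) > 0) {
        wt <- wilcoxon_rank_sum(sub$percent[sub$has_sequon],
                                sub$percent[!sub$has_sequon])
        wt$median_shift <- stats::median(sub$percent[sub$has_sequon]) -
          stats::median(sub$percent[!sub$has_sequon])
        mt[[key(g, l)]] <- wt
      }
    }
    if (length(mt) > 0) {
      p <- vapply(mt, `[[`, numeric(1), "p_value")
      fdr <- bh_adjust(p)
      for (i in seq_along(mt)) mt[[i]]$fdr <- fdr[i]
    }
    mutation_tests <- mt
  }

  result <- list(sequences = rep_ok, hits = hits, nxc_hits = nxc,
                 first_hits = firsts, prevalence = prevalence,
                 per_gene = per_gene, histograms = histograms,
                 correlations = correlations, plus2 = plus2,
                 region_fractions = regf, logos = logos,
                 mutations = mutations, mutation_tests = mutation_tests,
                 exclusions = excl, fdr_threshold = fdr_threshold)
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      utils::write.table(df, file.path(output_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  tsv(result$sequences, "sequences.tsv")
  tsv(result$hits, "sequon_hits.tsv")
  tsv(result$nxc_hits, "nxc_hits.tsv")
  tsv(result$prevalence, "prevalence.tsv")
  tsv(result$per_gene, "per_gene.tsv")
  tsv(result$mutations, "mutations.tsv")
  summary <- list(
    n_sequences = nrow(result$sequences),
    exclusions = lapply(result$exclusions, length),
    histograms = result$histograms,
    correlations = result$correlations,
    plus2 = result$plus2,
    mutation_tests = result$mutation_tests,
    logos = lapply(result$logos, function(m) {
      list(residues = rownames(m), offsets = colnames(m),
           frequencies = unclass(m))
    }),
    fdr_threshold = result$fdr_threshold)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
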