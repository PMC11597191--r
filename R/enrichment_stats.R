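#' Odds ratio from a 2x2 table, cross-product estimator
#'
#' For counts `a` (group A with sequon), `b` (A without), `c` (B with), `d`
#' (B without), the odds ratio is `(a d) / (b c)` with a Wald 95% CI
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. To avoid division by
#' zero an adjustment factor (default 0.1) can be added to the cells:
#' either only when some cell is zero (the default, which leaves tables of
#' non-zero counts exact), always, or never.
#'
#' @param a,b,c,d Non-negative counts.
#' @param adjustment Value added to cells (default 0.1).
#' @param adjust When to apply the adjustment: `"zero"` (only if any cell is
#'   0), `"always"`, or `"never"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: the four counts, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value` (two-sided Wald), `fdr` (`NA`, filled by the
#'   caller across a family via [bh_adjust()]), `method`, `undefined` flag
#'   (all-zero table).
#' @export
#' @examples
#' odds_ratio_manual(106, 578, 100, 869)  # OR 1.59
odds_ratio_manual <- function(a, b, c, d, adjustment = 0.1,
                              adjust = c("zero", "always", "never"),
                              conf_level = 0.95) {
  adjust <- match.arg(adjust)
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (adjustment < 0) stop("adjustment must be >= 0", call. = FALSE)
  undefined <- all(counts == 0)
  apply_adj <- !undefined && (adjust == "always" ||
                              (adjust == "zero" && any(counts == 0)))
  cells <- if (apply_adj) counts + adjustment else counts
  if (undefined || any(cells == 0)) {
    or <- NA_real_; lo <- NA_real_; hi <- NA_real_; p <- NA_real_
    undefined <- TRUE
  } else {
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- exp(log(or) - z * se)
    hi <- exp(log(or) + z * se)
    p <- 2 * stats::pnorm(-abs(log(or) / se))
  }
  tibble::tibble(group_a_with = a, group_a_without = b,
                 group_b_with = c, group_b_without = d,
                 odds_ratio = or, ci_low = lo, ci_high = hi,
                 p_value = p, fdr = NA_real_,
                 method = "manual_adjusted", undefined = undefined)
}

#' Odds ratio via logistic regression
#'
#' Fits a binomial GLM of sequon presence on group membership, optionally
#' stratified (one 2x2 table per stratum, e.g. locus or precursor gene,
#' entering as a covariate). On an unstratified all-non-zero 2x2 table the
#' exponentiated group coefficient equals the cross-product odds ratio.
#' When any cell is zero the fit is separable, so the function falls back
#' to [odds_ratio_manual()] with a warning.
#'
#' @param a,b,c,d Count vectors, one element per stratum.
#' @param strata Optional factor naming the strata (defaults to a single
#'   stratum).
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble in the same layout as [odds_ratio_manual()], with
#'   `method = "glm"` (pooled counts in the count columns).
#' @export
odds_ratio_glm <- function(a, b, c, d, strata = NULL, conf_level = 0.95) {
  n_str <- length(a)
  stopifnot(length(b) == n_str, length(c) == n_str, length(d) == n_str)
  if (is.null(strata)) strata <- rep("all", n_str)
  if (any(c(a, b, c, d) == 0)) {
    warning("zero cell: falling back to the manually adjusted odds ratio")
    out <- odds_ratio_manual(sum(a), sum(b), sum(c), sum(d),
                             conf_level = conf_level)
    return(out)
  }
  df <- data.frame(
    with_sequon = c(a, c), without = c(b, d),
    group = rep(c("A", "B"), each = n_str),
    stratum = factor(rep(strata, 2)))
  df$group <- stats::relevel(factor(df$group), ref = "B")
  fml <- if (nlevels(df$stratum) > 1) {
    cbind(with_sequon, without) ~ group + stratum
  } else {
    cbind(with_sequon, without) ~ group
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  est <- summary(fit)$coefficients["groupA", ]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(group_a_with = sum(a), group_a_without = sum(b),
                 group_b_with = sum(c), group_b_without = sum(d),
                 odds_ratio = exp(est[["Estimate"]]),
                 ci_low = exp(est[["Estimate"]] - z * est[["Std. Error"]]),
                 ci_high = exp(est[["Estimate"]] + z * est[["Std. Error"]]),
                 p_value = est[["Pr(>|z|)"]], fdr = NA_real_,
                 method = "glm", undefined = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust]), with input
#' validation; adjusted values are order-preserving with the input, each at
#' least the raw p-value and at most 1. FDR <= 0.05 is the conventional
#' significance threshold in this analysis.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon rank-sum test between two samples
#'
#' Two-sided rank-sum test: exact null distribution when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `statistic` (W), `p_value` and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact)
}

#' Pearson correlation between two positional histograms
#'
#' Correlates sequon counts across the detectable-position scaffold,
#' including positions where no sequon was observed; the p-value comes from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param hist_a,hist_b Equal-length count vectors over the scaffold.
#' @return List with `r`, `p_value`, `n` and an `undefined` flag (set, with
#'   `NA` estimates, when either vector has zero variance).
#' @export
pearson_position_correlation <- function(hist_a, hist_b) {
  if (length(hist_a) != length(hist_b)) {
    stop("histograms must have equal length", call. = FALSE)
  }
  if (stats::var(hist_a) == 0 || stats::var(hist_b) == 0) {
    warning("zero-variance histogram: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(hist_a),
                undefined = TRUE))
  }
  ct <- stats::cor.test(hist_a, hist_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(hist_a),
       undefined = FALSE)
}

#' Residue-frequency matrix for sequence logos
#'
#' Per-offset residue frequencies for the windows around each sequon
#' asparagine (offset 0). Frequencies are scaled by residue frequency, not
#' information content; terminal padding symbols are excluded from the
#' denominators.
#'
#' @param contexts Character vector of context windows of equal odd length,
#'   centred on N (see [detect_sequons()]).
#' @param pad Padding symbol (default `"-"`).
#' @return A `logo_matrix`: numeric matrix, rows = residues, columns =
#'   offsets (`"-5"` .. `"5"`); each column sums to 1 over observed
#'   residues.
#' @export
logo_matrix <- function(contexts, pad = "-") {
  stopifnot(length(contexts) > 0)
  w <- unique(nchar(contexts))
  if (length(w) != 1 || w %% 2 != 1) {
    stop("contexts must share one odd window length", call. = FALSE)
  }
  half <- (w - 1) / 2
  mat <- do.call(rbind, strsplit(contexts, ""))
  if (any(mat[, half + 1] != "N")) {
    stop("every context must be centred on N", call. = FALSE)
  }
  offsets <- as.character(-half:half)
  residues <- sort(setdiff(unique(as.vector(mat)), pad))
  freq <- matrix(0, nrow = length(residues), ncol = w,
                 dimnames = list(residues, offsets))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col != pad]
    if (length(col) > 0) {
      tab <- table(factor(col, levels = residues))
      freq[, j] <- as.numeric(tab) / length(col)
    }
  }
  structure(freq, class = c("logo_matrix", "matrix"))
}
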