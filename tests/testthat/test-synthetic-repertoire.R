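test_that("config validation rejects bad probabilities and usage", {
  expect_error(repertoire_config(groups = list(A = list(
    usage = c(IGKV = 0.5), sub_rate = 0, conversion_prob = 0))),
    "summing to 1")
  expect_error(repertoire_config(groups = list(A = list(
    usage = c(IGKV = 1), sub_rate = 1.5, conversion_prob = 0))),
    "\\[0, 1\\]")
  cfg <- repertoire_config(seed = 2, n_per_group = 5, groups = list(
    A = list(usage = c(NOTAGENE = 1), sub_rate = 0, conversion_prob = 0)))
  expect_error(generate_repertoire(cfg, bundled_set()), "unknown gene")
})

test_that("generation is deterministic for a fixed seed and config", {
  set <- bundled_set()
  cfg <- repertoire_config(seed = 42, n_per_group = 40, groups = list(
    AL = list(usage = usage_kappa(), sub_rate = 0.04, conversion_prob = 0.3),
    MM = list(usage = usage_kappa(), sub_rate = 0.04, conversion_prob = 0.1)))
  r1 <- generate_repertoire(cfg, set)
  r2 <- generate_repertoire(cfg, set)
  expect_identical(r1, r2)
  tmp1 <- withr::local_tempfile(fileext = ".fasta")
  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  write_repertoire(r1, fasta = tmp1)
  write_repertoire(r2, fasta = tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})

test_that("zero rates reproduce the germline exactly", {
  set <- bundled_set()
  cfg <- repertoire_config(seed = 3, n_per_group = 12, groups = list(
    A = list(usage = usage_kappa(), sub_rate = 0, conversion_prob = 0)))
  rep <- generate_repertoire(cfg, set)
  for (i in seq_len(nrow(rep))) {
    v <- get_germline(set, rep$v_call[i])
    ref <- concat_germline(v, default_j_gene(set, v$locus))
    expect_identical(rep$sequence_aa[i], ref$sequence)
  }
  expect_identical(rep$n_substitutions, rep(0L, nrow(rep)))
  ml <- mutation_load(rep$sequence_aa[1:4], rep$v_call[1:4], set)
  expect_equal(ml$fraction, rep(0, 4))
})

test_that("truth table is consistent with detection", {
  set <- bundled_set()
  cfg <- repertoire_config(seed = 14, n_per_group = 150, groups = list(
    A = list(usage = usage_kappa(), sub_rate = 0.05, conversion_prob = 0.4,
             plus2_T_prob = 0.7)))
  rep <- generate_repertoire(cfg, set)
  for (i in which(rep$sequon_introduced)) {
    v <- get_germline(set, rep$v_call[i])
    ref <- concat_germline(v, default_j_gene(set, v$locus))
    idx <- oracle_scan(rep$sequence_aa[i])
    # the introduced sequon is detectable at the recorded IMGT position
    expect_true(match(rep$introduced_position[i], ref$imgt_positions) %in% idx)
    expect_true(rep$introduced_position[i] %in%
                  get_germline(set, rep$v_call[i])$progenitor_sites)
  }
  # sequences without introduction may only carry spontaneous sequons,
  # expected at a low rate
  spont <- vapply(rep$sequence_aa[!rep$sequon_introduced],
                  function(s) length(oracle_scan(s)) > 0, logical(1))
  expect_lt(mean(spont), 0.25)
})

test_that("null generator gives odds ratios near one", {
  set <- bundled_set()
  log_ors <- vapply(1:20, function(k) {
    cfg <- repertoire_config(seed = 1000 + k, n_per_group = 400,
      groups = list(
        A = list(usage = usage_kappa(), sub_rate = 0.05, conversion_prob = 0),
        B = list(usage = usage_kappa(), sub_rate = 0.05, conversion_prob = 0)))
    rep <- generate_repertoire(cfg, set)
    has <- vapply(rep$sequence_aa, function(s) length(oracle_scan(s)) > 0,
                  logical(1))
    a <- sum(has[rep$group == "A"]); b <- sum(!has[rep$group == "A"])
    c_ <- sum(has[rep$group == "B"]); d <- sum(!has[rep$group == "B"])
    log(odds_ratio_manual(a, b, c_, d)$odds_ratio)
  }, numeric(1))
  expect_lt(abs(mean(log_ors)), 0.2)
})

test_that("gene usage is recovered within multinomial sampling error", {
  set <- bundled_set()
  usage <- c(0.5, 0.3, 0.15, 0.05)
  names(usage) <- names(usage_kappa())
  cfg <- repertoire_config(seed = 77, n_per_group = 1000, groups = list(
    A = list(usage = usage, sub_rate = 0, conversion_prob = 0)))
  rep <- generate_repertoire(cfg, set)
  obs <- table(factor(rep$v_call, levels = names(usage)))
  chi <- stats::chisq.test(obs, p = usage)
  expect_gt(chi$p.value, 0.001)
})

test_that("toy structure geometry is as constructed", {
  ep <- generate_toy_structure("extended_peptide", n_res = 5)
  xyz <- as.matrix(ep[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  nonadj <- abs(outer(ep$resno, ep$resno, "-")) >= 2
  expect_gt(min(d[nonadj]), 2.0)  # no clashes between non-adjacent residues
  fib <- generate_toy_structure("beta_arch_fibril", strand_len = 4,
                                n_layers = 5, rise = 4.8)
  ca <- fib[fib$elety == "CA" & fib$resno == 1, ]
  rises <- diff(sort(ca$z))
  expect_equal(rises, rep(4.8, 4), tolerance = 0.01)
  expect_identical(length(unique(fib$chain)), 5L)
})

test_that("FASTA/TSV round-trips preserve the repertoire table", {
  set <- bundled_set()
  cfg <- repertoire_config(seed = 5, n_per_group = 10, groups = list(
    A = list(usage = usage_lambda(), sub_rate = 0.02, conversion_prob = 0.5)))
  rep <- generate_repertoire(cfg, set)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, fasta = fa, truth = tsv)
  back_fa <- read_repertoire(fa)
  expect_identical(back_fa$sequence_aa, rep$sequence_aa)
  expect_identical(back_fa$v_call, rep$v_call)
  back_tsv <- read_repertoire(tsv)
  expect_identical(back_tsv$sequence_id, rep$sequence_id)
  expect_error(read_repertoire(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})
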